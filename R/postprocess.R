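#' Per-video frame prediction sequences
#'
#' Container for the per-frame classifier output of one time-lapse video:
#' the unit consumed by the postprocessing algorithm. Each frame carries a
#' probability vector over the stage ontology; the top label is the argmax
#' (ties broken toward the lower ordinal, i.e. the earlier stage) and the
#' confidence is the maximum probability.
#'
#' @param video_id single string identifying the video.
#' @param frame_index integer vector, strictly increasing.
#' @param time_minutes numeric vector, strictly increasing, minutes since
#'   fertilisation.
#' @param probabilities numeric matrix, one row per frame, columns named by
#'   stage label in developmental order (defaults to the full 17-class
#'   ontology). Rows must be non-negative and sum to 1 within 1e-6.
#' @return object of class `prediction_sequence`: a list with elements
#'   `video_id`, `frame_index`, `time_minutes`, `probabilities`,
#'   `top_label` (factor) and `confidence`.
#' @seealso [smooth_predictions()]
#' @export
prediction_sequence <- function(video_id, frame_index, time_minutes,
                                probabilities) {
  stopifnot(is.character(video_id), length(video_id) == 1L)
  probabilities <- as.matrix(probabilities)
  n <- nrow(probabilities)
  if (n == 0L) stop("prediction sequence must contain at least one frame",
                    call. = FALSE)
  if (is.null(colnames(probabilities))) {
    if (ncol(probabilities) != 17L) {
      stop("unnamed probability matrices must have 17 columns", call. = FALSE)
    }
    colnames(probabilities) <- stage_levels()
  }
  classes <- colnames(probabilities)
  frame_index <- as.integer(frame_index)
  time_minutes <- as.numeric(time_minutes)
  if (length(frame_index) != n || length(time_minutes) != n) {
    stop("frame_index, time_minutes and probability rows must align",
         call. = FALSE)
  }
  if (n > 1L && (any(diff(frame_index) <= 0) || any(diff(time_minutes) <= 0))) {
    stop("frame_index and time_minutes must be strictly increasing",
         call. = FALSE)
  }
  if (any(probabilities < 0)) {
    stop("probabilities must be non-negative", call. = FALSE)
  }
  rs <- rowSums(probabilities)
  if (any(abs(rs - 1) > 1e-6)) {
    stop(sprintf("probability rows must sum to 1 (worst deviation %.2e)",
                 max(abs(rs - 1))), call. = FALSE)
  }
  top <- max.col(probabilities, ties.method = "first")
  structure(list(
    video_id = video_id,
    frame_index = frame_index,
    time_minutes = time_minutes,
    probabilities = probabilities,
    top_label = factor(classes[top], levels = classes),
    confidence = probabilities[cbind(seq_len(n), top)]
  ), class = "prediction_sequence")
}

#' @export
print.prediction_sequence <- function(x, ...) {
  cat(sprintf("<prediction_sequence> video %s: %d frames, %.1f-%.1f min\n",
              x$video_id, length(x$frame_index),
              min(x$time_minutes), max(x$time_minutes)))
  cat("  stages observed:",
      paste(unique(as.character(x$top_label)), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.prediction_sequence <- function(x) length(x$frame_index)

#' Substitute low-confidence frame predictions
#'
#' First stage of the denoising algorithm: frames whose maximum class
#' probability does not exceed `threshold` (strictly) are assigned the top
#' label of the most recent earlier frame whose confidence does exceed it.
#' Leading frames with no confident predecessor keep their own top label.
#'
#' @param seq a [prediction_sequence()].
#' @param threshold confidence threshold in (0, 1]; default 0.8.
#' @return factor of per-frame labels, same length as the sequence.
#' @export
substitute_low_confidence <- function(seq, threshold = 0.8) {
  stopifnot(inherits(seq, "prediction_sequence"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single number in (0, 1]", call. = FALSE)
  }
  labels <- seq$top_label
  confident <- seq$confidence > threshold
  n <- length(labels)
  # index of latest confident frame at or before each position
  latest <- cummax(ifelse(confident, seq_len(n), 0L))
  out <- labels
  low <- !confident & latest > 0L
  out[low] <- labels[latest[low]]
  out
}

#' Change detection and run grouping for label sequences
#'
#' `compute_changes()` marks frames whose label differs from the previous
#' frame (the first frame is defined as unchanged). `assign_groups()` turns
#' the change vector into run identifiers by cumulative summation: frames
#' sharing a group id form one contiguous same-label run.
#'
#' @param labels factor or character vector of per-frame labels.
#' @param changes 0/1 integer vector as produced by `compute_changes()`.
#' @return `compute_changes()`: integer 0/1 vector; `assign_groups()`:
#'   non-decreasing integer vector of run ids starting at 0.
#' @examples
#' ch <- compute_changes(c("t2", "t2", "t3", "t2", "t2"))
#' ch                 # 0 0 1 1 0
#' assign_groups(ch)  # 0 0 1 2 2
#' @export
compute_changes <- function(labels) {
  if (length(labels) == 0L) stop("label sequence is empty", call. = FALSE)
  labels <- as.character(labels)
  c(0L, as.integer(labels[-1L] != labels[-length(labels)]))
}

#' @rdname compute_changes
#' @export
assign_groups <- function(changes) {
  stopifnot(is.numeric(changes), all(changes %in% c(0L, 1L)))
  as.integer(cumsum(changes))
}

#' Identify interruptive groups
#'
#' For each class `c` present in the sequence let `Gc` be the set of run
#' (group) ids labelled `c`. Any run id lying strictly inside
#' `[min(Gc), max(Gc)]` but not itself in `Gc` interrupts class `c`: it is a
#' short excursion to a foreign label inside the span of `c` and is treated
#' as noise by [remove_interruptions()].
#'
#' @param labels per-frame labels.
#' @param groups run ids aligned with `labels` (defaults to
#'   `assign_groups(compute_changes(labels))`).
#' @return named list, one element per class present (in order of first
#'   occurrence): an integer vector of interruptive-run lengths named by
#'   run id (empty when the class is not interrupted).
#' @examples
#' find_interruptive_groups(c("t2", "t2", "t3", "t2", "t2"))
#' @export
find_interruptive_groups <- function(labels,
                                     groups = assign_groups(compute_changes(labels))) {
  labels <- as.character(labels)
  if (length(labels) != length(groups)) {
    stop("labels and groups must align", call. = FALSE)
  }
  run_label <- labels[!duplicated(groups)]   # label of each run, in order
  run_len <- as.integer(table(factor(groups, levels = sort(unique(groups)))))
  classes <- unique(run_label)
  out <- lapply(classes, function(cl) {
    ids <- which(run_label == cl) - 1L      # run ids are 0-based
    if (length(ids) < 2L) return(stats::setNames(integer(0), character(0)))
    rng <- seq(min(ids), max(ids))
    inter <- setdiff(rng, ids)
    stats::setNames(run_len[inter + 1L], inter)
  })
  stats::setNames(out, classes)
}

#' Remove interruptive groups from a label sequence
#'
#' Second stage of the denoising algorithm. Classes are processed in
#' ascending order of first occurrence; every run that interrupts a class
#' (see [find_interruptive_groups()]) is relabelled to that class, runs are
#' recomputed, and the procedure repeats until no interruptive group
#' remains. Relabelling (rather than deleting) keeps the output
#' frame-aligned for timing extraction. Each relabelling strictly reduces
#' the number of runs, so the fixpoint iteration terminates.
#'
#' Genuine stage reversions survive: a sequence that ends in a lower stage
#' (e.g. a long `t3` run followed by a long `t2` run) has no interrupted
#' class and is returned unchanged, unlike monotonic-regression smoothing.
#'
#' By default an interruptive group is absorbed only when it is no longer
#' than the nearest same-class runs flanking it (the neighbouring-group
#' length comparison). This guard decides which side of a mutual
#' interruption is the noise: a one-frame excursion inside two long runs
#' is absorbed, while a long foreign run claimed by a stray one-frame
#' flip is kept. Without the guard (`length_guard = FALSE`, the literal
#' reading of "discard all interruptive groups") a single isolated flip
#' back to an earlier stage deep inside a later run would relabel the
#' whole intervening span and corrupt the onset of long stages.
#'
#' Absorption additionally requires the group to touch one of its
#' flanking same-class runs, so every absorption merges runs; this makes
#' the fixpoint provably terminating (mutually interruptive patterns
#' could otherwise flip a detached middle run between two classes
#' forever) and never changes the clean spike cases.
#'
#' @param labels per-frame labels (factor or character).
#' @param length_guard absorb an interruptive group only if its length
#'   does not exceed the shorter of the two flanking same-class runs
#'   (default `TRUE`).
#' @return factor of labels with the same length and levels as the input.
#' @examples
#' remove_interruptions(c("t2", "t2", "t3", "t2", "t2"))
#' @export
remove_interruptions <- function(labels, length_guard = TRUE) {
  n <- length(labels)
  if (n == 0L) stop("label sequence is empty", call. = FALSE)
  lev <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  lab <- as.character(labels)
  repeat {
    r <- rle(lab)
    run_label <- r$values
    changed <- FALSE
    for (cl in unique(run_label)) {          # ascending first occurrence
      ids <- which(run_label == cl)
      if (length(ids) < 2L) next
      inter <- setdiff(seq(min(ids), max(ids)), ids)
      for (ig in inter) {
        left <- max(ids[ids < ig])
        right <- min(ids[ids > ig])
        # absorb only groups touching a flanking same-class run, so every
        # absorption merges runs and the fixpoint provably terminates
        absorb <- left == ig - 1L || right == ig + 1L
        if (absorb && length_guard) {
          absorb <- r$lengths[ig] <= min(r$lengths[left], r$lengths[right])
        }
        if (absorb) {
          r$values[ig] <- cl
          lab <- inverse.rle(r)
          changed <- TRUE
          break                              # recompute runs, restart scan
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  factor(lab, levels = lev)
}

#' Denoise a prediction sequence
#'
#' Full two-stage postprocessing: low-confidence substitution
#' ([substitute_low_confidence()]) followed by interruptive-group removal
#' ([remove_interruptions()]). The output is a frame-aligned label
#' sequence suitable for transition-timing extraction.
#'
#' @inheritParams substitute_low_confidence
#' @inheritParams remove_interruptions
#' @return factor of final per-frame labels.
#' @examples
#' p <- diag(17)[c(4, 4, 5, 4, 4), ]  # t2 t2 t3 t2 t2, all confident
#' colnames(p) <- stage_levels()
#' s <- prediction_sequence("v1", 0:4, seq(0, 80, 20), p)
#' as.character(smooth_predictions(s))
#' @export
smooth_predictions <- function(seq, threshold = 0.8, length_guard = TRUE) {
  remove_interruptions(substitute_low_confidence(seq, threshold),
                       length_guard = length_guard)
}
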