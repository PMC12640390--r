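#' Extract stage-transition events from a final label sequence
#'
#' One event is emitted per run of identical labels (including the first
#' run, so the starting stage is timed too). Only the resulting stage is
#' recorded: a change from `t2` to `t4` and one from `t3` to `t4` are both
#' transitions *to* `t4`. The event time is the acquisition time of the
#' first frame bearing the new label, in hours.
#'
#' @param labels final per-frame labels (e.g. from [smooth_predictions()]).
#' @param time_minutes per-frame acquisition times in minutes, strictly
#'   increasing, aligned with `labels`.
#' @param video_id single string.
#' @return data.frame with columns `video_id`, `stage` (factor over the
#'   label levels) and `time_hours`.
#' @examples
#' extract_transitions(rep(c("t2", "t4"), each = 5), seq(0, 180, 20), "v1")
#' @export
extract_transitions <- function(labels, time_minutes, video_id = "video") {
  n <- length(labels)
  if (n == 0L) stop("label sequence is empty", call. = FALSE)
  if (length(time_minutes) != n) {
    stop("labels and time_minutes must align", call. = FALSE)
  }
  if (n > 1L && any(diff(time_minutes) <= 0)) {
    stop("time_minutes must be strictly increasing", call. = FALSE)
  }
  lev <- if (is.factor(labels)) levels(labels) else stage_levels()
  lab <- as.character(labels)
  r <- rle(lab)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  data.frame(
    video_id = rep(video_id, length(starts)),
    stage = factor(r$values, levels = lev),
    time_hours = time_minutes[starts] / 60,
    stringsAsFactors = FALSE
  )
}

#' Timing errors between predicted and ground-truth transition events
#'
#' Events are matched by (video, stage); the signed error is predicted time
#' minus true time, in hours. At a 20-minute frame interval a single-frame
#' misclassification therefore contributes 1/3 h (0.33 h) of error. Stages
#' present on only one side are reported as unmatched and excluded from the
#' error statistics.
#'
#' @param predicted,truth event data.frames as produced by
#'   [extract_transitions()] (columns `video_id`, `stage`, `time_hours`).
#' @param match duplicate-event policy. A stage can be reached twice in one
#'   video (e.g. after reverse cleavage). `"first"` (default, the standard
#'   morphokinetic convention) times each stage by its first occurrence;
#'   `"occurrence"` pairs the k-th occurrence in prediction with the k-th
#'   in truth; `"strict"` raises an error on any duplicate.
#' @return list with `errors` (data.frame `video_id`, `stage`,
#'   `error_hours`), `unmatched_truth` and `unmatched_predicted` (event
#'   data.frames).
#' @export
timing_errors <- function(predicted, truth,
                          match = c("first", "occurrence", "strict")) {
  match <- match.arg(match)
  for (nm in c("video_id", "stage", "time_hours")) {
    if (!nm %in% names(predicted) || !nm %in% names(truth)) {
      stop(sprintf("event tables must contain column '%s'", nm), call. = FALSE)
    }
  }
  key <- function(ev) {
    occ <- stats::ave(seq_len(nrow(ev)), ev$video_id, as.character(ev$stage),
                      FUN = seq_along)
    if (match == "strict" && any(occ > 1L)) {
      stop(paste0("duplicate (video, stage) events found; ",
                  "choose match = 'first' or 'occurrence'"), call. = FALSE)
    }
    if (match == "first") {
      keep <- occ == 1L
      ev <- ev[keep, , drop = FALSE]
      occ <- occ[keep]
    }
    ev$.key <- paste(ev$video_id, as.character(ev$stage), occ, sep = "\r")
    ev
  }
  p <- key(predicted)
  t_ <- key(truth)
  i <- base::match(t_$.key, p$.key)
  matched <- !is.na(i)
  errors <- data.frame(
    video_id = t_$video_id[matched],
    stage = t_$stage[matched],
    error_hours = p$time_hours[i[matched]] - t_$time_hours[matched],
    stringsAsFactors = FALSE
  )
  list(
    errors = errors,
    unmatched_truth = t_[!matched, c("video_id", "stage", "time_hours")],
    unmatched_predicted =
      p[!(p$.key %in% t_$.key), c("video_id", "stage", "time_hours")]
  )
}

# percentile levels reported in the timing-error summary
.summary_percentiles <- c(25, 50, 75, 80, 85, 90, 95, 99)

#' Quantile summary of per-stage timing errors
#'
#' For each stage: event count, mean error, sample standard deviation and
#' the 25/50/75/80/85/90/95/99th percentiles (linear interpolation between
#' order statistics), all in hours. Stages without matched events get
#' count 0 and `NA` statistics.
#'
#' @param errors data.frame with columns `stage` and `error_hours`
#'   (the `errors` element of [timing_errors()]), or a named list of
#'   per-stage numeric error vectors.
#' @param stages stages to report; defaults to those present.
#' @return data.frame of class `timing_error_summary`: one row per stage
#'   with columns `stage`, `count`, `mean`, `std` and `p25` .. `p99`.
#' @export
summarize_errors <- function(errors, stages = NULL) {
  if (is.list(errors) && !is.data.frame(errors)) {
    errors <- data.frame(
      stage = rep(names(errors), lengths(errors)),
      error_hours = unlist(errors, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  stage_chr <- as.character(errors$stage)
  if (is.null(stages)) {
    stages <- if (is.factor(errors$stage)) {
      intersect(levels(errors$stage), unique(stage_chr))
    } else unique(stage_chr)
  }
  rows <- lapply(stages, function(st) {
    e <- errors$error_hours[stage_chr == st]
    n <- length(e)
    qs <- if (n > 0) stats::quantile(e, .summary_percentiles / 100,
                                     names = FALSE, type = 7)
          else rep(NA_real_, length(.summary_percentiles))
    out <- data.frame(stage = st, count = n,
                      mean = if (n > 0) mean(e) else NA_real_,
                      std = if (n > 1) stats::sd(e) else NA_real_,
                      stringsAsFactors = FALSE)
    out[paste0("p", .summary_percentiles)] <- as.list(qs)
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("timing_error_summary", class(out))
  out
}
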