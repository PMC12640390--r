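# CSV/JSON interchange. All tables are UTF-8 comma-separated with a header
# row; stage labels appear verbatim in their canonical forms (including
# "t9+"). Probabilities are written at 6 decimal places, hours at 2 in
# summaries; round trips are stable at those precisions.

#' Read and validate a frame annotation table
#'
#' Expects columns `video_id`, `frame_index`, `time_minutes`, `label`.
#' Labels are parsed against the stage ontology; records are sorted by
#' video and frame; duplicate frames or non-increasing acquisition times
#' within a video are rejected with the offending row numbers.
#'
#' @param path CSV file path.
#' @return data.frame sorted by (`video_id`, `frame_index`) with `label`
#'   as a factor over [stage_levels()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("video_id", "frame_index", "time_minutes", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lab <- try(parse_label(df$label), silent = TRUE)
  if (inherits(lab, "try-error")) {
    bad <- which(!(df$label %in% stage_levels() |
                     df$label %in% names(.stage_aliases)))
    stop(sprintf("unparseable label(s) %s at row(s) %s",
                 paste(sQuote(unique(df$label[bad])), collapse = ", "),
                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  df$label <- lab
  df <- df[order(df$video_id, df$frame_index), , drop = FALSE]
  rownames(df) <- NULL
  for (v in split(seq_len(nrow(df)), df$video_id)) {
    if (anyDuplicated(df$frame_index[v])) {
      stop(sprintf("duplicate frame_index in video %s (rows %s)",
                   df$video_id[v[1]],
                   paste(utils::head(v[duplicated(df$frame_index[v])], 5),
                         collapse = ", ")), call. = FALSE)
    }
    if (length(v) > 1L && any(diff(df$time_minutes[v]) <= 0)) {
      r <- v[which(diff(df$time_minutes[v]) <= 0)[1] + 1L]
      stop(sprintf("non-increasing time_minutes in video %s at row %d",
                   df$video_id[v[1]], r), call. = FALSE)
    }
  }
  df
}

#' @rdname read_annotations
#' @param annotations data.frame with the four annotation columns.
#' @export
write_annotations <- function(path, annotations) {
  out <- annotations[c("video_id", "frame_index", "time_minutes", "label")]
  out$label <- as.character(out$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-frame prediction tables
#'
#' The predictions CSV carries one row per frame: `video_id`,
#' `frame_index`, `time_minutes` and one probability column per stage
#' named `p_<label>` (canonical label strings, 17 columns). On reading,
#' rows are renormalised to sum exactly to 1 (6-decimal rounding on write
#' perturbs sums by up to ~1e-5).
#'
#' @param path CSV file path.
#' @param seqs a [prediction_sequence()] or list of them.
#' @return `read_predictions()`: named list of [prediction_sequence()]
#'   objects, one per video.
#' @export
write_predictions <- function(path, seqs) {
  if (inherits(seqs, "prediction_sequence")) seqs <- list(seqs)
  tabs <- lapply(seqs, function(s) {
    p <- round(s$probabilities, 6)
    colnames(p) <- paste0("p_", colnames(p))
    data.frame(video_id = s$video_id, frame_index = s$frame_index,
               time_minutes = s$time_minutes, p, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pcols <- paste0("p_", stage_levels())
  miss <- setdiff(c("video_id", "frame_index", "time_minutes", pcols),
                  names(df))
  if (length(miss)) {
    stop("predictions file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$video_id, df$frame_index), , drop = FALSE]
  out <- lapply(split(df, df$video_id), function(d) {
    p <- as.matrix(d[pcols])
    dimnames(p) <- list(NULL, stage_levels())
    p <- p / rowSums(p)
    prediction_sequence(d$video_id[1], d$frame_index, d$time_minutes, p)
  })
  out[unique(df$video_id)]
}

#' Read and write transition-event tables
#'
#' Events CSV: `video_id`, `stage`, `time_hours` (written at 4 decimal
#' places, i.e. well below frame resolution).
#'
#' @param path CSV file path.
#' @param events event data.frame from [extract_transitions()].
#' @return `read_events()`: data.frame with `stage` parsed to a factor.
#' @export
write_events <- function(path, events) {
  out <- events[c("video_id", "stage", "time_hours")]
  out$stage <- as.character(out$stage)
  out$time_hours <- round(out$time_hours, 4)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$stage <- parse_label(as.character(df$stage))
  df
}

#' Write a timing-error quantile summary
#'
#' Lays the summary out with one column per stage and one row per
#' statistic, in the order count, mean, Std, 25%, 50%, 75%, 80%, 85%,
#' 90%, 95%, 99%. Hours are written at 2 decimal places.
#'
#' @param path CSV file path.
#' @param summary a [summarize_errors()] result.
#' @return `read_summary()`: the summary as a data.frame in the
#'   [summarize_errors()] row layout.
#' @export
write_summary <- function(path, summary) {
  stats_names <- c("count", "mean", "Std", paste0(.summary_percentiles, "%"))
  cols <- c("count", "mean", "std", paste0("p", .summary_percentiles))
  m <- t(as.matrix(summary[cols]))
  m[-1, ] <- round(m[-1, ], 2)
  out <- data.frame(statistic = stats_names, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("statistic", as.character(summary$stage))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[-1]))
  out <- data.frame(stage = rownames(m), stringsAsFactors = FALSE)
  out[c("count", "mean", "std", paste0("p", .summary_percentiles))] <-
    as.data.frame(m)
  out$count <- as.integer(out$count)
  rownames(out) <- NULL
  class(out) <- c("timing_error_summary", class(out))
  out
}

#' Write a metrics report as JSON
#'
#' @param path output path.
#' @param metrics a [classification_metrics()] result (or any list).
#' @export
write_metrics <- function(path, metrics) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a grayscale frame image
#'
#' @param path PNG file path.
#' @return numeric matrix in \[0, 1\] (first channel if the file has
#'   several).
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
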