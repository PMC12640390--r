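#' Confusion matrix over the stage ontology
#'
#' Raw counts and row-normalised percentages (each true-class row with
#' nonzero support sums to 100). Row/column order follows the
#' developmental ordering of the ontology (or the supplied levels).
#'
#' @param y_true,y_pred label vectors of equal length (character or
#'   factor; parsed against `levels`).
#' @param levels label set defining row/column order; defaults to the full
#'   17-class ontology.
#' @return object of class `confusion_matrix`: list with `counts`
#'   (integer matrix), `percent` (row-normalised, `NA` rows for zero
#'   support), and `support` (per-class true counts).
#' @export
confusion_matrix <- function(y_true, y_pred, levels = stage_levels()) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  yt <- factor(as.character(y_true), levels = levels)
  yp <- factor(as.character(y_pred), levels = levels)
  if (anyNA(yt) || anyNA(yp)) stop("labels outside the given levels",
                                   call. = FALSE)
  counts <- table(true = yt, predicted = yp)
  counts <- matrix(as.integer(counts), nrow = length(levels),
                   dimnames = list(true = levels, predicted = levels))
  support <- rowSums(counts)
  percent <- counts / ifelse(support == 0, NA_real_, support) * 100
  structure(list(counts = counts, percent = percent, support = support),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("<confusion_matrix>", sum(x$counts), "frames,",
      sum(x$support > 0), "classes with support\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Accuracy and macro-averaged precision/recall/F1
#'
#' Accuracy is the fraction of correct predictions over all retained
#' frames. Precision, recall and F1 are macro-averaged over classes with
#' nonzero support (classes absent from a batch are skipped, not counted
#' as zero). Frames whose *true* label is in `exclude` are removed before
#' computing any metric; by default the rare hatched-blastocyst class
#' (`tHB`), which has too few examples for stable evaluation, is excluded.
#'
#' @inheritParams confusion_matrix
#' @param exclude character vector of true labels to drop (default
#'   `"tHB"`; use `character(0)` to keep everything).
#' @return list with elements `accuracy`, `precision`, `recall`, `f1`
#'   (macro averages) and `per_class` (data.frame of per-class metrics).
#' @export
classification_metrics <- function(y_true, y_pred, exclude = "tHB",
                                   levels = stage_levels()) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  keep <- !(as.character(y_true) %in% exclude)
  y_true <- y_true[keep]
  y_pred <- y_pred[keep]
  if (length(y_true) == 0L) stop("no frames left after exclusion",
                                 call. = FALSE)
  cm <- confusion_matrix(y_true, y_pred, levels = levels)$counts
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec <- ifelse(predicted > 0, tp / predicted, NA_real_)
  rec <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec),
               ifelse(support > 0, 0, NA_real_))
  with_support <- support > 0
  per_class <- data.frame(class = rownames(cm), support = support,
                          precision = prec, recall = rec, f1 = f1,
                          row.names = NULL, stringsAsFactors = FALSE)
  list(
    accuracy = sum(tp) / sum(cm),
    precision = mean(prec[with_support], na.rm = TRUE),
    recall = mean(rec[with_support]),
    f1 = mean(f1[with_support]),
    per_class = per_class
  )
}

#' Inverse-class-frequency loss weights
#'
#' Weight for class c is `(N / K) / n_c` where `N` is the total sample
#' count, `K` the number of classes and `n_c` the class count. Under this
#' normalisation `sum(w_c * n_c) == N`, i.e. the count-weighted mean
#' weight is 1, keeping the loss scale comparable across experiments while
#' boosting the gradient contribution of under-represented stages.
#'
#' @param counts named (or unnamed) vector of positive per-class counts.
#' @return numeric vector of weights, same names as `counts`.
#' @examples
#' inverse_class_frequency_weights(c(A = 10, B = 40))  # 2.5, 0.625
#' @export
inverse_class_frequency_weights <- function(counts) {
  if (any(counts <= 0)) {
    stop(paste0("all class counts must be positive; ",
                "exclude classes with zero count before weighting"),
         call. = FALSE)
  }
  (sum(counts) / length(counts)) / counts
}
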