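#' Encode minutes since fertilisation as a two-hour-window index
#'
#' The fused classifier consumes elapsed time as a one-hot vector over
#' two-hour windows spanning a maximum incubation of seven days, i.e.
#' 7 x 24 / 2 = 84 windows. The window index is `floor(minutes / 120)`:
#' 150 minutes falls in window 1, 240 minutes in window 2. Times at or
#' beyond seven days (10,080 minutes) are clamped to the last window (83)
#' with a warning rather than rejected, since acquisition occasionally
#' overruns the nominal incubation period.
#'
#' @param minutes non-negative numeric vector, minutes since fertilisation.
#'   Fractional minutes are accepted; the floor is applied after division.
#' @return `time_to_index()`: integer vector of window indices in 0..83.
#'   `encode_time()`: for scalar input a length-84 0/1 vector with a single
#'   1; for vector input a matrix with one such row per element.
#' @examples
#' time_to_index(c(0, 150, 160, 240))
#' which(encode_time(150) == 1) - 1  # window index 1
#' @export
time_to_index <- function(minutes) {
  if (!is.numeric(minutes) || length(minutes) == 0) {
    stop("minutes must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(minutes) || any(minutes < 0)) {
    stop("minutes since fertilisation must be non-negative", call. = FALSE)
  }
  idx <- as.integer(floor(minutes / 120))
  over <- idx > 83L
  if (any(over)) {
    warning(sprintf(
      "%d time(s) exceed the assumed 7-day incubation; clamped to window 83",
      sum(over)
    ), call. = FALSE)
    idx[over] <- 83L
  }
  idx
}

#' @rdname time_to_index
#' @export
encode_time <- function(minutes) {
  idx <- time_to_index(minutes)
  if (length(idx) == 1L) {
    v <- integer(84)
    v[idx + 1L] <- 1L
    return(v)
  }
  m <- matrix(0L, nrow = length(idx), ncol = 84)
  m[cbind(seq_along(idx), idx + 1L)] <- 1L
  m
}
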