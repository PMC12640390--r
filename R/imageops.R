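# Image preprocessing for grayscale well images: CLAHE, bilinear resize,
# channel replication + ImageNet standardisation, and stochastic training
# augmentation. Images are numeric matrices in [0, 1] (rows = y, cols = x).

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Local contrast normalisation for microscopy images with uneven
#' illumination. The image is divided into a grid of tiles; each tile's
#' histogram is clipped at `clip_limit` times the uniform bin height (the
#' excess is redistributed) before computing its equalisation mapping, and
#' pixel values are bilinearly interpolated between the mappings of the
#' four surrounding tiles.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param n_tiles tiles per image side (default 8).
#' @param clip_limit relative histogram clip factor (default 2).
#' @param n_bins histogram bins (default 256).
#' @return matrix of the same shape, values in \[0, 1\].
#' @export
clahe <- function(img, n_tiles = 8L, clip_limit = 2, n_bins = 256L) {
  stopifnot(is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  nt <- max(1L, min(as.integer(n_tiles), H, W))
  b <- pmin(floor(pmin(pmax(img, 0), 1) * n_bins) + 1L, n_bins)
  tsr <- H / nt; tsc <- W / nt
  kr <- pmin(ceiling(row(img) / tsr), nt)
  kc <- pmin(ceiling(col(img) / tsc), nt)
  tile <- (kr - 1L) + nt * (kc - 1L)
  counts <- tabulate(b + n_bins * tile, nbins = n_bins * nt * nt)
  hist <- matrix(counts, nrow = n_bins)
  npix <- colSums(hist)
  clip <- pmax(1, clip_limit * npix / n_bins)
  excess <- pmax(sweep(hist, 2, clip), 0)
  hist <- pmin(hist, matrix(clip, n_bins, nt * nt, byrow = TRUE))
  hist <- sweep(hist, 2, colSums(excess) / n_bins, "+")
  maps <- apply(hist, 2, function(h) cumsum(h) / sum(h))   # n_bins x tiles
  # bilinear interpolation between tile mappings at tile centres
  interp <- function(i, ts) {
    pos <- (i - 0.5) / ts + 0.5
    k1 <- floor(pos)
    w <- pos - k1
    list(k1 = pmin(pmax(k1, 1L), nt), k2 = pmin(pmax(k1 + 1L, 1L), nt), w = w)
  }
  ri <- interp(as.vector(row(img)), tsr)
  ci <- interp(as.vector(col(img)), tsc)
  bv <- as.vector(b)
  g <- function(kr_, kc_) maps[bv + n_bins * ((kr_ - 1L) + nt * (kc_ - 1L))]
  out <- (1 - ri$w) * (1 - ci$w) * g(ri$k1, ci$k1) +
    ri$w * (1 - ci$w) * g(ri$k2, ci$k1) +
    (1 - ri$w) * ci$w * g(ri$k1, ci$k2) +
    ri$w * ci$w * g(ri$k2, ci$k2)
  matrix(out, H, W)
}

# bilinear resize of a matrix to out_h x out_w
resize_bilinear <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  if (H == out_h && W == out_w) return(img)
  coord <- function(n_out, n_in) {
    p <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    k1 <- pmin(pmax(floor(p), 1), n_in)
    k2 <- pmin(k1 + 1, n_in)
    list(k1 = k1, k2 = k2, w = pmin(pmax(p - floor(p), 0), 1))
  }
  r <- coord(out_h, H); cc <- coord(out_w, W)
  a11 <- img[r$k1, cc$k1, drop = FALSE]; a21 <- img[r$k2, cc$k1, drop = FALSE]
  a12 <- img[r$k1, cc$k2, drop = FALSE]; a22 <- img[r$k2, cc$k2, drop = FALSE]
  wr <- matrix(r$w, out_h, out_w)
  wc <- matrix(cc$w, out_h, out_w, byrow = TRUE)
  (1 - wr) * (1 - wc) * a11 + wr * (1 - wc) * a21 +
    (1 - wr) * wc * a12 + wr * wc * a22
}

#' Preprocess a grayscale frame for the classifier
#'
#' Resizes to the model input size, applies CLAHE, replicates the
#' grayscale channel into R, G and B, and standardises each channel with
#' the ImageNet constants (means 0.485/0.456/0.406, standard deviations
#' 0.229/0.224/0.225) so that ImageNet-pretrained backbones remain
#' compatible. Deterministic.
#'
#' @param img single-channel numeric matrix; values in \[0, 1\], or 0..255
#'   (rescaled automatically). Multi-channel input is rejected.
#' @param image_size output side length in pixels.
#' @param apply_clahe apply CLAHE before standardisation (default `TRUE`).
#' @param means,stds per-channel standardisation constants.
#' @return numeric array of shape `(image_size, image_size, 3)`.
#' @export
preprocess_image <- function(img, image_size = 64L, apply_clahe = TRUE,
                             means = c(0.485, 0.456, 0.406),
                             stds = c(0.229, 0.224, 0.225)) {
  if (!is.matrix(img)) {
    stop("expected a single-channel image as a numeric matrix", call. = FALSE)
  }
  x <- img
  if (max(x) > 1) x <- x / 255
  x <- resize_bilinear(x, image_size, image_size)
  if (apply_clahe) x <- clahe(x)
  out <- array(0, c(image_size, image_size, 3L))
  for (k in 1:3) out[, , k] <- (x - means[k]) / stds[k]
  out
}

#' Training augmentation policy
#'
#' Stochastic augmentation applied during training only: rotation plus
#' shift with probability `p_rotate_shift` (0.3), horizontal flip with
#' probability `p_flip` (0.5), and additive Gaussian noise or box blur
#' (one of the two, chosen at random) with probability `p_noise_blur`
#' (0.5).
#'
#' @param p_rotate_shift,p_flip,p_noise_blur transform probabilities.
#' @param max_angle maximum rotation in degrees (uniform in +/-).
#' @param max_shift maximum shift as a fraction of the image side.
#' @param noise_sd standard deviation of the additive noise.
#' @return list of class `augmentation_policy`.
#' @export
augmentation_policy <- function(p_rotate_shift = 0.3, p_flip = 0.5,
                                p_noise_blur = 0.5, max_angle = 15,
                                max_shift = 0.1, noise_sd = 0.02) {
  p <- c(p_rotate_shift, p_flip, p_noise_blur)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  structure(list(p_rotate_shift = p_rotate_shift, p_flip = p_flip,
                 p_noise_blur = p_noise_blur, max_angle = max_angle,
                 max_shift = max_shift, noise_sd = noise_sd),
            class = "augmentation_policy")
}

rotate_shift_nn <- function(img, angle_deg, shift_r, shift_c) {
  H <- nrow(img); W <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  dst_r <- as.vector(row(img)) - cr - shift_r
  dst_c <- as.vector(col(img)) - cc - shift_c
  src_r <- round(cos(th) * dst_r - sin(th) * dst_c + cr)
  src_c <- round(sin(th) * dst_r + cos(th) * dst_c + cc)
  ok <- src_r >= 1 & src_r <= H & src_c >= 1 & src_c <= W
  out <- numeric(H * W)
  out[ok] <- img[cbind(src_r[ok], src_c[ok])]
  matrix(out, H, W)
}

#' Apply stochastic augmentation to a grayscale frame
#'
#' Each transform of the [augmentation_policy()] is applied independently
#' with its configured probability. Deterministic for a given seed; the
#' caller's RNG state is left untouched.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param policy an [augmentation_policy()].
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @return augmented matrix, same shape, values in \[0, 1\].
#' @export
augment_image <- function(img, policy = augmentation_policy(), seed = NULL) {
  stopifnot(inherits(policy, "augmentation_policy"), is.matrix(img))
  with_local_seed(seed, {
    x <- img
    if (stats::runif(1) < policy$p_rotate_shift) {
      ang <- stats::runif(1, -policy$max_angle, policy$max_angle)
      sh <- stats::runif(2, -policy$max_shift, policy$max_shift) * dim(img)
      x <- rotate_shift_nn(x, ang, sh[1], sh[2])
    }
    if (stats::runif(1) < policy$p_flip) {
      x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    }
    if (stats::runif(1) < policy$p_noise_blur) {
      if (stats::runif(1) < 0.5) {
        x <- x + matrix(stats::rnorm(length(x), 0, policy$noise_sd),
                        nrow(x), ncol(x))
      } else {
        x <- box_blur3(x)
      }
    }
    pmin(pmax(x, 0), 1)
  })
}

# 3x3 box blur with edge replication
box_blur3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  p <- img[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  acc <- matrix(0, H, W)
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + p[di + seq_len(H), dj + seq_len(W)]
  }
  acc / 9
}
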