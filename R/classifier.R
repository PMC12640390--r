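#' Classifier model configuration
#'
#' Two architectures are scaffolded. The image-only variant is a
#' convolutional feature extractor with a single classification head. The
#' fused variant shares the extractor, projects its feature vector to
#' `fusion_hidden`, combines it with a linearly embedded one-hot time
#' vector (84 two-hour windows) through a single attention-based encoder
#' layer, and emits logits from two heads: head 1 directly from the
#' extractor features (keeps gradient flowing into the backbone and stops
#' the model overfitting on time alone), head 2 from the fused
#' representation (used at inference).
#'
#' The `"tiny"` backbone (two small convolution blocks) is the default and
#' trains at desk scale on synthetic images; `"reference"` selects a
#' deeper, wider stack at 380 px input and 512-wide fusion, standing in
#' for an EfficientNet-class extractor at a scale this package does not
#' exercise in tests.
#'
#' @param backbone `"tiny"` or `"reference"`.
#' @param image_size input side length; defaults 32 (tiny) / 380
#'   (reference).
#' @param num_classes number of output classes (>= 2), default 17.
#' @param fused add the time-fusion branch and second head.
#' @param conv_channels output channels of the successive 3x3 conv +
#'   pool blocks.
#' @param feature_dim width of the extracted feature vector.
#' @param fusion_hidden,fusion_heads,fusion_layers encoder layer size;
#'   defaults 32/4/1 (tiny), 512/4/1 (reference). Only one encoder layer
#'   is supported.
#' @param time_vector_length length of the one-hot time input (84).
#' @return list of class `model_config`.
#' @export
model_config <- function(backbone = c("tiny", "reference"),
                         image_size = NULL, num_classes = 17L,
                         fused = FALSE, conv_channels = NULL,
                         feature_dim = NULL, fusion_hidden = NULL,
                         fusion_heads = 4L, fusion_layers = 1L,
                         time_vector_length = 84L) {
  backbone <- match.arg(backbone)
  defaults <- switch(backbone,
    tiny = list(image_size = 32L, conv_channels = c(8L, 16L),
                feature_dim = 64L, fusion_hidden = 32L),
    reference = list(image_size = 380L,
                     conv_channels = c(32L, 64L, 128L, 256L),
                     feature_dim = 512L, fusion_hidden = 512L))
  image_size <- as.integer(image_size %||% defaults$image_size)
  conv_channels <- as.integer(conv_channels %||% defaults$conv_channels)
  feature_dim <- as.integer(feature_dim %||% defaults$feature_dim)
  fusion_hidden <- as.integer(fusion_hidden %||% defaults$fusion_hidden)
  if (image_size <= 0 || num_classes < 2L) {
    stop("image_size must be positive and num_classes >= 2", call. = FALSE)
  }
  if (image_size %% 2L^length(conv_channels) != 0L) {
    stop("image_size must be divisible by 2^length(conv_channels)",
         call. = FALSE)
  }
  if (fused && fusion_hidden %% fusion_heads != 0L) {
    stop("fusion_hidden must be divisible by fusion_heads", call. = FALSE)
  }
  if (fusion_layers != 1L) {
    stop("only a single encoder layer is supported", call. = FALSE)
  }
  structure(list(backbone = backbone, image_size = image_size,
                 num_classes = as.integer(num_classes), fused = fused,
                 conv_channels = conv_channels, feature_dim = feature_dim,
                 fusion_hidden = fusion_hidden,
                 fusion_heads = as.integer(fusion_heads),
                 fusion_layers = 1L,
                 time_vector_length = as.integer(time_vector_length)),
            class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training configuration
#'
#' Adam optimisation with an initial learning rate of 0.001, weighted
#' cross-entropy loss, and learning-rate reduction on a validation-loss
#' plateau (patience 3 epochs, factor 0.1, floor 1e-6 -- the schedule is
#' monotone non-increasing). Up to `epochs` epochs are run (50 by
#' default); the checkpoint with the best validation loss is returned.
#'
#' @param epochs maximum training epochs.
#' @param initial_lr initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param patience epochs without validation improvement before the
#'   learning rate is reduced.
#' @param factor multiplicative learning-rate reduction.
#' @param min_lr learning-rate floor.
#' @param class_weighting `"inverse_frequency"` (default) or `"none"`.
#' @param augment optional [augmentation_policy()] applied to training
#'   images each epoch (`NULL` = off).
#' @param seed RNG seed controlling initialisation, shuffling and
#'   augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, initial_lr = 0.001, batch_size = 16L,
                         patience = 3L, factor = 0.1, min_lr = 1e-6,
                         class_weighting = c("inverse_frequency", "none"),
                         augment = NULL, seed = 1L) {
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), factor = factor,
                 min_lr = min_lr,
                 class_weighting = match.arg(class_weighting),
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Build a classifier model
#'
#' Initialises the parameters of the architecture described by
#' [model_config()] (He initialisation for convolutional and dense
#' weights, Glorot for the attention projections). Weights are random;
#' ImageNet-pretrained initialisation is not bundled.
#'
#' @param config a [model_config()].
#' @param classes optional character vector of class names (length
#'   `num_classes`).
#' @param seed RNG seed for initialisation.
#' @return list of class `stage_model` with elements `config`, `classes`
#'   and `params`.
#' @export
build_model <- function(config, classes = NULL, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(classes)) {
    classes <- if (config$num_classes == 17L) stage_levels()
               else paste0("class", seq_len(config$num_classes))
  }
  if (length(classes) != config$num_classes) {
    stop("classes must have length num_classes", call. = FALSE)
  }
  he <- function(n_out, n_in) {
    matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
  }
  glorot <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))),
           n_in, n_out)
  }
  with_local_seed(seed, {
    p <- list()
    c_in <- 3L
    for (i in seq_along(config$conv_channels)) {
      c_out <- config$conv_channels[i]
      p[[paste0("conv", i, "_W")]] <- he(c_out, 9L * c_in)
      p[[paste0("conv", i, "_b")]] <- numeric(c_out)
      c_in <- c_out
    }
    side <- config$image_size %/% 2L^length(config$conv_channels)
    flat <- side * side * c_in
    p$fc_W <- t(he(config$feature_dim, flat))      # flat x feature_dim
    p$fc_b <- numeric(config$feature_dim)
    p$head1_W <- t(he(config$num_classes, config$feature_dim))
    p$head1_b <- numeric(config$num_classes)
    if (config$fused) {
      Hf <- config$fusion_hidden
      p$proj_W <- t(he(Hf, config$feature_dim))
      p$proj_b <- numeric(Hf)
      p$time_W <- t(he(Hf, config$time_vector_length))
      p$time_b <- numeric(Hf)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[nm]] <- glorot(Hf, Hf)
      p$W1 <- glorot(Hf, 2L * Hf)
      p$b1 <- numeric(2L * Hf)
      p$W2 <- glorot(2L * Hf, Hf)
      p$b2 <- numeric(Hf)
      p$head2_W <- t(he(config$num_classes, Hf))
      p$head2_b <- numeric(config$num_classes)
    }
    structure(list(config = config, classes = classes, params = p),
              class = "stage_model")
  })
}

#' @export
print.stage_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<stage_model> %s backbone, %d classes, %s, %d parameters\n",
              x$config$backbone, x$config$num_classes,
              if (x$config$fused) "image+time fused (2 heads)"
              else "image-only (1 head)", np))
  invisible(x)
}

# forward pass for one preprocessed sample; returns logits and cache
model_forward <- function(model, x, tvec = NULL) {
  cfg <- model$config
  p <- model$params
  caches <- list()
  c_in <- 3L
  side <- cfg$image_size
  h <- x
  for (i in seq_along(cfg$conv_channels)) {
    ii <- im2col_cache(side, c_in)
    cv <- conv_forward(h, p[[paste0("conv", i, "_W")]],
                       p[[paste0("conv", i, "_b")]], ii)
    a <- pmax(cv$y, 0)
    mp <- maxpool_forward(a)
    caches[[i]] <- list(ii = ii, conv = cv, relu_in = cv$y, pool = mp)
    h <- mp$y
    side <- side %/% 2L
    c_in <- cfg$conv_channels[i]
  }
  flat <- as.vector(h)
  pre_f <- drop(flat %*% p$fc_W) + p$fc_b
  f <- pmax(pre_f, 0)
  logits1 <- drop(f %*% p$head1_W) + p$head1_b
  out <- list(logits1 = logits1, logits2 = NULL,
              cache = list(convs = caches, flat = flat, pre_f = pre_f, f = f))
  if (cfg$fused) {
    if (is.null(tvec)) stop("fused model requires a time vector",
                            call. = FALSE)
    img_tok <- drop(f %*% p$proj_W) + p$proj_b
    time_tok <- drop(tvec %*% p$time_W) + p$time_b
    Tm <- rbind(img_tok, time_tok)
    enc <- encoder_forward(Tm, p, cfg$fusion_heads)
    out$logits2 <- drop(enc$T2[1L, ] %*% p$head2_W) + p$head2_b
    out$cache$tvec <- tvec
    out$cache$Tm <- Tm
    out$cache$enc <- enc
  }
  out
}

# cached construction of im2col index tables (memoised per geometry)
im2col_cache <- local({
  store <- new.env(parent = emptyenv())
  function(side, C) {
    key <- paste0(side, "x", C)
    if (is.null(store[[key]])) store[[key]] <- im2col_indices(side, side, C)
    store[[key]]
  }
})

# backward pass; dlogits1/dlogits2 may be NULL to probe a single head
model_backward <- function(model, fwd, dlogits1, dlogits2 = NULL) {
  cfg <- model$config
  p <- model$params
  ca <- fwd$cache
  g <- lapply(p, function(q) q * 0)
  df <- numeric(cfg$feature_dim)
  if (!is.null(dlogits1)) {
    g$head1_W <- outer(ca$f, dlogits1)
    g$head1_b <- dlogits1
    df <- df + drop(p$head1_W %*% dlogits1)
  }
  if (!is.null(dlogits2)) {
    t2 <- ca$enc$T2[1L, ]
    g$head2_W <- outer(t2, dlogits2)
    g$head2_b <- dlogits2
    dT2 <- matrix(0, 2L, cfg$fusion_hidden)
    dT2[1L, ] <- drop(p$head2_W %*% dlogits2)
    eb <- encoder_backward(dT2, p, ca$enc$cache, cfg$fusion_heads)
    for (nm in names(eb$grads)) g[[nm]] <- g[[nm]] + eb$grads[[nm]]
    d_img_tok <- eb$dTm[1L, ]
    d_time_tok <- eb$dTm[2L, ]
    g$proj_W <- g$proj_W + outer(ca$f, d_img_tok)
    g$proj_b <- g$proj_b + d_img_tok
    g$time_W <- g$time_W + outer(as.numeric(ca$tvec), d_time_tok)
    g$time_b <- g$time_b + d_time_tok
    df <- df + drop(p$proj_W %*% d_img_tok)
  }
  dpre_f <- df * (ca$pre_f > 0)
  g$fc_W <- g$fc_W + outer(ca$flat, dpre_f)
  g$fc_b <- g$fc_b + dpre_f
  dflat <- drop(p$fc_W %*% dpre_f)
  nconv <- length(cfg$conv_channels)
  last <- ca$convs[[nconv]]
  dh <- array(dflat, dim(last$pool$y))
  for (i in rev(seq_len(nconv))) {
    ci <- ca$convs[[i]]
    da <- maxpool_backward(dh, ci$pool)
    dy <- da * (ci$relu_in > 0)
    cb <- conv_backward(dy, model$params[[paste0("conv", i, "_W")]],
                        ci$conv, ci$ii)
    g[[paste0("conv", i, "_W")]] <- g[[paste0("conv", i, "_W")]] + cb$dW
    g[[paste0("conv", i, "_b")]] <- g[[paste0("conv", i, "_b")]] + cb$db
    dh <- cb$dx
  }
  g
}

#' Predict class probabilities for a batch of frames
#'
#' Runs the forward pass on preprocessed frames. The fused model predicts
#' from head 2 (the fused representation); the image-only model from its
#' single head.
#'
#' @param model a trained [build_model()] object.
#' @param images list of preprocessed arrays (see [preprocess_image()]).
#' @param minutes numeric vector of acquisition times (required for the
#'   fused model).
#' @return probability matrix (frames x classes), columns named by class.
#' @export
predict_classifier <- function(model, images, minutes = NULL) {
  stopifnot(inherits(model, "stage_model"))
  cfg <- model$config
  if (cfg$fused && is.null(minutes)) {
    stop("fused model requires minutes since fertilisation", call. = FALSE)
  }
  tmat <- if (cfg$fused) encode_time(minutes) else NULL
  if (cfg$fused && is.null(dim(tmat))) tmat <- matrix(tmat, nrow = 1L)
  probs <- t(vapply(seq_along(images), function(i) {
    fwd <- model_forward(model, images[[i]],
                         if (cfg$fused) tmat[i, ] else NULL)
    z <- if (cfg$fused) fwd$logits2 else fwd$logits1
    e <- exp(z - max(z))
    e / sum(e)
  }, numeric(cfg$num_classes)))
  colnames(probs) <- model$classes
  probs
}

#' Drop transition-adjacent frames from a training annotation table
#'
#' Stage boundaries are the most subjective part of manual annotation, so
#' frames within `margin` frames of any label change are removed from the
#' training data (`margin` frames ending at the old label and `margin`
#' starting the new one, i.e. 2 x `margin` frames per boundary). Intended
#' for training sets only; evaluation uses all frames.
#'
#' @param annotations data.frame with columns `video_id`, `frame_index`
#'   and `label`, ordered by frame within each video.
#' @param margin frames to drop on each side of a boundary (default 2;
#'   0 is the identity).
#' @return filtered data.frame.
#' @export
exclude_transition_frames <- function(annotations, margin = 2L) {
  stopifnot(all(c("video_id", "label") %in% names(annotations)))
  margin <- as.integer(margin)
  if (margin == 0L) return(annotations)
  keep <- unlist(lapply(split(seq_len(nrow(annotations)),
                              annotations$video_id), function(ix) {
    lab <- as.character(annotations$label[ix])
    n <- length(lab)
    drop <- rep(FALSE, n)
    bounds <- which(lab[-1L] != lab[-n]) + 1L   # first frame of each new run
    for (b in bounds) {
      lo <- max(1L, b - margin)
      hi <- min(n, b + margin - 1L)
      drop[lo:hi] <- TRUE
    }
    ix[!drop]
  }), use.names = FALSE)
  annotations[sort(keep), , drop = FALSE]
}

#' Train a stage classifier
#'
#' Minibatch Adam on the summed two-head weighted cross-entropy (fused
#' model) or the single-head loss (image-only). The learning rate is
#' reduced on a validation-loss plateau and the best-validation
#' checkpoint is returned. Deterministic for a given
#' `train_config()$seed`.
#'
#' @param dataset list with elements `images` (list of grayscale matrices
#'   in \[0, 1\]), `minutes` (numeric), `labels` (factor) and `split`
#'   (character/factor with values `"train"` and `"val"`).
#' @param config a [model_config()].
#' @param train a [train_config()].
#' @return list with `model` (best checkpoint), `history` (data.frame:
#'   epoch, lr, train_loss, val_loss, val_accuracy) and `best_epoch`.
#' @export
train_classifier <- function(dataset, config, train = train_config()) {
  stopifnot(inherits(config, "model_config"), inherits(train, "train_config"))
  split <- as.character(dataset$split)
  labels <- dataset$labels
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != config$num_classes) {
    stop("number of label levels must equal num_classes", call. = FALSE)
  }
  itr <- which(split == "train")
  iva <- which(split == "val")
  if (length(itr) == 0L || length(iva) == 0L) {
    stop("dataset must contain non-empty train and val splits", call. = FALSE)
  }
  tr_counts <- table(labels[itr])
  weights <- rep(1, nlevels(labels))
  if (train$class_weighting == "inverse_frequency") {
    present <- tr_counts > 0
    if (!all(present)) {
      warning("classes absent from the training split get weight 0: ",
              paste(names(tr_counts)[!present], collapse = ", "),
              call. = FALSE)
    }
    weights[present] <- inverse_class_frequency_weights(
      as.numeric(tr_counts[present]))
    weights[!present] <- 0
  }
  pre <- lapply(dataset$images, preprocess_image,
                image_size = config$image_size)
  tmat <- if (config$fused) {
    m <- encode_time(dataset$minutes)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    m
  } else NULL
  y <- as.integer(labels)

  eval_split <- function(model, ix) {
    loss <- 0; wsum <- 0; correct <- 0
    for (i in ix) {
      fwd <- model_forward(model, pre[[i]],
                           if (config$fused) tmat[i, ] else NULL)
      z1 <- matrix(fwd$logits1, 1L)
      z2 <- if (config$fused) matrix(fwd$logits2, 1L) else NULL
      w <- weights[y[i]]
      loss <- loss + w * combined_loss(z1, z2, y[i], class_weights = weights)
      wsum <- wsum + w
      zp <- if (config$fused) fwd$logits2 else fwd$logits1
      correct <- correct + (which.max(zp) == y[i])
    }
    c(loss = loss / wsum, acc = correct / length(ix))
  }

  with_local_seed(train$seed, {
    model <- build_model(config, classes = levels(labels),
                         seed = sample.int(.Machine$integer.max, 1L))
    history <- data.frame(epoch = integer(), lr = numeric(),
                          train_loss = numeric(), val_loss = numeric(),
                          val_accuracy = numeric())
    if (train$epochs == 0L) {
      list(model = model, history = history, best_epoch = NA_integer_)
    } else {
      state <- adam_init(model$params)
      lr <- train$initial_lr
      best_loss <- Inf; best_params <- model$params
      best_epoch <- NA_integer_
      stall <- 0L
      for (epoch in seq_len(train$epochs)) {
        ord <- sample(itr)
        ep_loss <- 0; ep_w <- 0
        for (start in seq(1L, length(ord), by = train$batch_size)) {
          batch <- ord[start:min(start + train$batch_size - 1L, length(ord))]
          grads <- NULL
          bw <- 0
          for (i in batch) {
            if (!is.null(train$augment)) {
              xi <- preprocess_image(
                augment_image(dataset$images[[i]], train$augment),
                image_size = config$image_size)
            } else xi <- pre[[i]]
            fwd <- model_forward(model, xi,
                                 if (config$fused) tmat[i, ] else NULL)
            w <- weights[y[i]]
            ce1 <- weighted_ce(matrix(fwd$logits1, 1L), y[i], weights)
            d1 <- drop(ce1$grad) * w
            loss_i <- ce1$loss * w
            d2 <- NULL
            if (config$fused) {
              ce2 <- weighted_ce(matrix(fwd$logits2, 1L), y[i], weights)
              d2 <- drop(ce2$grad) * w
              loss_i <- loss_i + ce2$loss * w
            }
            gi <- model_backward(model, fwd, d1, d2)
            grads <- if (is.null(grads)) gi
                     else mapply(`+`, grads, gi, SIMPLIFY = FALSE)
            bw <- bw + w
            ep_loss <- ep_loss + loss_i
            ep_w <- ep_w + w
          }
          grads <- lapply(grads, `/`, bw)
          upd <- adam_step(model$params, grads, state, lr)
          model$params <- upd$params
          state <- upd$state
        }
        ev <- eval_split(model, iva)
        history <- rbind(history, data.frame(
          epoch = epoch, lr = lr, train_loss = ep_loss / ep_w,
          val_loss = unname(ev["loss"]), val_accuracy = unname(ev["acc"]),
          row.names = NULL))
        if (ev["loss"] < best_loss - 1e-4) {
          best_loss <- ev["loss"]; best_params <- model$params
          best_epoch <- epoch; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= train$patience && lr > train$min_lr) {
            lr <- max(lr * train$factor, train$min_lr)
            stall <- 0L
          }
        }
      }
      model$params <- best_params
      list(model = model, history = history, best_epoch = best_epoch)
    }
  })
}
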