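test_that("preprocessing yields a standardised 3-channel array", {
  img <- matrix(0.5, 48, 48)
  out <- preprocess_image(img, image_size = 64L, apply_clahe = FALSE)
  expect_identical(dim(out), c(64L, 64L, 3L))
  means <- c(0.485, 0.456, 0.406); stds <- c(0.229, 0.224, 0.225)
  for (k in 1:3) {
    expect_equal(unique(as.vector(out[, , k])), (0.5 - means[k]) / stds[k])
  }
  # 8-bit inputs are rescaled
  out255 <- preprocess_image(matrix(128, 8, 8), 8L, apply_clahe = FALSE)
  expect_equal(out255[1, 1, 1], (128 / 255 - means[1]) / stds[1])
  expect_error(preprocess_image(array(0.5, c(8, 8, 3))), "single-channel")
})

test_that("CLAHE stretches low-contrast local texture", {
  # faint texture on a mid-gray background: local equalisation should
  # amplify it strongly (a pure smooth gradient is the wrong probe --
  # adaptive equalisation removes global illumination trends)
  g <- expand.grid(i = 1:64, j = 1:64)
  img <- matrix(0.5 + 0.02 * sin(g$i / 2) * cos(g$j / 3), 64, 64)
  out <- clahe(img)
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
  expect_gt(sd(out), 2 * sd(img))
})

test_that("augmentation is seeded, probability-gated and involutive flips", {
  img <- render_frame("t4", size = 32L, seed = 1)
  none <- augmentation_policy(p_rotate_shift = 0, p_flip = 0,
                              p_noise_blur = 0)
  expect_identical(augment_image(img, none, seed = 4), img)
  fl <- augmentation_policy(p_rotate_shift = 0, p_flip = 1,
                            p_noise_blur = 0)
  expect_identical(augment_image(augment_image(img, fl, 1), fl, 2), img)
  pol <- augmentation_policy()
  expect_identical(augment_image(img, pol, seed = 99),
                   augment_image(img, pol, seed = 99))
  # flip frequency across seeds is binomial around p_flip = 0.5
  n <- 400L
  fl_half <- augmentation_policy(p_rotate_shift = 0, p_flip = 0.5,
                                 p_noise_blur = 0)
  flipped <- vapply(seq_len(n), function(s) {
    !identical(augment_image(img, fl_half, seed = s), img)
  }, logical(1))
  expect_lt(abs(mean(flipped) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("combined_loss has its closed-form values", {
  k <- 17L
  z <- matrix(0, 3, k)
  expect_equal(combined_loss(z, z, c(1L, 5L, 17L)), 2 * log(k))
  # identical heads double the single-head loss
  set.seed(1)
  z2 <- matrix(rnorm(3 * k), 3, k)
  expect_equal(combined_loss(z2, z2, c(2L, 3L, 4L)),
               2 * combined_loss(z2, NULL, c(2L, 3L, 4L)))
  # a certain, correct model drives the loss to zero
  zbig <- matrix(-50, 1, k); zbig[1, 7] <- 50
  expect_lt(combined_loss(zbig, zbig, 7L), 1e-12)
  # unit weights reduce to the unweighted mean
  w <- inverse_class_frequency_weights(c(10, 10, 10))
  z3 <- matrix(rnorm(3 * 3), 3, 3)
  expect_equal(combined_loss(z3, NULL, c(1L, 2L, 3L), w),
               combined_loss(z3, NULL, c(1L, 2L, 3L)))
  expect_error(combined_loss(z, z[, 1:3], 1L), "identical shape")
})

test_that("model forward pass honours the head contract", {
  cfg <- model_config("tiny", image_size = 16L, num_classes = 5L,
                      conv_channels = c(4L, 8L), feature_dim = 16L)
  m <- build_model(cfg, seed = 1)
  x <- preprocess_image(matrix(runif(256), 16, 16), 16L)
  fwd <- asNamespace("embryostage")$model_forward(m, x)
  expect_length(fwd$logits1, 5L)
  expect_null(fwd$logits2)
  cfgf <- model_config("tiny", image_size = 16L, num_classes = 5L,
                       conv_channels = c(4L, 8L), feature_dim = 16L,
                       fused = TRUE, fusion_hidden = 16L)
  mf <- build_model(cfgf, seed = 1)
  fwdf <- asNamespace("embryostage")$model_forward(mf, x, encode_time(300))
  expect_length(fwdf$logits1, 5L)
  expect_length(fwdf$logits2, 5L)
  probs <- predict_classifier(mf, list(x, x), minutes = c(100, 5000))
  expect_identical(dim(probs), c(2L, 5L))
  expect_equal(unname(rowSums(probs)), c(1, 1))
  expect_error(predict_classifier(mf, list(x)), "minutes")
})

test_that("analytic gradients match finite differences in the fused model", {
  ns <- asNamespace("embryostage")
  cfg <- model_config("tiny", image_size = 8L, num_classes = 3L,
                      fused = TRUE, conv_channels = c(2L, 3L),
                      feature_dim = 5L, fusion_hidden = 8L,
                      fusion_heads = 2L)
  m <- build_model(cfg, classes = c("a", "b", "c"), seed = 3)
  set.seed(9)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  tv <- encode_time(150)
  y <- 2L
  w <- c(1.3, 0.8, 1.1)
  loss_fn <- function(mm) {
    f <- ns$model_forward(mm, x, tv)
    ns$weighted_ce(matrix(f$logits1, 1), y, w)$loss +
      ns$weighted_ce(matrix(f$logits2, 1), y, w)$loss
  }
  f <- ns$model_forward(m, x, tv)
  d1 <- drop(ns$weighted_ce(matrix(f$logits1, 1), y, w)$grad)
  d2 <- drop(ns$weighted_ce(matrix(f$logits2, 1), y, w)$grad)
  g <- ns$model_backward(m, f, d1, d2)
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      up <- m; up$params[[nm]][i] <- p[i] + eps
      dn <- m; dn$params[[nm]][i] <- p[i] - eps
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("both heads propagate gradient into the backbone", {
  ns <- asNamespace("embryostage")
  cfg <- model_config("tiny", image_size = 8L, num_classes = 3L,
                      fused = TRUE, conv_channels = c(2L, 3L),
                      feature_dim = 5L, fusion_hidden = 8L,
                      fusion_heads = 2L)
  m <- build_model(cfg, classes = c("a", "b", "c"), seed = 3)
  set.seed(10)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  f <- ns$model_forward(m, x, encode_time(150))
  d <- rep(1 / 3, 3); d[2] <- d[2] - 1
  g1 <- ns$model_backward(m, f, d, NULL)
  g2 <- ns$model_backward(m, f, NULL, d)
  expect_gt(sum(abs(g1$conv1_W)), 0)
  expect_gt(sum(abs(g2$conv1_W)), 0)
})

test_that("transition-adjacent frames are dropped from training data", {
  ann <- data.frame(video_id = "v", frame_index = 0:9,
                    label = rep(c("t2", "t3"), each = 5))
  out <- exclude_transition_frames(ann, margin = 2L)
  expect_identical(nrow(out), 6L)
  expect_identical(out$frame_index, c(0:2, 7:9))
  expect_identical(exclude_transition_frames(ann, margin = 0L), ann)
  const <- data.frame(video_id = "v", frame_index = 0:5, label = "t4")
  expect_identical(exclude_transition_frames(const), const)
  # margins never bleed across videos
  two <- rbind(ann, transform(ann, video_id = "w"))
  expect_identical(nrow(exclude_transition_frames(two)), 12L)
})

test_that("training runs, improves the loss and honours epochs = 0", {
  ds <- render_stage_dataset(classes = c("tPNf", "t4", "Empty"),
                             n_per_class = 25L, size = 32L, seed = 2)
  cfg <- model_config("tiny", num_classes = 3L)
  fit0 <- train_classifier(ds, cfg, train_config(epochs = 0L, seed = 1))
  expect_identical(nrow(fit0$history), 0L)
  expect_s3_class(fit0$model, "stage_model")
  fit <- train_classifier(ds, cfg, train_config(epochs = 4L, seed = 1))
  expect_identical(nrow(fit$history), 4L)
  expect_lt(fit$history$train_loss[4], fit$history$train_loss[1])
  expect_true(all(diff(fit$history$lr) <= 0))
})

test_that("a constant time vector does not harm the fused model", {
  ds <- render_stage_dataset(classes = c("tPNf", "t4", "Empty"),
                             n_per_class = 30L, size = 32L, seed = 4)
  ds$minutes <- rep(1000, length(ds$minutes))   # time carries no signal
  cfg1 <- model_config("tiny", num_classes = 3L)
  cfg2 <- model_config("tiny", num_classes = 3L, fused = TRUE)
  tc <- train_config(epochs = 6L, seed = 2)
  acc1 <- max(train_classifier(ds, cfg1, tc)$history$val_accuracy)
  acc2 <- max(train_classifier(ds, cfg2, tc)$history$val_accuracy)
  expect_gte(acc2, acc1 - 0.05)
})
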