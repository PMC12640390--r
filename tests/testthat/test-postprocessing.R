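test_that("prediction_sequence validates its invariants", {
  p <- matrix(1 / 17, 2, 17, dimnames = list(NULL, stage_levels()))
  s <- prediction_sequence("v", 0:1, c(0, 20), p)
  expect_s3_class(s, "prediction_sequence")
  # argmax ties break toward the lower ordinal
  expect_identical(as.character(s$top_label), c("tPB2", "tPB2"))
  expect_equal(s$confidence, rep(1 / 17, 2))
  expect_error(prediction_sequence("v", 0:1, c(20, 0), p), "increasing")
  expect_error(prediction_sequence("v", c(1, 1), c(0, 20), p), "increasing")
  bad <- p; bad[1, 1] <- 0.5
  expect_error(prediction_sequence("v", 0:1, c(0, 20), bad), "sum to 1")
  expect_error(prediction_sequence("v", integer(0), numeric(0),
                                   p[0, , drop = FALSE]), "at least one")
})

test_that("low-confidence substitution uses the latest confident label", {
  s <- make_seq(c("t2", "t3", "t3"), conf = c(0.95, 0.60, 0.90))
  expect_identical(as.character(substitute_low_confidence(s)),
                   c("t2", "t2", "t3"))
  # identity when everything clears the threshold
  s2 <- make_seq(c("t2", "t3", "t4"), conf = 0.9)
  expect_identical(as.character(substitute_low_confidence(s2)),
                   c("t2", "t3", "t4"))
  # leading low-confidence frames keep their own label
  s3 <- make_seq(c("t3", "t2"), conf = c(0.50, 0.95))
  expect_identical(as.character(substitute_low_confidence(s3)),
                   c("t3", "t2"))
  # threshold is a strict inequality
  s4 <- make_seq(c("t2", "t3"), conf = c(0.9, 0.8))
  expect_identical(as.character(substitute_low_confidence(s4, 0.8)),
                   c("t2", "t2"))
  expect_error(substitute_low_confidence(s4, 0), "in \\(0, 1\\]")
})

test_that("change detection and grouping follow the running-sum scheme", {
  expect_identical(compute_changes(c("t2", "t2", "t3", "t2", "t2")),
                   c(0L, 0L, 1L, 1L, 0L))
  expect_identical(compute_changes(c("t4", "t4", "t4")), c(0L, 0L, 0L))
  expect_identical(compute_changes(c("t2", "t3")), c(0L, 1L))
  expect_identical(assign_groups(c(0L, 0L, 1L, 1L, 0L)),
                   c(0L, 0L, 1L, 2L, 2L))
  expect_identical(assign_groups(c(0L, 1L, 1L, 1L)), 0:3)
  expect_error(compute_changes(character(0)), "empty")
  # properties over random sequences
  set.seed(42)
  for (i in 1:25) {
    lab <- random_label_seq(sample(2:40, 1))
    g <- assign_groups(compute_changes(lab))
    expect_true(all(diff(g) %in% 0:1))
    expect_identical(g[length(g)] + 1L, length(rle(lab)$lengths))
  }
})

test_that("interruptive groups are identified per class", {
  ig <- find_interruptive_groups(c("t2", "t2", "t3", "t2", "t2"))
  expect_identical(ig$t2, c("1" = 1L))
  expect_identical(unname(ig$t3), integer(0))
  ig2 <- find_interruptive_groups(c("t2", "t2", "t3", "t3"))
  expect_true(all(lengths(ig2) == 0L))
  ig3 <- find_interruptive_groups(c("t4", "t5", "t4", "t5", "t4"))
  expect_identical(names(ig3$t4), c("1", "3"))
  expect_identical(names(ig3$t5), "2")
})

test_that("remove_interruptions matches the worked examples", {
  expect_identical(
    as.character(remove_interruptions(c("t2", "t2", "t3", "t2", "t2"))),
    rep("t2", 5))
  mono <- c("t2", "t2", "t3", "t3", "t4", "t4")
  expect_identical(as.character(remove_interruptions(mono)), mono)
  expect_identical(
    as.character(remove_interruptions(
      c(rep("t4", 3), "t5", rep("t4", 3), rep("t5", 3)))),
    c(rep("t4", 7), rep("t5", 3)))
})

test_that("the length guard protects long runs from stray early-class flips", {
  # one isolated t2 flip deep inside a long t3 run: without the guard the
  # whole span between the true t2 run and the flip is relabelled t2,
  # destroying the t3 onset
  lab <- c(rep("t2", 5), rep("t3", 10), "t2", rep("t3", 10))
  guarded <- as.character(remove_interruptions(lab))
  expect_identical(guarded, c(rep("t2", 5), rep("t3", 21)))
  unguarded <- as.character(remove_interruptions(lab, length_guard = FALSE))
  expect_identical(unguarded, c(rep("t2", 16), rep("t3", 10)))
})

test_that("smoothing is identity on clean input and removes spikes", {
  clean <- make_seq(rep(c("t2", "t3", "t4"), each = 6), conf = 1)
  expect_identical(as.character(smooth_predictions(clean)),
                   as.character(clean$top_label))
  spike <- make_seq(c(rep("t8", 5), "t9+", rep("t8", 5)), conf = 0.95)
  expect_identical(as.character(smooth_predictions(spike)), rep("t8", 11))
  # genuine reversions are representable (no monotonicity constraint)
  rev_seq <- make_seq(c(rep("t3", 20), rep("t2", 20)), conf = 0.95)
  expect_identical(as.character(smooth_predictions(rev_seq)),
                   c(rep("t3", 20), rep("t2", 20)))
})

test_that("smoothing is idempotent and length preserving", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    s <- make_seq(random_label_seq(n, c("t2", "t3", "t4", "t5")),
                  conf = runif(n, 0.4, 1))
    out <- smooth_predictions(s)
    expect_length(out, n)
    sub <- substitute_low_confidence(s)
    expect_true(all(as.character(out) %in% as.character(sub)))
    again <- smooth_predictions(make_seq(as.character(out), conf = 1))
    expect_identical(as.character(again), as.character(out))
  }
})

test_that("mutually interruptive patterns terminate (regression)", {
  # a detached middle run alternately claimed by t4 and t6 cycled forever
  # before absorption required adjacency to a flanking same-class run
  lab <- c("t4", "t4", "t3", "t3", "t4", "t6", "t6", "t2", "t3", "t4",
           "t4", "t4", "t4", rep("t2", 9), "t4", "t4", "t2", "t2", "t2",
           "t5", "t3", rep("t6", 8), "t4", "t4", "t4")
  out <- remove_interruptions(lab)
  expect_length(out, length(lab))
  expect_identical(as.character(out), oracle_remove_interruptions(lab))
})

test_that("remove_interruptions agrees with the naive oracle on random data", {
  set.seed(11)
  for (i in 1:200) {
    lab <- random_label_seq(sample(1:12, 1))
    expect_identical(as.character(remove_interruptions(lab)),
                     oracle_remove_interruptions(lab))
    expect_identical(
      as.character(remove_interruptions(lab, length_guard = FALSE)),
      oracle_remove_interruptions(lab, length_guard = FALSE))
  }
})
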