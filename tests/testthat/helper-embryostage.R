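# Shared fixtures and the independent oracle for the interruptive-group
# removal fixpoint. The oracle is deliberately naive: per-frame change and
# group vectors recomputed with explicit loops each pass, no run-length
# encoding, no early bookkeeping -- only the documented policy is shared
# (classes in ascending first occurrence; candidate groups in increasing
# id order; neighbour-length guard; restart after each absorption).

oracle_remove_interruptions <- function(labels, length_guard = TRUE) {
  lab <- as.character(labels)
  n <- length(lab)
  repeat {
    G <- integer(n)
    if (n > 1L) {
      for (i in 2:n) G[i] <- G[i - 1L] + as.integer(lab[i] != lab[i - 1L])
    }
    nruns <- G[n] + 1L
    run_lab <- character(nruns)
    run_len <- integer(nruns)
    for (i in seq_len(n)) {
      g <- G[i] + 1L
      run_lab[g] <- lab[i]
      run_len[g] <- run_len[g] + 1L
    }
    changed <- FALSE
    for (cl in unique(lab)) {
      ids <- which(run_lab == cl)
      if (length(ids) < 2L) next
      for (ig in seq(min(ids), max(ids))) {
        if (run_lab[ig] == cl) next
        left <- max(ids[ids < ig])
        right <- min(ids[ids > ig])
        absorb <- left == ig - 1L || right == ig + 1L
        if (absorb && length_guard) {
          absorb <- run_len[ig] <= min(run_len[left], run_len[right])
        }
        if (absorb) {
          lab[G == (ig - 1L)] <- cl
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  lab
}

# prediction_sequence from plain labels; leak spread over the other classes
# so the argmax stays put for any conf > 0.06
make_seq <- function(labels, conf = 1, video_id = "v",
                     interval = 20) {
  labels <- as.character(labels)
  n <- length(labels)
  conf <- rep_len(conf, n)
  p <- matrix(0, n, 17, dimnames = list(NULL, stage_levels()))
  for (i in seq_len(n)) {
    p[i, ] <- (1 - conf[i]) / 16
    p[i, labels[i]] <- conf[i]
  }
  prediction_sequence(video_id, seq_len(n) - 1L, (seq_len(n) - 1L) * interval,
                      p)
}

# count connected foreground components (4-connectivity) above a threshold
count_blobs <- function(img, threshold = 0.55) {
  fg <- img > threshold
  H <- nrow(fg); W <- ncol(fg)
  seen <- matrix(FALSE, H, W)
  blobs <- 0L
  for (s in which(fg)) {
    if (seen[s]) next
    blobs <- blobs + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (q - 1L) %% H + 1L
      j <- (q - 1L) %/% H + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1L]; jj <- j + d[2L]
        if (ii >= 1L && ii <= H && jj >= 1L && jj <= W) {
          q2 <- (jj - 1L) * H + ii
          if (fg[q2] && !seen[q2]) {
            seen[q2] <- TRUE
            queue <- c(queue, q2)
          }
        }
      }
    }
  }
  blobs
}

# random stage-label sequences over a small alphabet
random_label_seq <- function(n, classes = c("t2", "t3", "t4")) {
  sample(classes, n, replace = TRUE)
}
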