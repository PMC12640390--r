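# Synthetic time-lapse embryos: ground-truth stage timelines, stage-coded
# rendered frames, and noisy per-frame probability vectors that emulate the
# behaviour of a frame-level classifier (uncertainty concentrated around
# stage transitions, occasional isolated flips to an adjacent stage).

# default mean dwell time (hours) in each developmental stage; onsets
# loosely anchored to clinical morphokinetics (t2 ~ day 1, tB ~ day 4.5)
.default_stage_hours <- c(
  tPB2 = 2, tPNa = 21, tPNf = 3, t2 = 11, t3 = 2, t4 = 11, t5 = 1.5,
  t6 = 2, t7 = 2.5, t8 = 11, `t9+` = 17, tM = 15, tSB = 8, tB = 7,
  tEB = 10, tHB = 8
)

#' Synthetic timeline configuration
#'
#' Parameters of the ground-truth generator. Stage dwell times are drawn
#' log-normally around `stage_duration_means` (log-sd
#' `stage_duration_sdlog`), giving positive, right-skewed durations. A
#' fraction of videos arrest at a random stage; a fraction shows one
#' reverse-cleavage episode (a temporary reversion to the previous
#' cleavage stage). Embryos are removed from the well on `removal_day`,
#' after which frames are `Empty`.
#'
#' @param frame_interval_minutes acquisition interval (default 20).
#' @param stage_duration_means named vector of mean dwell hours for the 16
#'   developmental stages.
#' @param stage_duration_sdlog log-scale standard deviation of dwell times.
#' @param reversion_probability per-video probability of one
#'   reverse-cleavage episode (default 0.05).
#' @param reversion_hours range (min, max) of the episode duration.
#' @param arrest_probability chance development halts at a random stage
#'   (default 0.25, mirroring the substantial non-viable fraction of
#'   clinical datasets).
#' @param removal_day day of embryo removal (default 5).
#' @param empty_tail_hours hours of `Empty` frames recorded after removal.
#' @return list of class `timeline_config`.
#' @export
timeline_config <- function(frame_interval_minutes = 20,
                            stage_duration_means = .default_stage_hours,
                            stage_duration_sdlog = 0.25,
                            reversion_probability = 0.05,
                            reversion_hours = c(1, 3),
                            arrest_probability = 0.25,
                            removal_day = 5,
                            empty_tail_hours = 6) {
  stopifnot(frame_interval_minutes > 0, all(stage_duration_means > 0),
            reversion_probability >= 0, reversion_probability <= 1,
            arrest_probability >= 0, arrest_probability <= 1)
  structure(as.list(environment()), class = "timeline_config")
}

#' Sample a ground-truth per-frame stage timeline
#'
#' Stages traverse the developmental order with log-normal dwell times;
#' optionally one reversion episode and/or arrest at a random stage; all
#' frames after the removal day are `Empty`.
#'
#' @param config a [timeline_config()].
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @return data.frame with columns `frame_index` (0-based),
#'   `time_minutes` and `label` (factor over [stage_levels()]).
#' @export
sample_timeline <- function(config = timeline_config(), seed = NULL) {
  stopifnot(inherits(config, "timeline_config"))
  with_local_seed(seed, {
    means <- config$stage_duration_means
    sdl <- config$stage_duration_sdlog
    dur <- stats::rlnorm(length(means), log(means) - sdl^2 / 2, sdl)
    names(dur) <- names(means)
    sched_lab <- names(means)
    sched_dur <- unname(dur)
    # arrest: development halts at a random stage (t2 .. tEB)
    if (stats::runif(1) < config$arrest_probability) {
      arrest_at <- sample(4:15, 1)             # positions in sched (t2..tEB)
      sched_lab <- sched_lab[seq_len(arrest_at)]
      sched_dur <- sched_dur[seq_len(arrest_at)]
      sched_dur[arrest_at] <- Inf              # dwell until removal
    }
    # one reverse-cleavage episode: s -> s-1 -> s inside a cleavage stage
    if (stats::runif(1) < config$reversion_probability) {
      cand <- which(sched_lab %in% c("t3", "t4", "t5", "t6", "t7", "t8") &
                      is.finite(sched_dur))
      if (length(cand)) {
        k <- if (length(cand) == 1L) cand else sample(cand, 1)
        ep <- stats::runif(1, config$reversion_hours[1],
                           config$reversion_hours[2])
        u <- stats::runif(1, 0.3, 0.7)
        d <- sched_dur[k]
        prev <- sched_lab[k - 1L]
        sched_lab <- append(sched_lab, c(prev, sched_lab[k]), after = k)
        sched_dur <- append(sched_dur, c(ep, d * (1 - u)), after = k)
        sched_dur[k] <- d * u
      }
    }
    removal_h <- config$removal_day * 24
    onset <- cumsum(c(0, sched_dur[-length(sched_dur)]))
    keep <- onset < removal_h
    sched_lab <- c(sched_lab[keep], "Empty")
    onset <- c(onset[keep], removal_h)
    end_h <- removal_h + config$empty_tail_hours
    tmin <- seq(0, end_h * 60, by = config$frame_interval_minutes)
    lab <- sched_lab[findInterval(tmin / 60, onset)]
    data.frame(frame_index = seq_along(tmin) - 1L, time_minutes = tmin,
               label = factor(lab, levels = stage_levels()))
  })
}

#' Prediction-noise configuration
#'
#' Emulates the error structure of a frame-level stage classifier.
#' Away from stage boundaries, a frame's argmax flips to an
#' ordinal-adjacent stage with probability `baseline_error_rate`. Around
#' each true boundary the classifier is systematically uncertain:
#' with probability `transition_error_rate` the perceived boundary is
#' displaced by up to `transition_window_frames` frames (displacement
#' magnitude decays geometrically, mirroring how adjacent-stage confusion
#' concentrates immediately at the transition), and the affected frames
#' carry reduced confidence. Confidences never drop below
#' `confidence_floor`.
#'
#' @param baseline_error_rate per-frame adjacent-flip probability away
#'   from boundaries (default 0.05).
#' @param transition_window_frames maximum boundary displacement in
#'   frames (default 3).
#' @param transition_error_rate probability that a boundary is displaced
#'   (default 0.4).
#' @param confidence_floor lower bound on any frame confidence
#'   (default 0.35).
#' @return list of class `noise_config`.
#' @export
noise_config <- function(baseline_error_rate = 0.05,
                         transition_window_frames = 3L,
                         transition_error_rate = 0.4,
                         confidence_floor = 0.35) {
  stopifnot(baseline_error_rate >= 0, baseline_error_rate <= 1,
            transition_error_rate >= baseline_error_rate,
            transition_error_rate <= 1,
            confidence_floor >= 0, confidence_floor < 1)
  structure(list(baseline_error_rate = baseline_error_rate,
                 transition_window_frames = as.integer(transition_window_frames),
                 transition_error_rate = transition_error_rate,
                 confidence_floor = confidence_floor),
            class = "noise_config")
}

# ordinal-adjacent developmental neighbours of a label (Empty leaks to tEB)
.adjacent_labels <- function(label) {
  lev <- stage_levels()
  if (label == "Empty") return("tEB")
  o <- match(label, lev)                      # 1-based, 1..16 here
  neigh <- c(o - 1L, o + 1L)
  lev[neigh[neigh >= 1L & neigh <= 16L]]
}

#' Simulate noisy per-frame classifier predictions
#'
#' Turns a ground-truth timeline into a [prediction_sequence()] under a
#' [noise_config()]. With all noise rates zero the argmax equals the truth
#' everywhere with confidence 1.
#'
#' @param timeline data.frame from [sample_timeline()].
#' @param noise a [noise_config()].
#' @param video_id id recorded in the sequence.
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @return a [prediction_sequence()].
#' @export
simulate_predictions <- function(timeline, noise = noise_config(),
                                 video_id = "sim", seed = NULL) {
  stopifnot(inherits(noise, "noise_config"))
  lev <- stage_levels()
  truth <- as.character(timeline$label)
  n <- length(truth)
  with_local_seed(seed, {
    observed <- truth
    conf <- stats::runif(n, 0.86, 0.995)
    noiseless <- noise$baseline_error_rate == 0 &&
      noise$transition_error_rate == 0
    if (noiseless) conf <- rep(1, n)
    w <- noise$transition_window_frames
    bounds <- which(truth[-1L] != truth[-n]) + 1L   # first frame of new run
    in_window <- rep(FALSE, n)
    if (!noiseless) {
      for (b in bounds) {
        in_window[max(1L, b - w):min(n, b + w - 1L)] <- TRUE
      }
      conf[in_window] <- stats::runif(sum(in_window), 0.82, 0.99)
      # boundary displacement around each transition (Empty boundary is
      # sharp: the empty-well class is trivially recognised)
      lo_conf_min <- max(noise$confidence_floor, 0.51)
      for (bi in seq_along(bounds)) {
        b <- bounds[bi]
        old_lab <- truth[b - 1L]
        new_lab <- truth[b]
        if (old_lab == "Empty" || new_lab == "Empty") next
        if (stats::runif(1) >= noise$transition_error_rate) next
        m <- sample.int(w, 1, prob = 0.1^(seq_len(w) - 1L))
        lo <- if (bi > 1L) bounds[bi - 1L] else 1L
        hi <- (if (bi < length(bounds)) bounds[bi + 1L] else n + 1L) - 1L
        if (stats::runif(1) < 0.5) {
          ix <- b:min(b + m - 1L, hi)                 # boundary seen late
          observed[ix] <- old_lab
        } else {
          ix <- max(b - m, lo):(b - 1L)               # boundary seen early
          observed[ix] <- new_lab
        }
        conf[ix] <- stats::runif(length(ix), lo_conf_min, 0.9)
      }
      # isolated adjacent flips away from boundaries
      flip_ok <- !in_window & truth != "Empty"
      flips <- which(flip_ok & stats::runif(n) < noise$baseline_error_rate)
      for (i in flips) {
        nb <- .adjacent_labels(truth[i])
        observed[i] <- if (length(nb) == 1L) nb else sample(nb, 1)
        conf[i] <- stats::runif(1, max(noise$confidence_floor, 0.51), 0.95)
      }
    }
    probs <- matrix(0, n, 17L, dimnames = list(NULL, lev))
    for (i in seq_len(n)) {
      leak <- 1 - conf[i]
      probs[i, observed[i]] <- conf[i]
      if (leak > 0) {
        nb <- .adjacent_labels(observed[i])
        probs[i, nb] <- probs[i, nb] + leak / length(nb)
      }
    }
    prediction_sequence(video_id, timeline$frame_index,
                        timeline$time_minutes, probs)
  })
}

#' Render a stage-coded synthetic well image
#'
#' Draws a bright well circle containing stage-specific geometry on a dark
#' background: a single large cell with marks for the pronuclear stages,
#' `k` fixed-radius non-overlapping cells for cleavage stage `tk` (>= 9
#' for `t9+`), a cluster of many tiny cells for the morula, a cell with a
#' growing cavity for the blastocyst stages, an external bulge for the
#' hatched blastocyst, and nothing for `Empty`. Blob positions are rotated
#' randomly per image and Gaussian pixel noise is added. The rendering is
#' a visual proxy whose class identity is recoverable by a small model --
#' the test surface is the pipeline, not photorealism.
#'
#' @param stage a stage label.
#' @param size image side in pixels (>= 32).
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @return numeric matrix `size` x `size` in \[0, 1\].
#' @export
render_frame <- function(stage, size = 64L, seed = NULL) {
  size <- as.integer(size)
  if (size < 32L) stop("size must be at least 32 pixels", call. = FALSE)
  stage <- as.character(parse_label(stage))
  ax <- seq(-1, 1, length.out = size)
  X <- matrix(ax, size, size, byrow = TRUE)   # x = column coordinate
  Y <- matrix(ax, size, size)                 # y = row coordinate
  with_local_seed(seed, {
    img <- matrix(0.08, size, size)
    img[X^2 + Y^2 < 0.95^2] <- 0.35           # the well
    phi <- stats::runif(1, 0, 2 * pi)
    jit <- stats::runif(2, -0.04, 0.04)
    disc <- function(cx, cy, r, v) {
      x <- cos(phi) * cx - sin(phi) * cy + jit[1]
      y <- sin(phi) * cx + cos(phi) * cy + jit[2]
      img[(X - x)^2 + (Y - y)^2 < r^2] <<- v
    }
    ring_of <- function(k, R, r, v = 0.75) {
      for (j in seq_len(k)) {
        a <- 2 * pi * (j - 1) / k
        disc(R * cos(a), R * sin(a), r, v)
      }
    }
    cells <- function(k) {
      if (k == 1L) disc(0, 0, 0.55, 0.75)
      else if (k <= 4L) ring_of(k, 0.42, 0.24)
      else if (k <= 8L) ring_of(k, 0.55, 0.17)
      else { ring_of(8L, 0.6, 0.13); ring_of(2L, 0.2, 0.13) }
    }
    switch(stage,
      tPB2 = { disc(0, 0, 0.55, 0.7); disc(0.65, 0, 0.1, 0.9) },
      tPNa = { disc(0, 0, 0.55, 0.7); disc(-0.15, 0, 0.12, 0.45)
               disc(0.15, 0, 0.12, 0.45) },
      tPNf = disc(0, 0, 0.55, 0.7),
      t2 = cells(2L), t3 = cells(3L), t4 = cells(4L), t5 = cells(5L),
      t6 = cells(6L), t7 = cells(7L), t8 = cells(8L), `t9+` = cells(10L),
      tM = { ring_of(10L, 0.55, 0.09); ring_of(6L, 0.26, 0.09) },
      tSB = { disc(0, 0, 0.8, 0.75); disc(0, 0, 0.18, 0.35) },
      tB = { disc(0, 0, 0.8, 0.75); disc(0, 0, 0.38, 0.35) },
      tEB = { disc(0, 0, 0.8, 0.75); disc(0, 0, 0.55, 0.35) },
      tHB = { disc(0, 0, 0.72, 0.75); disc(0, 0, 0.5, 0.35)
              disc(0.85, 0, 0.16, 0.75) },
      Empty = invisible(NULL))
    img <- img + matrix(stats::rnorm(size^2, 0, 0.03), size, size)
    pmin(pmax(img, 0), 1)
  })
}

# largest-remainder apportionment of n videos into named fractions
largest_remainder_split <- function(n, fractions = c(train = 0.7, val = 0.1,
                                                     test = 0.2)) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a synthetic on-disk time-lapse dataset
#'
#' Writes the dataset layout consumed by the classifier tooling:
#' `videos/<video_id>/<frame>.png` grayscale frames, an `annotations.csv`
#' (video_id, frame_index, time_minutes, label), a `split.csv` assigning
#' whole videos to train/validation/test at 70/10/20 (largest-remainder
#' rounding, seeded random assignment), and a `predictions.csv` of
#' simulated noisy classifier output for the postprocessing tools.
#'
#' @param n_videos number of videos (>= 10).
#' @param out_dir output directory (created).
#' @param config a [timeline_config()].
#' @param noise a [noise_config()] for the simulated predictions.
#' @param size frame side length in pixels.
#' @param seed integer seed.
#' @param write_frames render and write PNG frames (`FALSE` writes only
#'   the tables, which is considerably faster).
#' @return invisibly, a list with `annotations`, `split` (data.frames)
#'   and `dir`.
#' @export
generate_dataset <- function(n_videos, out_dir,
                             config = timeline_config(),
                             noise = noise_config(), size = 64L, seed = 1L,
                             write_frames = TRUE) {
  if (n_videos < 10L) stop("n_videos must be at least 10", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("video%03d", seq_len(n_videos))
  with_local_seed(seed, {
    counts <- largest_remainder_split(n_videos)
    assign_split <- rep(names(counts), counts)[sample.int(n_videos)]
    ann <- vector("list", n_videos)
    preds <- vector("list", n_videos)
    for (v in seq_len(n_videos)) {
      tl <- sample_timeline(config)
      ann[[v]] <- data.frame(video_id = ids[v], tl,
                             stringsAsFactors = FALSE)
      preds[[v]] <- simulate_predictions(tl, noise, video_id = ids[v])
      if (write_frames) {
        vdir <- file.path(out_dir, "videos", ids[v])
        dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
        for (k in seq_len(nrow(tl))) {
          img <- render_frame(tl$label[k], size = size)
          png::writePNG(img, file.path(
            vdir, sprintf("%05d.png", tl$frame_index[k])))
        }
      }
    }
    annotations <- do.call(rbind, ann)
    split <- data.frame(video_id = ids, split = assign_split,
                        stringsAsFactors = FALSE)
    write_annotations(file.path(out_dir, "annotations.csv"), annotations)
    utils::write.csv(split, file.path(out_dir, "split.csv"),
                     row.names = FALSE, quote = FALSE)
    write_predictions(file.path(out_dir, "predictions.csv"), preds)
    invisible(list(annotations = annotations, split = split, dir = out_dir))
  })
}

#' Render a labelled blob dataset for classifier tests
#'
#' Renders `n_per_class` frames per stage with acquisition times drawn
#' from each stage's typical onset window, and assigns a 70/10/20 split.
#' The default five classes (`tPNf`, `t2`, `t3`, `t4`, `Empty`) have
#' well-separated foreground areas, making the task learnable by the tiny
#' backbone within a few epochs.
#'
#' @param classes stages to render.
#' @param n_per_class images per stage.
#' @param size image side length in pixels.
#' @param seed integer seed.
#' @return dataset list (`images`, `minutes`, `labels`, `split`,
#'   `video_id`) as consumed by [train_classifier()].
#' @export
render_stage_dataset <- function(classes = c("tPNf", "t2", "t3", "t4",
                                             "Empty"),
                                 n_per_class = 120L, size = 32L, seed = 1L) {
  classes <- as.character(parse_label(classes))
  onset <- cumsum(c(0, .default_stage_hours))
  names(onset) <- c(names(.default_stage_hours), "Empty")
  dwell <- c(.default_stage_hours, Empty = 6)
  with_local_seed(seed, {
    n <- length(classes) * n_per_class
    lab <- rep(classes, each = n_per_class)
    minutes <- (onset[lab] + stats::runif(n, 0, 1) * dwell[lab]) * 60
    images <- lapply(seq_len(n), function(i) render_frame(lab[i], size))
    counts <- largest_remainder_split(n)
    split <- rep(names(counts), counts)[sample.int(n)]
    list(images = images, minutes = unname(minutes),
         labels = factor(lab, levels = classes),
         split = split, video_id = sprintf("img%04d", seq_len(n)))
  })
}
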