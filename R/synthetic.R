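# Synthetic reach generator with known ground-truth submovements. The
# generative policy emulates the recording conditions of rapid 3D radial
# reaches: start-to-target distances 20-70 cm (43.5 +/- 11.2 cm), 2-5
# overlapping minimum-jerk submovements per reach with mean ~2.9, a first
# submovement that undershoots the target, corrective submovements that aim
# at the remaining vector but land with a zero-mean endpoint error (the
# final one closing exactly), and band-limited velocity noise. Because the
# corrective policy's conditional mean is "cover the remaining vector", it
# is the learnable mapping a deterministic network can recover, and the
# endpoint errors keep successive submovements large enough for the
# decomposition to identify.

#' Synthetic-reach generator configuration
#'
#' @param dist_mean,dist_sd,dist_range Start-to-target distance distribution:
#'   normal truncated to the range (cm).
#' @param n_sub_range Bounds on submovements per reach. The count itself is
#'   endogenous: a reach continues because the latest correction missed, and
#'   stops when one lands inside the target (forced closure at the upper
#'   bound). With `p_close = 0.5` the count distribution over 2--5 is
#'   approximately (.5, .25, .125, .125), mean about 2.9.
#' @param p_close Probability that a corrective submovement lands inside the
#'   target (ending the reach) rather than missing.
#' @param close_scatter Maximum endpoint offset of a closing correction (cm);
#'   closers land uniformly within this radius of the target centre.
#' @param undershoot First-submovement fraction of the start-to-target
#'   distance, sampled uniformly in this range.
#' @param corr_err Relative endpoint-error range of intermediate corrective
#'   submovements: each covers the remaining vector plus an error of
#'   magnitude `U(corr_err) * |remaining|` in a uniformly random direction
#'   (the final submovement closes the remainder exactly). Zero-mean errors
#'   make "aim at the target" the learnable conditional-mean policy, while
#'   keeping successive submovements large enough for the decomposition to
#'   identify.
#' @param corr_err_floor Absolute floor on a missing correction's
#'   endpoint-error magnitude (cm): motor noise does not scale down
#'   indefinitely with movement size, so the corrections that keep a reach
#'   going stay observable.
#' @param jitter_deg Direction jitter (degrees) applied to non-final
#'   submovement amplitudes.
#' @param onset_phase Range of the phase of the ongoing submovement at which
#'   the next correction is launched: the next onset is
#'   `t0_k + U(onset_phase) * D_k` (plus `onset_jitter` noise), so
#'   corrections begin before the previous submovement ends (overlap) and
#'   onset times are predictable from the ongoing submovement's duration.
#' @param onset_jitter Additive onset noise sd (s).
#' @param min_gap Minimum inter-onset gap (s).
#' @param dur_intercept,dur_slope,dur_sd Duration model
#'   `D = intercept + slope * |A| + N(0, sd)` (s, s/cm, s), clamped to
#'   `dur_range`.
#' @param dur_range Allowed duration range (s).
#' @param noise_sd Standard deviation of the band-limited velocity noise
#'   vector (cm/s); per-axis sd is `noise_sd / sqrt(3)`.
#' @param noise_cutoff Low-pass cutoff of the noise (Hz); below the 10 Hz
#'   preprocessing cutoff so the noise survives filtering.
#' @param gap_rate Per-trial probability of injecting one occlusion run.
#' @param gap_len Length (samples) of an injected occlusion.
#' @param fs Sampling rate (Hz).
#' @param tail Recording tail after the last submovement ends (s).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(dist_mean = 43.5, dist_sd = 11.2,
                             dist_range = c(20, 70),
                             n_sub_range = c(2L, 5L),
                             p_close = 0.48, close_scatter = 1.0,
                             undershoot = c(0.6, 0.9),
                             corr_err = c(0.35, 0.55),
                             corr_err_floor = 5.0,
                             jitter_deg = 10,
                             onset_phase = c(0.6, 0.9),
                             onset_jitter = 0.02, min_gap = 0.15,
                             dur_intercept = 0.22, dur_slope = 0.011,
                             dur_sd = 0.02, dur_range = c(0.1, 1.5),
                             noise_sd = 0.5, noise_cutoff = 8,
                             gap_rate = 0, gap_len = 6L,
                             fs = 100, tail = 0.3) {
  structure(as.list(environment()), class = "generator_config")
}

rtrunc_norm <- function(mean, sd, range) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

jitter_vec <- function(A, deg) {
  if (deg <= 0) return(A)
  s <- sqrt(sum(A^2)) * sin(deg * pi / 180) / sqrt(3)
  A + stats::rnorm(3, 0, s)
}

#' Sample the ground truth of one synthetic reach
#'
#' Draws a target in the forward-upward reachable cone at a truncated-normal
#' distance, then composes the reach: the first submovement covers an
#' undershoot fraction of the start-to-target vector (with direction
#' jitter), and corrective submovements aim at the remaining vector until
#' one lands inside the target. Each correction closes with probability
#' `p_close` (landing within `close_scatter` of the target centre);
#' otherwise it misses by a zero-mean error of magnitude
#' `max(U(corr_err) * |remaining|, corr_err_floor)` and the sequence
#' continues, closing by force at the submovement cap. Corrections launch at
#' a sampled phase of the ongoing submovement's course; durations follow an
#' affine function of amplitude magnitude.
#'
#' Uses the current RNG state; seed at the corpus level.
#'
#' @param cfg A [generator_config()].
#' @return List with `start`, `target`, `submovements` (onset-ordered list of
#'   [submovement()]), and `success` flag.
#' @export
sample_reach <- function(cfg = generator_config()) {
  start <- c(0, 0, 0)
  dist <- rtrunc_norm(cfg$dist_mean, cfg$dist_sd, cfg$dist_range)
  az <- stats::runif(1, -30, 30) * pi / 180
  el <- stats::runif(1, 15, 55) * pi / 180
  dir <- c(cos(el) * sin(az), cos(el) * cos(az), sin(el))
  target <- start + dist * dir
  k_max <- cfg$n_sub_range[2]
  subs <- list()
  pos <- start
  t0 <- 0
  k <- 0
  repeat {
    k <- k + 1
    remaining <- target - pos
    closing <- FALSE
    if (k == 1) {
      A <- jitter_vec(stats::runif(1, cfg$undershoot[1], cfg$undershoot[2]) *
                        remaining, cfg$jitter_deg)
    } else if (k == k_max) {
      A <- remaining
      closing <- TRUE
    } else if (stats::runif(1) < cfg$p_close) {
      e <- stats::rnorm(3)
      A <- remaining +
        stats::runif(1, 0, cfg$close_scatter) * e / sqrt(sum(e^2))
      closing <- TRUE
    } else {
      u <- stats::runif(1, cfg$corr_err[1], cfg$corr_err[2])
      mag <- max(u * sqrt(sum(remaining^2)), cfg$corr_err_floor)
      e <- stats::rnorm(3)
      A <- remaining + mag * e / sqrt(sum(e^2))
    }
    D <- min(max(cfg$dur_intercept + cfg$dur_slope * sqrt(sum(A^2)) +
                   stats::rnorm(1, 0, cfg$dur_sd), cfg$dur_range[1]),
             cfg$dur_range[2])
    subs[[k]] <- submovement(t0, D, A)
    pos <- pos + A
    if (k > 1 && closing) break
    t0 <- t0 + max(cfg$min_gap,
                   stats::runif(1, cfg$onset_phase[1], cfg$onset_phase[2]) *
                     D + stats::rnorm(1, 0, cfg$onset_jitter))
  }
  list(start = start, target = target, submovements = subs, success = TRUE)
}

# Band-limited noise with vector sd sigma (filtered white noise, rescaled).
bandlimited_noise <- function(n, sigma, fs, cutoff) {
  per_axis <- sigma / sqrt(3)
  sapply(1:3, function(d) {
    w <- stats::rnorm(n)
    x <- zero_phase_filter(w, fs = fs, cutoff = cutoff)
    x * per_axis / max(stats::sd(x), 1e-12)
  })
}

#' Render a ground-truth reach into a sampled trial
#'
#' Positions are the closed-form superposition of the true submovements plus
#' time-integrated band-limited velocity noise, sampled at `cfg$fs`.
#' Optionally injects one run of occluded (NA) samples to exercise the
#' preprocessing exclusion rule.
#'
#' Uses the current RNG state; seed at the corpus level.
#'
#' @param truth Output of [sample_reach()].
#' @param cfg A [generator_config()].
#' @param trial_id Identifier for the rendered trial.
#' @return A [reach_trial()] (raw; run [preprocess()]/[differentiate()]
#'   before analysis).
#' @export
render_trial <- function(truth, cfg = generator_config(), trial_id = 1L) {
  t_end <- max(vapply(truth$submovements, function(s) s$t0 + s$D, 0)) +
    cfg$tail
  dt <- 1 / cfg$fs
  t <- seq(0, t_end, by = dt)
  p <- position_trajectory(truth$submovements, truth$start, t)
  if (cfg$noise_sd > 0) {
    vn <- bandlimited_noise(length(t), cfg$noise_sd, cfg$fs, cfg$noise_cutoff)
    p <- p + apply(vn, 2, cumsum) * dt
  }
  if (cfg$gap_rate > 0 && stats::runif(1) < cfg$gap_rate) {
    i0 <- sample(seq(2L, max(2L, length(t) - cfg$gap_len)), 1)
    p[i0:(i0 + cfg$gap_len - 1L), ] <- NA_real_
  }
  reach_trial(trial_id = trial_id, t = t, p = p, target = truth$target,
              start = truth$start)
}

#' Generate a synthetic reach corpus with ground truth
#'
#' @param n_reaches Number of reaches.
#' @param cfg A [generator_config()].
#' @param seed RNG seed; fixes the whole corpus.
#' @param participant_id Label for the synthetic participant.
#' @return List with `dataset` (a `reach_dataset` of raw trials) and `truth`
#'   (per-reach ground-truth list).
#' @export
synth_corpus <- function(n_reaches, cfg = generator_config(), seed = 0,
                         participant_id = "synthetic") {
  set.seed(seed)
  truths <- list(); trials <- list()
  for (i in seq_len(n_reaches)) {
    truths[[i]] <- sample_reach(cfg)
    trials[[i]] <- render_trial(truths[[i]], cfg, trial_id = i)
  }
  dataset <- structure(list(participant_id = participant_id, trials = trials,
                            provenance = list(
                              source = sprintf("synthetic(seed=%d)", seed),
                              log = character())),
                       class = "reach_dataset")
  list(dataset = dataset, truth = truths)
}

#' Export a synthetic corpus to CSV (+ ground-truth JSON sidecar)
#'
#' Round-trips through [load_dataset()].
#'
#' @param corpus Output of [synth_corpus()].
#' @param path CSV output path.
#' @param truth_path Optional JSON sidecar path for the ground truth.
#' @return `path`, invisibly.
#' @export
export_corpus <- function(corpus, path, truth_path = NULL) {
  write_dataset(corpus$dataset, path)
  if (!is.null(truth_path)) {
    ser <- lapply(corpus$truth, function(tr) list(
      start = tr$start, target = tr$target, success = tr$success,
      submovements = lapply(tr$submovements, function(s)
        list(t0 = s$t0, D = s$D, A = s$A))))
    jsonlite::write_json(ser, truth_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a ground-truth sidecar written by [export_corpus()]
#'
#' @param path JSON sidecar path.
#' @return Per-reach ground-truth list.
#' @export
read_truth <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(ser, function(tr)
    list(start = as.numeric(unlist(tr$start)),
         target = as.numeric(unlist(tr$target)),
         success = isTRUE(tr$success),
         submovements = lapply(tr$submovements, function(s)
           submovement(s$t0, s$D, as.numeric(unlist(s$A))))))
}
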