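# Closed-loop trajectory generation: the three predictors are chained so
# that each network's inputs come from the trajectory produced by earlier
# network predictions, letting prediction errors propagate causally as they
# would in real reaching.

#' Simulation configuration
#'
#' @param dt Simulation timestep (s).
#' @param target_radius Virtual target radius (cm).
#' @param dwell Continuous in-target residence required for a hit (s).
#' @param timeout Simulated-time cap (s).
#' @param max_submovements Submovement cap; exceeding it is a failure.
#' @param refractory Minimum steps after a trigger before the initiation
#'   network is queried again.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.01, target_radius = 1.27, dwell = 1.0,
                              timeout = 3.0, max_submovements = 30,
                              refractory = 1) {
  stopifnot(dt > 0, target_radius > 0, dwell > 0, timeout > 0,
            max_submovements > 0, refractory >= 1)
  structure(list(dt = dt, target_radius = target_radius, dwell = dwell,
                 timeout = timeout, max_submovements = max_submovements,
                 refractory = as.integer(refractory)),
            class = "simulation_config")
}

#' Simulate one closed-loop reach
#'
#' The first submovement is triggered automatically at `t = 0` with
#' network-predicted amplitude and duration. At each subsequent `dt` step
#' the initiation features are built from the simulated state (the planned
#' trajectory of all triggered submovements) and the initiation network is
#' queried; when its output exceeds 0.5 a corrective submovement is added
#' with network-predicted amplitude and duration. The simulation ends in
#' success when the fingertip has stayed inside the target radius for the
#' full dwell time, or in failure at the time-out or the submovement cap.
#' After the last submovement ends the position holds constant.
#'
#' @param nets A `trained_nets` object, or a list whose `initiation`,
#'   `amplitude`, `duration` elements are plain functions
#'   (`f(features) -> probability`, `f(features, dttaps) -> 3-vector cm`,
#'   `f(features) -> seconds`) -- stub predictors for contract tests.
#' @param start,target Length-3 positions (cm).
#' @param cfg A [simulation_config()].
#' @param feature_cfg A [feature_config()].
#' @return Object of class `sim_result`: `t`, `trajectory`
#'   (`length(t) x 3`), `submovements`, `success`, `failure_reason`,
#'   `end_distance` (cm), `n_submovements`, `movement_time` (s).
#' @export
simulate_reach <- function(nets, start, target, cfg = simulation_config(),
                           feature_cfg = feature_config()) {
  start <- as.numeric(start); target <- as.numeric(target)
  dwell_steps <- round(cfg$dwell / cfg$dt)
  n_steps <- round(cfg$timeout / cfg$dt)
  tgrid <- seq(0, by = cfg$dt, length.out = n_steps + 1)

  query_init <- function(f)
    if (is.function(nets$initiation)) nets$initiation(f)
    else predict_initiation(nets$initiation, f)
  amp_dur_at <- function(subs_prior, t_now, p, v, a) {
    af <- build_amplitude_features(start, target, v, a, subs_prior, t_now,
                                   feature_cfg)
    A <- if (is.function(nets$amplitude)) nets$amplitude(af$features, af$dttaps)
         else predict_amplitude(nets$amplitude, af$features, af$dttaps)
    df <- build_duration_features(start, target, v, a, subs_prior, t_now, A,
                                  feature_cfg)
    D <- if (is.function(nets$duration)) nets$duration(df)
         else predict_duration(nets$duration, df)
    list(A = A, D = D)
  }

  ad <- amp_dur_at(list(), 0, start, c(0, 0, 0), c(0, 0, 0))
  subs <- list(submovement(0, ad$D, ad$A))
  last_trigger_step <- 0L
  in_count <- if (sqrt(sum((start - target)^2)) <= cfg$target_radius) 1L else 0L
  success <- FALSE
  failure <- NULL
  end_step <- n_steps

  for (k in seq_len(n_steps)) {
    t_now <- tgrid[k + 1]
    p <- planned_position(subs, start, t_now)
    if (sqrt(sum((p - target)^2)) <= cfg$target_radius)
      in_count <- in_count + 1L else in_count <- 0L
    if (in_count >= dwell_steps + 1L) { success <- TRUE; end_step <- k; break }
    if (k - last_trigger_step >= cfg$refractory) {
      f <- build_initiation_features(start, target, p, subs, t_now,
                                     feature_cfg)
      pr <- query_init(f)
      if (pr > 0.5) {
        if (length(subs) >= cfg$max_submovements) {
          failure <- "submovement-cap"; end_step <- k; break
        }
        v <- as.numeric(superpose(subs, t_now))
        a <- as.numeric(superpose_acceleration(subs, t_now))
        ad <- amp_dur_at(subs, t_now, p, v, a)
        subs[[length(subs) + 1L]] <- submovement(t_now, ad$D, ad$A)
        last_trigger_step <- k
      }
    }
  }
  if (!success && is.null(failure)) failure <- "timeout"
  tt <- tgrid[seq_len(end_step + 1L)]
  traj <- position_trajectory(subs, start, tt)
  structure(list(t = tt, trajectory = traj, submovements = subs,
                 success = success,
                 failure_reason = if (success) NA_character_ else failure,
                 end_distance = sqrt(sum((traj[nrow(traj), ] - target)^2)),
                 n_submovements = length(subs),
                 movement_time = tt[length(tt)],
                 start = start, target = target),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %s in %.2f s, %d submovements, end distance %.2f cm\n",
              if (x$success) "hit" else paste0("miss (", x$failure_reason, ")"),
              x$movement_time, x$n_submovements, x$end_distance))
  invisible(x)
}

# Compare a simulated trajectory with a measured trial over the overlap of
# the two time bases, on the measured grid.
compare_trajectories <- function(sim, trial) {
  t_max <- min(sim$t[length(sim$t)], trial$t[length(trial$t)])
  idx <- which(trial$t <= t_max + 1e-9)
  obs <- trial$p[idx, , drop = FALSE]
  pred <- sapply(1:3, function(d)
    stats::approx(sim$t, sim$trajectory[, d], xout = trial$t[idx],
                  rule = 2)$y)
  list(observed = obs, predicted = pred)
}

#' Evaluate the closed-loop model on a set of trials
#'
#' Simulates one reach per trial (same start/target) and compares the
#' simulated and measured trajectories over the overlap of their time bases
#' on the measured grid, pooling the three dimensions into a single VAF and
#' 3D RMSE.
#'
#' @param nets A `trained_nets` object.
#' @param trials List of measured [reach_trial()]s.
#' @param cfg A [simulation_config()].
#' @param feature_cfg A [feature_config()].
#' @return List with `sims`, `acquisition_rate` (percent), end-distance
#'   summaries (all and failed-only), pooled `vaf` (percent) and `rmse`
#'   (cm), and a per-trial data frame `per_trial`.
#' @export
evaluate_closed_loop <- function(nets, trials, cfg = simulation_config(),
                                 feature_cfg = feature_config()) {
  sims <- lapply(trials, function(tr)
    simulate_reach(nets, tr$start, tr$target, cfg, feature_cfg))
  obs <- list(); pred <- list()
  per <- data.frame(trial_id = vapply(trials, function(x)
                      as.character(x$trial_id), ""),
                    success = vapply(sims, `[[`, TRUE, "success"),
                    end_distance = vapply(sims, `[[`, 0, "end_distance"),
                    n_submovements = vapply(sims, `[[`, 0L, "n_submovements"))
  for (i in seq_along(sims)) {
    cmp <- compare_trajectories(sims[[i]], trials[[i]])
    obs[[i]] <- cmp$observed; pred[[i]] <- cmp$predicted
  }
  obs <- do.call(rbind, obs); pred <- do.call(rbind, pred)
  ed <- per$end_distance
  list(sims = sims,
       acquisition_rate = 100 * mean(per$success),
       end_distance_mean = mean(ed), end_distance_sd = stats::sd(ed),
       end_distance_failed_mean = if (any(!per$success))
         mean(ed[!per$success]) else NA_real_,
       vaf = vaf(obs, pred), rmse = rmse(obs, pred),
       per_trial = per)
}
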