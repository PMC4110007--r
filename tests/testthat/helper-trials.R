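# Small in-code fixtures: noiseless trials built directly from the
# closed-form minimum-jerk expressions (no filtering), so decomposition and
# feature tests see exactly the model they assume.

closed_form_trial <- function(subs, start = c(0, 0, 0), t_end = NULL,
                              dt = 0.01, trial_id = 1L,
                              target = NULL) {
  if (is.null(t_end))
    t_end <- max(vapply(subs, function(s) s$t0 + s$D, 0)) + 0.2
  t <- seq(0, t_end, by = dt)
  if (is.null(target))
    target <- start + Reduce(`+`, lapply(subs, `[[`, "A"), init = c(0, 0, 0))
  tr <- reach_trial(trial_id = trial_id, t = t,
                    p = position_trajectory(subs, start, t),
                    target = target, start = start)
  tr$v <- superpose(subs, t)
  tr$a <- superpose_acceleration(subs, t)
  tr
}

# trapezoid quadrature used as an independent oracle
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

fast_decomp_cfg <- function(n_max = 6, seed = 1)
  decomposition_config(n_range = seq_len(n_max), n_restarts = 1, seed = seed)
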