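# Decomposition of a measured 3D velocity trajectory into N overlapping
# minimum-jerk submovements by bounded nonlinear least squares, with an
# overlap penalty that discourages simultaneous submovements of opposite
# amplitude, and knee-point selection of the optimal N.

#' Decomposition configuration
#'
#' @param n_range Candidate submovement counts (ascending), default `1:14`:
#'   the knee criterion can only resolve a submovement whose share of the
#'   normalised cost range exceeds roughly `1/(max(n_range) - 1)`, so the
#'   range extends a little past the largest count expected in the data.
#' @param d_min Minimum submovement duration (s); 0.1 s, the approximate
#'   duration of a muscle-twitch force transient.
#' @param d_max Maximum duration (s).
#' @param lambda_overlap Relative weight of the overlap penalty. The absolute
#'   weight is `lambda_overlap * max(speed)` of the trial being fitted, which
#'   puts the penalty term (units cm) on the scale of the squared-error term
#'   (units cm^2/s).
#' @param n_restarts Number of perturbed restarts per N (in addition to the
#'   warm start and the greedy residual-peak start).
#' @param seed Optional RNG seed for restart jitter.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param tol Slack allowed when checking cost monotonicity in N.
#' @param flat_tol Parsimony guard for knee selection: when the smallest
#'   candidate N already reconstructs the trial almost perfectly (its cost is
#'   below `flat_tol` times the empty-model cost, i.e. velocity VAF above
#'   99.9% at the default), the knee of the residual curve is numerical noise
#'   and the smallest N is selected directly.
#' @return Object of class `decomposition_config`.
#' @export
decomposition_config <- function(n_range = 1:14, d_min = 0.1, d_max = 2,
                                 lambda_overlap = 0.01, n_restarts = 5,
                                 seed = NULL, maxit = 300, tol = 1e-6,
                                 flat_tol = 1e-3) {
  stopifnot(length(n_range) >= 1, all(diff(n_range) > 0), d_min > 0,
            d_max > d_min, lambda_overlap >= 0, n_restarts >= 0)
  structure(list(n_range = as.integer(n_range), d_min = d_min, d_max = d_max,
                 lambda_overlap = lambda_overlap, n_restarts = n_restarts,
                 seed = seed, maxit = maxit, tol = tol, flat_tol = flat_tol),
            class = "decomposition_config")
}

# theta layout for N submovements: c(t0[1:N], D[1:N], Ax[1:N], Ay[1:N], Az[1:N])
theta_to_subs <- function(theta) {
  n <- length(theta) / 5L
  lapply(seq_len(n), function(j)
    submovement(max(theta[j], 0), theta[n + j],
                theta[c(2 * n + j, 3 * n + j, 4 * n + j)]))
}

subs_to_theta <- function(subs) {
  c(vapply(subs, `[[`, 0, "t0"), vapply(subs, `[[`, 0, "D"),
    vapply(subs, function(s) s$A[1], 0), vapply(subs, function(s) s$A[2], 0),
    vapply(subs, function(s) s$A[3], 0))
}

# Cost and analytic gradient of the decomposition objective at theta.
# M: T x 3 measured velocity on times t (uniform step dt); lambda absolute.
decomp_cost_grad <- function(theta, M, t, dt, lambda) {
  n <- length(theta) / 5L
  t0 <- theta[seq_len(n)]
  D <- theta[n + seq_len(n)]
  A <- cbind(theta[2 * n + seq_len(n)], theta[3 * n + seq_len(n)],
             theta[4 * n + seq_len(n)])                     # n x 3
  Tn <- length(t)
  B <- matrix(0, Tn, n)       # basis b_j(t) = shape(tau)/D
  dBdt0 <- matrix(0, Tn, n)
  dBdD <- matrix(0, Tn, n)
  for (j in seq_len(n)) {
    tau <- (t - t0[j]) / D[j]
    sh <- mj_shape(tau)
    ac <- mj_accel_shape(tau)
    B[, j] <- sh / D[j]
    dBdt0[, j] <- -ac / D[j]^2
    dBdD[, j] <- -(sh + tau * ac) / D[j]^2
  }
  R <- B %*% A                # T x 3 reconstructed velocity
  err <- R - M
  E <- sum(err^2) * dt
  cB <- colSums(B)            # ~ 1/dt each (basis integrates to 1)
  sgnR <- sign(R)
  P <- dt * (sum(cB * rowSums(abs(A))) - sum(abs(R)))
  value <- E + lambda * P

  Gw <- 2 * dt * err                                   # T x 3
  gA <- t(B) %*% Gw +
    lambda * dt * (sign(A) * cB - t(B) %*% sgnR)       # n x 3
  # shared T x n weights for the t0/D chain rule
  W <- Gw %*% t(A) - lambda * dt * (sgnR %*% t(A))     # T x n
  absA <- rowSums(abs(A))
  gt0 <- colSums(dBdt0 * W) + lambda * dt * absA * colSums(dBdt0)
  gD <- colSums(dBdD * W) + lambda * dt * absA * colSums(dBdD)
  grad <- c(gt0, gD, gA[, 1], gA[, 2], gA[, 3])
  list(value = value, grad = grad)
}

#' Reconstruction cost of a submovement set against a measured trial
#'
#' The objective minimised by the decomposition: the time-integrated squared
#' velocity error summed over x, y, z, plus an overlap penalty
#' \deqn{\lambda \sum_d \int \Big(\sum_j |v_{j,d}| - \big|\sum_j v_{j,d}\big|\Big) dt}
#' that is zero unless simultaneously active submovements oppose each other
#' in some dimension, which prevents the optimizer from cancelling opposite
#' amplitudes against each other.
#'
#' @param subs List of [submovement()] objects.
#' @param trial A preprocessed, differentiated [reach_trial()].
#' @param cfg A [decomposition_config()].
#' @return Non-negative scalar cost (cm^2/s).
#' @export
reconstruction_cost <- function(subs, trial, cfg = decomposition_config()) {
  stopifnot(inherits(trial, "reach_trial"), !is.null(trial$v))
  dt <- trial$t[2] - trial$t[1]
  lambda <- cfg$lambda_overlap * max(sqrt(rowSums(trial$v^2)), 1e-9)
  if (length(subs) == 0L) return(sum(trial$v^2) * dt)
  decomp_cost_grad(subs_to_theta(subs), trial$v, trial$t, dt, lambda)$value
}

# Greedy residual-peak initialization: repeatedly take the residual speed
# peak, estimate the pulse's extent by walking out to 20% of the peak, seed
# a submovement with the residual displacement over that window, and
# subtract it.
greedy_init <- function(trial, n, d_min, d_max) {
  dt <- trial$t[2] - trial$t[1]
  resid <- trial$v
  subs <- list()
  t_end <- trial$t[length(trial$t)]
  for (j in seq_len(n)) {
    speed <- sqrt(rowSums(resid^2))
    k <- which.max(speed)
    thr <- 0.2 * speed[k]
    lo <- k; while (lo > 1 && speed[lo - 1] >= thr) lo <- lo - 1
    hi <- k; while (hi < length(speed) && speed[hi + 1] >= thr) hi <- hi + 1
    t0 <- min(max(trial$t[lo], 0), max(t_end - d_min, 0))
    D <- min(max(trial$t[hi] - t0, max(d_min, 0.2)), d_max)
    win <- trial$t >= t0 & trial$t <= t0 + D
    Aj <- colSums(resid[win, , drop = FALSE]) * dt
    if (all(abs(Aj) < 1e-6)) Aj <- c(1e-3, 1e-3, 1e-3)
    s <- submovement(t0, D, Aj)
    subs[[j]] <- s
    resid <- resid - minjerk_velocity(s, trial$t)
  }
  subs
}

fit_from_start <- function(theta0, M, t, dt, lambda, lower, upper, maxit) {
  # optim evaluates fn and gr at the same point back-to-back; cache one step
  last <- NULL
  eval_at <- function(th) {
    if (is.null(last) || !identical(th, last$theta))
      last <<- c(list(theta = th), decomp_cost_grad(th, M, t, dt, lambda))
    last
  }
  fn <- function(th) eval_at(th)$value
  gr <- function(th) eval_at(th)$grad
  res <- try(stats::optim(pmin(pmax(theta0, lower), upper), fn, gr,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(maxit = maxit, factr = 1e4)),
             silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  res
}

#' Fit exactly N submovements to a trial
#'
#' Bounded quasi-Newton nonlinear least squares over the `5 N` parameter
#' vector (initiation times, durations, 3D amplitudes), multi-started from a
#' greedy residual-peak initialization, optional warm starts, and
#' `n_restarts` jittered perturbations; the best converged fit is returned.
#'
#' @param trial A preprocessed, differentiated [reach_trial()].
#' @param N Number of submovements (`>= 1`).
#' @param cfg A [decomposition_config()].
#' @param warm_start Optional list of submovement lists (length-N) used as
#'   additional starting points.
#' @return List with `subs` (length-N list of submovements), `cost`, and
#'   `n_starts` tried.
#' @export
decompose_fixed_n <- function(trial, N, cfg = decomposition_config(),
                              warm_start = NULL) {
  stopifnot(inherits(trial, "reach_trial"), !is.null(trial$v), N >= 1)
  dt <- trial$t[2] - trial$t[1]
  t_end <- trial$t[length(trial$t)]
  lambda <- cfg$lambda_overlap * max(sqrt(rowSums(trial$v^2)), 1e-9)
  a_max <- max(10, 3 * max(abs(trial$v)) )  # generous amplitude bound, cm
  lower <- c(rep(0, N), rep(cfg$d_min, N), rep(-a_max, 3 * N))
  upper <- c(rep(max(t_end - cfg$d_min, 0.01), N), rep(cfg$d_max, N),
             rep(a_max, 3 * N))
  starts <- list(subs_to_theta(greedy_init(trial, N, cfg$d_min, cfg$d_max)))
  if (!is.null(warm_start))
    for (ws in warm_start)
      if (length(ws) == N) starts <- c(starts, list(subs_to_theta(ws)))
  if (cfg$n_restarts > 0) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed + N)
    base <- starts[[1]]
    for (r in seq_len(cfg$n_restarts)) {
      jit <- c(stats::runif(N, -0.15, 0.15), stats::runif(N, -0.1, 0.2),
               stats::rnorm(3 * N, 0, 2))
      starts <- c(starts, list(base + jit))
    }
  }
  best <- NULL
  for (th0 in starts) {
    res <- fit_from_start(th0, trial$v, trial$t, dt, lambda, lower, upper,
                          cfg$maxit)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("decompose_fixed_n: optimizer failed on all starts (N=", N, ")",
         call. = FALSE)
  subs <- theta_to_subs(best$par)
  subs <- subs[order(vapply(subs, `[[`, 0, "t0"))]
  list(subs = subs, cost = best$value, n_starts = length(starts))
}

#' Select the optimal submovement count from a cost curve (knee point)
#'
#' Both axes of the cost-per-N curve are min-max normalised to `[0, 1]`; the
#' selected N maximises the distance below the descending diagonal from
#' `(0, 1)` to `(1, 0)` -- the point of maximum curvature of the decreasing
#' cost curve, i.e. the smallest model order with near-asymptotic fit.
#' Ties break toward the smaller N; a constant curve returns the smallest N
#' with a warning.
#'
#' @param cost_curve Cost values `J(N)`, one per candidate N.
#' @param n_range The candidate N values (same length).
#' @return The selected count `n_star`.
#' @export
#' @examples
#' select_optimal_n(c(1.0, 0.2, 0.1, 0.05), 1:4)  # 2
select_optimal_n <- function(cost_curve, n_range = seq_along(cost_curve)) {
  stopifnot(length(cost_curve) == length(n_range), length(cost_curve) >= 3,
            all(is.finite(cost_curve)))
  rng <- diff(range(cost_curve))
  if (rng < .Machine$double.eps * max(abs(cost_curve), 1)) {
    warning("select_optimal_n: constant cost curve; returning smallest N")
    return(n_range[1])
  }
  x <- (n_range - min(n_range)) / diff(range(n_range))
  y <- (cost_curve - min(cost_curve)) / rng
  d <- 1 - x - y  # proportional to perpendicular distance below the diagonal
  n_range[which.max(d - seq_along(d) * 1e-12)]  # exact ties -> smaller N
}

# Pooled percent variance accounted for of reconstructed vs measured velocity.
recon_vaf <- function(subs, trial) {
  R <- superpose(subs, trial$t)
  sse <- sum((trial$v - R)^2)
  sst <- sum(sweep(trial$v, 2, colMeans(trial$v))^2)
  100 * (1 - sse / sst)
}

#' Decompose a reach into its optimal submovement set
#'
#' Runs [decompose_fixed_n()] over `cfg$n_range`, warm-starting each N + 1
#' fit from the N fit plus one new submovement (a zero-amplitude one, which
#' makes the cost curve non-increasing by construction, and one placed at
#' the residual-speed peak), then selects the optimal count with
#' [select_optimal_n()].
#'
#' @param trial A preprocessed, differentiated [reach_trial()].
#' @param cfg A [decomposition_config()].
#' @return Object of class `decomposition_result`: list with `n_star`,
#'   `submovements`, `cost_curve`, `fits` (per-N submovement lists),
#'   `recon_vaf` (percent) and `n_range`.
#' @export
decompose_reach <- function(trial, cfg = decomposition_config()) {
  fits <- list(); costs <- numeric(length(cfg$n_range))
  prev <- NULL
  t_end <- trial$t[length(trial$t)]
  for (i in seq_along(cfg$n_range)) {
    N <- cfg$n_range[i]
    warm <- NULL
    if (!is.null(prev) && length(prev$subs) == N - 1) {
      # zero-amplitude extension: cost identical to the N-1 fit
      pad0 <- c(prev$subs, list(submovement(0, cfg$d_min, c(0, 0, 0))))
      resid <- trial$v - superpose(prev$subs, trial$t)
      k <- which.max(sqrt(rowSums(resid^2)))
      t0 <- min(max(trial$t[k] - 0.15, 0), max(t_end - cfg$d_min, 0.01))
      win <- trial$t >= t0 & trial$t <= t0 + 0.3
      Aj <- colSums(resid[win, , drop = FALSE]) * (trial$t[2] - trial$t[1])
      padP <- c(prev$subs, list(submovement(t0, 0.3, Aj)))
      warm <- list(pad0, padP)
    }
    fit <- decompose_fixed_n(trial, N, cfg, warm_start = warm)
    fits[[i]] <- fit$subs
    costs[i] <- fit$cost
    prev <- fit
  }
  j_empty <- sum(trial$v^2) * (trial$t[2] - trial$t[1])
  n_star <- if (costs[1] < cfg$flat_tol * j_empty) cfg$n_range[1]
            else select_optimal_n(costs, cfg$n_range)
  subs <- fits[[match(n_star, cfg$n_range)]]
  structure(list(trial_id = trial$trial_id, n_star = n_star,
                 submovements = subs, cost_curve = costs,
                 fits = fits, n_range = cfg$n_range,
                 recon_vaf = recon_vaf(subs, trial)),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("decomposition: n* = %d (VAF %.1f%%), cost curve over N = %s\n",
              x$n_star, x$recon_vaf,
              paste(signif(x$cost_curve, 3), collapse = ", ")))
  invisible(x)
}

#' Decompose every trial of a dataset
#'
#' @param dataset A preprocessed `reach_dataset`.
#' @param cfg A [decomposition_config()].
#' @param verbose Print one line per trial.
#' @return List of `decomposition_result`, one per trial.
#' @export
decompose_dataset <- function(dataset, cfg = decomposition_config(),
                              verbose = FALSE) {
  stopifnot(inherits(dataset, "reach_dataset"))
  lapply(dataset$trials, function(tr) {
    r <- decompose_reach(tr, cfg)
    if (verbose)
      message(sprintf("trial %s: n*=%d vaf=%.1f", tr$trial_id, r$n_star,
                      r$recon_vaf))
    r
  })
}
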