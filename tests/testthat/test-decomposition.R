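# Decomposition cost, fixed-N fitting, knee selection and full per-reach
# decomposition.

test_that("reconstruction cost is zero for a perfect same-signed fit", {
  subs <- list(submovement(0, 0.6, c(30, 5, 2)),
               submovement(0.5, 0.4, c(8, 2, 3)))
  tr <- closed_form_trial(subs)
  expect_lt(reconstruction_cost(subs, tr) /
              reconstruction_cost(list(), tr), 1e-8)
})

test_that("the empty decomposition costs the full signal power", {
  s <- submovement(0, 0.6, c(30, 0, 0))
  tr <- closed_form_trial(list(s))
  dt <- tr$t[2] - tr$t[1]
  expect_equal(reconstruction_cost(list(), tr), sum(tr$v^2) * dt)
})

test_that("opposing simultaneous submovements are penalised", {
  # a fully overlapping +A/-A pair sums to zero velocity, so it leaves the
  # squared-error term unchanged but incurs the overlap penalty
  real <- submovement(1.0, 0.4, c(10, 0, 0))
  tr <- closed_form_trial(list(real), t_end = 1.6)
  pair <- list(submovement(0, 0.5, c(10, 0, 0)),
               submovement(0, 0.5, c(-10, 0, 0)))
  cfg <- decomposition_config(lambda_overlap = 0.01)
  got <- reconstruction_cost(pair, tr, cfg)
  base <- reconstruction_cost(list(), tr, cfg)
  # quadrature oracle: penalty integrand is |v1| + |v2| = 2|v1|
  v1 <- minjerk_velocity(pair[[1]], tr$t)
  lambda <- 0.01 * max(sqrt(rowSums(tr$v^2)))
  expect_gt(got, base)
  expect_equal(got - base, lambda * trapz(tr$t, 2 * abs(v1[, 1])),
               tolerance = 1e-3)
})

test_that("a single noiseless submovement is recovered within tight tolerances", {
  s <- submovement(0.1, 0.6, c(30, -8, 12))
  tr <- closed_form_trial(list(s), t_end = 1.2)
  fit <- decompose_fixed_n(tr, 1, fast_decomp_cfg())
  expect_lt(abs(fit$subs[[1]]$t0 - 0.1), 0.02)
  expect_lt(abs(fit$subs[[1]]$D - 0.6), 0.05)
  expect_lt(max(abs(fit$subs[[1]]$A - s$A)), 0.5)
  expect_equal(fit$cost, reconstruction_cost(fit$subs, tr, fast_decomp_cfg()),
               tolerance = 1e-8)
})

test_that("two well-separated submovements are recovered at N = 2", {
  subs <- list(submovement(0, 0.5, c(30, 0, 10)),
               submovement(0.8, 0.4, c(8, 4, -2)))
  tr <- closed_form_trial(subs, t_end = 1.6)
  fit <- decompose_fixed_n(tr, 2, fast_decomp_cfg())
  got <- fit$subs[order(vapply(fit$subs, `[[`, 0, "t0"))]
  for (j in 1:2) {
    expect_lt(abs(got[[j]]$t0 - subs[[j]]$t0), 0.02)
    expect_lt(abs(got[[j]]$D - subs[[j]]$D), 0.05)
    expect_lt(max(abs(got[[j]]$A - subs[[j]]$A)), 0.5)
  }
})

test_that("N = 1 fit matches an exhaustive coarse grid search", {
  s <- submovement(0.15, 0.55, c(28, 0, 0))
  tr <- closed_form_trial(list(s), t_end = 1.2)
  cfg <- fast_decomp_cfg()
  fit <- decompose_fixed_n(tr, 1, cfg)
  best <- Inf; best_par <- NULL
  for (t0 in seq(0, 0.4, by = 0.05))
    for (D in seq(0.3, 1, by = 0.05))
      for (a in seq(20, 36, by = 1)) {
        cost <- reconstruction_cost(list(submovement(t0, D, c(a, 0, 0))),
                                    tr, cfg)
        if (cost < best) { best <- cost; best_par <- c(t0, D, a) }
      }
  expect_lte(fit$cost, best + 1e-8)
  expect_lt(abs(fit$subs[[1]]$t0 - best_par[1]), 0.05)
  expect_lt(abs(fit$subs[[1]]$D - best_par[2]), 0.05)
  expect_lt(abs(fit$subs[[1]]$A[1] - best_par[3]), 1)
})

test_that("knee selection follows the normalised-diagonal geometry", {
  expect_equal(select_optimal_n(c(1.0, 0.2, 0.1, 0.05), 1:4), 2)
  expect_equal(select_optimal_n(c(1.0, 0.0, 0.0, 0.0), 1:4), 2)
  # strictly linear descent: all distances zero, tie goes to the smallest N
  expect_equal(select_optimal_n(c(4, 3, 2, 1), 1:4), 1)
  expect_warning(n <- select_optimal_n(c(1, 1, 1, 1), 1:4), "constant")
  expect_equal(n, 1)
  expect_error(select_optimal_n(c(1, 0.5), 1:2), "3")
})

test_that("a noiseless one-submovement reach selects a minimal model", {
  truth <- list(start = c(0, 0, 0), target = c(30, 0, 0),
                submovements = list(submovement(0, 0.6, c(30, 0, 0))))
  tr <- differentiate(preprocess(render_trial(truth,
                                              generator_config(noise_sd = 0),
                                              1)))
  res <- decompose_reach(tr, fast_decomp_cfg(4))
  expect_true(res$n_star %in% c(1, 2))
  expect_gte(res$recon_vaf, 99.9)
})

test_that("cost curves are non-increasing in N and the true count is selected", {
  set.seed(31)
  truth <- sample_reach(generator_config())
  tr <- differentiate(preprocess(render_trial(truth, generator_config(), 1)))
  res <- decompose_reach(tr, fast_decomp_cfg(8, seed = 31))
  expect_true(all(diff(res$cost_curve) <= 1e-6))
  expect_equal(res$n_star, length(truth$submovements))
  expect_gte(res$recon_vaf, 95)
})

test_that("decomposition is deterministic under a fixed seed", {
  set.seed(8)
  truth <- sample_reach()
  tr <- differentiate(preprocess(render_trial(truth, generator_config(), 1)))
  r1 <- decompose_reach(tr, fast_decomp_cfg(5, seed = 4))
  r2 <- decompose_reach(tr, fast_decomp_cfg(5, seed = 4))
  expect_identical(r1$cost_curve, r2$cost_curve)
  expect_identical(r1$submovements, r2$submovements)
})
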