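# Closed-form minimum-jerk basis functions and their superposition.

test_that("minimum-jerk velocity has the canonical peak, support and integral", {
  s <- submovement(0, 1, c(10, 0, 0))
  expect_equal(minjerk_velocity(s, 0.5)[1, ], c(30 / 16 * 10, 0, 0))
  # zero outside (and exactly at) the closed support
  expect_equal(minjerk_velocity(s, c(-0.01, 0, 1, 1.01)),
               matrix(0, 4, 3))
  # displacement conservation: trapezoidal integral of v equals A
  t <- seq(0, 1, by = 0.001)
  v <- minjerk_velocity(s, t)
  expect_equal(trapz(t, v[, 1]), 10, tolerance = 1e-6)
  expect_equal(trapz(t, v[, 2]), 0)
})

test_that("speed profile is C1 at the boundaries", {
  s <- submovement(0.2, 0.5, c(5, -3, 2))
  eps <- 1e-6
  v_in <- minjerk_velocity(s, c(0.2 + eps, 0.7 - eps))
  # the shape's first derivative vanishes at the boundaries, so velocity
  # eps inside the support is O(eps^2), far below O(eps)
  expect_lt(max(abs(v_in)), 1e-8)
})

test_that("submovement validation enforces the 0.1 s minimum duration", {
  expect_error(submovement(0, 0.05, c(1, 0, 0)), "0.1")
  expect_error(submovement(-0.1, 0.5, c(1, 0, 0)), "t0")
  expect_error(submovement(0, 0.5, c(1, NA, 0)), "finite")
  expect_error(submovement(0, 0.5, c(1, 0)), "3-vector")
})

test_that("superposition is the linear pointwise sum", {
  t <- seq(0, 1.5, by = 0.01)
  expect_equal(superpose(list(), t), matrix(0, length(t), 3))
  s1 <- submovement(0, 0.6, c(30, 5, -4))
  expect_equal(superpose(list(s1), t), minjerk_velocity(s1, t))
  expect_equal(superpose(list(s1, s1), t), 2 * minjerk_velocity(s1, t))
})

test_that("position trajectory matches the closed-form displacement", {
  t <- seq(0, 1.5, by = 0.01)
  start <- c(1, 2, 3)
  expect_equal(position_trajectory(list(), start, t),
               matrix(rep(start, each = length(t)), ncol = 3))
  s <- submovement(0, 1, c(10, 0, 0))
  expect_equal(position_trajectory(list(s), start, 0.5)[1, ],
               start + c(5, 0, 0))
  # telescoping: sum of amplitudes equal to target - start ends on target
  subs <- list(submovement(0, 0.6, c(20, 0, 5)),
               submovement(0.4, 0.4, c(10, 0, -5)))
  p_end <- position_trajectory(subs, start, 1.2)[1, ]
  expect_equal(p_end, start + c(30, 0, 0))
})

test_that("displacement conservation and velocity consistency hold for random sets", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    subs <- lapply(seq_len(n), function(i)
      submovement(runif(1, 0, 1), runif(1, 0.1, 0.8), rnorm(3, 0, 15)))
    t <- seq(0, 2.5, by = 0.01)
    p <- position_trajectory(subs, c(0, 0, 0), t)
    A_sum <- Reduce(`+`, lapply(subs, `[[`, "A"))
    expect_lt(max(abs(p[nrow(p), ] - A_sum)), 1e-6)
    # closed-form position equals cumulative trapezoid of velocity to
    # O(dt^2); the trapezoid constant scales with |A| / D^2 per pulse
    v <- superpose(subs, t)
    p_num <- apply(v, 2, function(col)
      c(0, cumsum((head(col, -1) + tail(col, -1)) / 2)) * 0.01)
    bound <- sum(vapply(subs, function(s)
      5 * 0.01^2 * max(abs(s$A)) / s$D^2, 0)) + 1e-9
    expect_lt(max(abs(p - p_num)), bound)
  }
})
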