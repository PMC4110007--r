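# Closed-loop simulator contracts, exercised with stub predictors whose
# behaviour is known exactly.

remaining_from_features <- function(f, dk) {
  -c(f["diff_G_EI_x"], f["diff_G_EI_y"], f["diff_G_EI_z"]) * dk
}

stub_nets <- function(initiation = function(f) 0,
                      amplitude = function(f, dk) remaining_from_features(f, dk),
                      duration = function(f) 0.5) {
  list(initiation = initiation, amplitude = amplitude, duration = duration)
}

test_that("an exact-amplitude stub hits with one submovement and zero end distance", {
  s <- simulate_reach(stub_nets(), c(0, 0, 0), c(20, 10, 30))
  expect_true(s$success)
  expect_equal(s$n_submovements, 1)
  expect_lt(s$end_distance, 1e-9)
  # success requires a full one-second dwell; the fingertip enters the
  # target sphere slightly before the 0.5 s submovement completes
  expect_gte(s$movement_time, 1.0)
  expect_lte(s$movement_time, 1.51)
})

test_that("an always-firing stub fails at exactly the 30-submovement cap", {
  nets <- stub_nets(initiation = function(f) 1,
                    amplitude = function(f, dk) c(0.1, 0, 0))
  s <- simulate_reach(nets, c(0, 0, 0), c(40, 0, 0))
  expect_false(s$success)
  expect_equal(s$failure_reason, "submovement-cap")
  expect_equal(s$n_submovements, 30)
})

test_that("a zero-amplitude stub times out at 3 s with the full distance remaining", {
  nets <- stub_nets(amplitude = function(f, dk) c(0, 0, 0))
  s <- simulate_reach(nets, c(0, 0, 0), c(30, 0, 40))
  expect_false(s$success)
  expect_equal(s$failure_reason, "timeout")
  expect_equal(s$movement_time, 3.0)
  expect_equal(s$end_distance, 50)
})

test_that("simulation is deterministic for fixed predictors and endpoints", {
  nets <- stub_nets(initiation = function(f)
    if (f["t_since_start"] > 0.3 && f["in_target_planned"] < 1) 0.9 else 0.1)
  s1 <- simulate_reach(nets, c(0, 0, 0), c(25, 5, 15))
  s2 <- simulate_reach(nets, c(0, 0, 0), c(25, 5, 15))
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$n_submovements, s2$n_submovements)
})

test_that("closed-loop evaluation reports exact-match trajectories as perfect", {
  # measured trials that equal the stub's generated trajectory
  trials <- lapply(1:3, function(i) {
    target <- c(10 * i, 5, 20)
    D <- 0.5
    sub <- submovement(0, D, target)
    t <- seq(0, 1.6, by = 0.01)
    tr <- reach_trial(i, t, position_trajectory(list(sub), c(0, 0, 0), t),
                      target = target, start = c(0, 0, 0))
    tr$v <- superpose(list(sub), t); tr$a <- superpose_acceleration(list(sub), t)
    tr
  })
  ev <- evaluate_closed_loop(stub_nets(), trials)
  expect_equal(ev$acquisition_rate, 100)
  expect_gt(ev$vaf, 99.99)
  expect_lt(ev$rmse, 1e-6)
  expect_equal(nrow(ev$per_trial), 3)
})

test_that("acquisition rate is the success ratio", {
  trials <- lapply(1:2, function(i) {
    target <- c(30, 0, 0)
    sub <- submovement(0, 0.5, target)
    t <- seq(0, 1.6, by = 0.01)
    reach_trial(i, t, position_trajectory(list(sub), c(0, 0, 0), t),
                target = target, start = c(0, 0, 0))
  })
  ev_fail <- evaluate_closed_loop(stub_nets(amplitude = function(f, dk)
    c(0, 0, 0)), trials)
  expect_equal(ev_fail$acquisition_rate, 0)
  ev_ok <- evaluate_closed_loop(stub_nets(), trials)
  expect_equal(ev_ok$acquisition_rate, 100)
})
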