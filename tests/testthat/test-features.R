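# Causal feature construction: DTTAPS, transforms, the three feature
# vectors and the training tables.

test_that("DTTAPS follows the prior-submovement accounting with a floor", {
  expect_equal(dttaps(c(0, 0, 0), c(30, 0, 40), list()), 50)
  expect_equal(dttaps(c(0, 0, 0), c(10, 0, 0),
                      list(submovement(0, 0.5, c(6, 0, 0)))), 4)
  # priors summing exactly to the target hit the divisor floor
  expect_equal(dttaps(c(0, 0, 0), c(10, 0, 0),
                      list(submovement(0, 0.5, c(10, 0, 0)))), 0.1)
})

test_that("scalar transforms match their closed forms", {
  expect_equal(signed_fourth_root(16), 2)
  expect_equal(signed_fourth_root(-16), -2)
  expect_equal(signed_fourth_root(0), 0)
  expect_equal(time_decay(0), 1)
  expect_equal(time_decay(0.05), exp(-1))
  expect_equal(time_decay(1), exp(-20))
})

test_that("initiation features have the documented 21-value layout", {
  s <- submovement(0, 0.6, c(30, 0, 0))
  f <- build_initiation_features(c(0, 0, 0), c(40, 0, 0), c(5, 0, 0),
                                 list(s), t_now = 0)
  expect_length(f, 21)
  expect_equal(sum(grepl("^dist_", names(f))), 15)
  # at the instant the submovement starts
  expect_equal(unname(f["t_since_start"]), 0)
  expect_equal(unname(f["t_decay"]), 1)
  expect_equal(unname(f["t_remaining_norm"]), 1)
  expect_equal(unname(f["in_target_now"]), 0)
  # fingertip within the 1.27 cm target radius flips the flag
  f2 <- build_initiation_features(c(0, 0, 0), c(40, 0, 0), c(39.5, 0, 0),
                                  list(s), t_now = 0.3)
  expect_equal(unname(f2["in_target_now"]), 1)
})

test_that("amplitude features are 24 DTTAPS-normalised values", {
  af <- build_amplitude_features(c(0, 0, 0), c(50, 0, 0), c(0, 0, 0),
                                 c(0, 0, 0), list(), t_now = 0)
  expect_length(af$features, 24)
  expect_equal(af$dttaps, 50)
  # start-to-target difference self-normalises to a unit vector
  expect_equal(unname(af$features[c("diff_S_G_x", "diff_S_G_y",
                                    "diff_S_G_z")]), c(1, 0, 0))
  expect_true(all(af$features[c("v4_x", "v4_y", "v4_z",
                                "a4_x", "a4_y", "a4_z")] == 0))
})

test_that("duration features are 12 values, zero in the degenerate cases", {
  d <- build_duration_features(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                               c(0, 0, 0), list(), 0, A_cur = c(0, 0, 0))
  expect_length(d, 12)
  expect_true(all(d == 0))
})

test_that("training tables have one parameter row per submovement and dense initiation rows", {
  subs <- list(submovement(0, 0.5, c(25, 0, 5)),
               submovement(0.4, 0.3, c(8, 0, -2)),
               submovement(0.75, 0.3, c(3, 0, 1)))
  tr <- closed_form_trial(subs, t_end = 1.3)
  ds <- structure(list(participant_id = "x", trials = list(tr),
                       provenance = list()), class = "reach_dataset")
  dec <- list(structure(list(n_star = 3, submovements = subs),
                        class = "decomposition_result"))
  tb <- build_training_tables(ds, dec)
  expect_equal(nrow(tb$amplitude$x), 3)
  expect_equal(nrow(tb$duration$x), 3)
  expect_equal(ncol(tb$initiation$x), 21)
  expect_equal(ncol(tb$amplitude$x), 24)
  expect_equal(ncol(tb$duration$x), 12)
  # labels are 0 strictly before the next onset
  m <- tb$initiation$meta
  before <- which(m$k == 1 & m$t < 0.4)
  expect_true(all(tb$initiation$y[before, 1] == 0))
  at_after <- which(m$k == 1 & m$t >= 0.4)
  expect_true(all(tb$initiation$y[at_after, 1] == 1))
  # amplitude labels are the decomposed amplitudes over DTTAPS
  # (target sits at start + sum(A) = (36, 0, 4) for this fixture)
  expect_equal(unname(tb$amplitude$y[1, ]),
               c(25, 0, 5) / sqrt(36^2 + 4^2))
})

test_that("a single-window reach yields one initiation row per timestep", {
  s <- submovement(0, 1.5, c(30, 0, 0))
  t <- seq(0, 1.49, by = 0.01)
  tr <- reach_trial(1, t, position_trajectory(list(s), c(0, 0, 0), t),
                    target = c(30, 0, 0), start = c(0, 0, 0))
  tr$v <- superpose(list(s), t); tr$a <- superpose_acceleration(list(s), t)
  ds <- structure(list(participant_id = "x", trials = list(tr),
                       provenance = list()), class = "reach_dataset")
  dec <- list(list(n_star = 1, submovements = list(s)))
  tb <- build_training_tables(ds, dec)
  expect_equal(nrow(tb$initiation$x), 150)
  expect_true(all(tb$initiation$y == 0))
})

test_that("first-submovement amplitude labels reflect undershoot", {
  co <- synth_corpus(15, seed = 6)
  firsts <- vapply(co$truth, function(tr) {
    a1 <- sqrt(sum(tr$submovements[[1]]$A^2))
    d <- sqrt(sum((tr$target - tr$start)^2))
    a1 / d
  }, 0)
  expect_true(all(firsts <= 1.3))
  expect_gt(mean(firsts < 1), 0.8)
})
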