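# Fold assignment, target encodings, trigger decoding, training machinery
# and model serialisation.

test_that("folds partition reaches 80:10:10 and are seed-deterministic", {
  fl <- make_folds(100, 10, seed = 1)
  tests <- lapply(fl$folds, `[[`, "test")
  expect_true(all(lengths(tests) == 10))
  expect_setequal(unlist(tests), 1:100)
  expect_equal(sum(lengths(tests)), 100)  # covers each reach exactly once
  for (f in fl$folds) {
    expect_length(f$validation, 10)
    expect_length(f$train, 80)
    expect_length(intersect(f$train, c(f$validation, f$test)), 0)
  }
  expect_identical(fl$assignment, make_folds(100, 10, seed = 1)$assignment)
  expect_false(identical(fl$assignment, make_folds(100, 10, seed = 2)$assignment))
  expect_error(make_folds(7, 10), "at least")
})

test_that("trigger decoding fires at the first strict threshold crossing", {
  expect_equal(decode_trigger(c(0.1, 0.3, 0.6, 0.9)), 3L)
  expect_true(is.na(decode_trigger(c(0.1, 0.2, 0.5))))
  expect_equal(decode_trigger(c(0.5, 0.51)), 2L)  # exactly 0.5 never triggers
  # raising a sub-threshold value never makes the trigger earlier than the
  # first true crossing
  p <- c(0.1, 0.2, 0.7, 0.4)
  p2 <- p; p2[4] <- 0.49
  expect_gte(decode_trigger(p2), decode_trigger(p))
})

test_that("amplitude and duration encodings round-trip", {
  r <- 1.3
  a <- c(-1.2, 0, 0.7)
  expect_equal(submovekit:::amp_decode(submovekit:::amp_encode(a, r), r), a)
  # logistic midpoint maps to zero amplitude
  expect_equal(submovekit:::amp_decode(c(0.5, 0.5, 0.5), 1), c(0, 0, 0))
})

test_that("network specs match the fixed architectures", {
  expect_equal(network_spec("initiation")[c("n_inputs", "n_hidden", "n_outputs")],
               list(n_inputs = 21L, n_hidden = 5L, n_outputs = 1L))
  expect_equal(network_spec("amplitude")[c("n_inputs", "n_hidden", "n_outputs")],
               list(n_inputs = 24L, n_hidden = 10L, n_outputs = 3L))
  expect_equal(network_spec("duration")[c("n_inputs", "n_hidden", "n_outputs")],
               list(n_inputs = 12L, n_hidden = 10L, n_outputs = 1L))
})

test_that("training fits a simple nonlinear target and rejects mismatched input", {
  set.seed(4)
  X <- matrix(rnorm(800 * 4), 800)
  y <- 1 / (1 + exp(-(X[, 1] - 0.5 * X[, 2] + 0.2 * X[, 3] * X[, 4])))
  net <- train_net(X, cbind(y), 5, val_idx = 701:800,
                   cfg = training_config(l2 = 0, max_epochs = 1500, seed = 4))
  pred <- submovekit:::mlp_forward(net, X[1:700, ])$Y
  expect_gt(vaf(y[1:700], as.numeric(pred)), 95)
})

test_that("predictors validate feature-vector length", {
  co <- synth_corpus(12, seed = 12)
  ds <- preprocess_dataset(co$dataset)
  dec <- lapply(seq_along(ds$trials), function(i)
    list(n_star = length(co$truth[[i]]$submovements),
         submovements = co$truth[[i]]$submovements))
  tb <- build_training_tables(ds, dec)
  cfg <- training_config(max_epochs = 50, seed = 12)
  p <- fit_predictor(tb$duration, 1:10, 11:12, cfg)
  expect_error(predict_duration(p, rnorm(5)), "mismatch")
  expect_equal(predict_duration(p, tb$duration$x[1, ]),
               predict_duration(p, tb$duration$x[1, ]))  # deterministic
  expect_gte(predict_duration(p, tb$duration$x[1, ]), 0.1)
})

test_that("models round-trip through JSON serialisation", {
  co <- synth_corpus(12, seed = 13)
  ds <- preprocess_dataset(co$dataset)
  dec <- lapply(seq_along(ds$trials), function(i)
    list(n_star = length(co$truth[[i]]$submovements),
         submovements = co$truth[[i]]$submovements))
  tb <- build_training_tables(ds, dec)
  nets <- train_submovement_nets(tb, 1:10, 11:12,
                                 training_config(max_epochs = 60, seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(nets, path)
  nets2 <- load_model(path)
  x <- tb$amplitude$x[1, ]
  expect_equal(predict_amplitude(nets$amplitude, x, 10),
               predict_amplitude(nets2$amplitude, x, 10), tolerance = 1e-12)
  expect_equal(predict_initiation(nets$initiation, tb$initiation$x[5, ]),
               predict_initiation(nets2$initiation, tb$initiation$x[5, ]),
               tolerance = 1e-12)
})

test_that("our trainer is comparable to an independent single-hidden-layer fit", {
  skip_if_not_installed("nnet")
  set.seed(21)
  X <- matrix(rnorm(600 * 6), 600)
  y <- 1 / (1 + exp(-(X[, 1] - X[, 2] + 0.5 * X[, 3] * X[, 4])))
  net <- train_net(X, cbind(y), 10, val_idx = 501:600,
                   cfg = training_config(l2 = 0, max_epochs = 1500, seed = 21))
  ours <- vaf(y[1:500],
              as.numeric(submovekit:::mlp_forward(net, X[1:500, ])$Y))
  ref <- nnet::nnet(X[1:500, ], y[1:500], size = 10, linout = FALSE,
                    maxit = 500, trace = FALSE, decay = 0)
  theirs <- vaf(y[1:500], as.numeric(ref$fitted.values))
  expect_gt(ours, 90)
  expect_gt(ours, theirs - 10)  # within the same quality band
})
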