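# Small feed-forward networks (one tanh hidden layer, logistic outputs)
# trained full-batch with Adam and early stopping on a validation set, plus
# the 10-fold 80:10:10 cross-validation harness. Splits are by reach, never
# by row, so no reach leaks between training and testing.

#' Network architecture for one predictor
#'
#' Architectures are fixed per predictor: initiation uses 5 hidden units and
#' one logistic output (thresholded at 0.5 to decode a trigger), amplitude
#' uses 10 hidden units and three logistic outputs, duration uses 10 hidden
#' units and one logistic output. Hidden activations are hyperbolic tangent.
#'
#' @param kind One of `"initiation"`, `"amplitude"`, `"duration"`.
#' @return List with `n_inputs`, `n_hidden`, `n_outputs`, `kind`.
#' @export
network_spec <- function(kind = c("initiation", "amplitude", "duration")) {
  kind <- match.arg(kind)
  switch(kind,
    initiation = list(n_inputs = 21L, n_hidden = 5L, n_outputs = 1L,
                      kind = kind),
    amplitude = list(n_inputs = 24L, n_hidden = 10L, n_outputs = 3L,
                     kind = kind),
    duration = list(n_inputs = 12L, n_hidden = 10L, n_outputs = 1L,
                    kind = kind))
}

#' Training configuration
#'
#' @param n_folds Number of cross-validation folds.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param max_epochs Epoch cap.
#' @param lr Adam learning rate.
#' @param l2 L2 weight-decay coefficient on the connection weights
#'   (regularises the parameter-rich amplitude/duration networks, whose
#'   training tables have only a few rows per reach).
#' @param seed RNG seed for weight initialisation and fold assignment.
#' @param d_scale Duration scaling constant (s): duration targets are encoded
#'   as `D / d_scale` for the logistic output.
#' @return Object of class `training_config`.
#' @export
training_config <- function(n_folds = 10, patience = 200, max_epochs = 4000,
                            lr = 0.005, l2 = 1e-3, seed = 0, d_scale = 2.0) {
  structure(list(n_folds = n_folds, patience = patience,
                 max_epochs = max_epochs, lr = lr, l2 = l2, seed = seed,
                 d_scale = d_scale),
            class = "training_config")
}

#' Assign reaches to cross-validation folds (80:10:10 by reach)
#'
#' Reaches are shuffled and dealt round-robin into `n_folds` groups. Fold `f`
#' tests on group `f`, validates on group `f + 1` (mod `n_folds`) and trains
#' on the remaining groups, so with 10 folds the split is 80:10:10 and the
#' union of test sets covers every reach exactly once.
#'
#' @param n_reaches Number of reaches (`>= n_folds`).
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return List with `assignment` (group per reach) and `folds`, a list of
#'   `list(train, validation, test)` reach-index vectors.
#' @export
make_folds <- function(n_reaches, n_folds = 10, seed = 0) {
  if (n_reaches < n_folds)
    stop("make_folds: need at least ", n_folds, " reaches", call. = FALSE)
  set.seed(seed)
  grp <- rep_len(seq_len(n_folds), n_reaches)[order(stats::runif(n_reaches))]
  folds <- lapply(seq_len(n_folds), function(f) {
    val <- f %% n_folds + 1L
    list(test = which(grp == f), validation = which(grp == val),
         train = which(grp != f & grp != val))
  })
  list(assignment = grp, folds = folds)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(n_in, n_hidden, n_out, seed = 0) {
  set.seed(seed)
  lim1 <- sqrt(6 / (n_in + n_hidden)); lim2 <- sqrt(6 / (n_hidden + n_out))
  list(W1 = matrix(stats::runif(n_in * n_hidden, -lim1, lim1), n_in, n_hidden),
       b1 = numeric(n_hidden),
       W2 = matrix(stats::runif(n_hidden * n_out, -lim2, lim2), n_hidden,
                   n_out),
       b2 = numeric(n_out))
}

mlp_forward <- function(net, X) {
  H <- tanh(sweep(X %*% net$W1, 2, net$b1, `+`))
  Y <- sigmoid(sweep(H %*% net$W2, 2, net$b2, `+`))
  list(H = H, Y = Y)
}

mlp_loss_grad <- function(net, X, Y) {
  fw <- mlp_forward(net, X)
  n <- nrow(X)
  err <- fw$Y - Y
  loss <- mean(err^2)
  dZ2 <- (2 / length(Y)) * err * fw$Y * (1 - fw$Y)
  dH <- dZ2 %*% t(net$W2)
  dZ1 <- dH * (1 - fw$H^2)
  list(loss = loss,
       gW1 = t(X) %*% dZ1, gb1 = colSums(dZ1),
       gW2 = t(fw$H) %*% dZ2, gb2 = colSums(dZ2))
}

#' Train a feed-forward network with early stopping
#'
#' Full-batch Adam minimising mean squared error; training stops when the
#' validation loss has not improved for `patience` epochs (or at
#' `max_epochs`) and the best-validation weights are returned.
#'
#' @param x Numeric feature matrix (already standardised).
#' @param y Numeric target matrix, entries in `[0, 1]`.
#' @param n_hidden Hidden-layer width.
#' @param val_idx Row indices used for validation (never trained on).
#' @param cfg A [training_config()].
#' @param seed Weight-initialisation seed (defaults to `cfg$seed`).
#' @return List with the weights (`W1`, `b1`, `W2`, `b2`), `n_epochs` run and
#'   `val_loss` at the returned weights.
#' @export
train_net <- function(x, y, n_hidden, val_idx, cfg = training_config(),
                      seed = cfg$seed) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), length(val_idx) >= 1)
  tr <- setdiff(seq_len(nrow(x)), val_idx)
  Xt <- x[tr, , drop = FALSE]; Yt <- y[tr, , drop = FALSE]
  Xv <- x[val_idx, , drop = FALSE]; Yv <- y[val_idx, , drop = FALSE]
  net <- mlp_init(ncol(x), n_hidden, ncol(y), seed)
  m <- lapply(net, function(w) w * 0); v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- net; best_loss <- Inf; wait <- 0; epoch <- 0
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1
    g <- mlp_loss_grad(net, Xt, Yt)
    if (!is.finite(g$loss))
      stop("train_net: divergence (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    gl <- list(W1 = g$gW1 + cfg$l2 * net$W1, b1 = g$gb1,
               W2 = g$gW2 + cfg$l2 * net$W2, b2 = g$gb2)
    for (k in names(net)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * gl[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * gl[[k]]^2
      mh <- m[[k]] / (1 - b1^epoch); vh <- v[[k]] / (1 - b2^epoch)
      net[[k]] <- net[[k]] - cfg$lr * mh / (sqrt(vh) + eps)
    }
    vl <- mean((mlp_forward(net, Xv)$Y - Yv)^2)
    if (vl < best_loss - 1e-9) {
      best_loss <- vl; best <- net; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }
  c(best, list(n_epochs = epoch, val_loss = best_loss))
}

# z-score scaler fitted on training rows; also records the training range,
# to which inputs are clamped at prediction time so that closed-loop states
# outside the training distribution cannot drive the network into wild
# extrapolation.
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  list(center = ctr, scale = scl,
       xmin = apply(x, 2, min), xmax = apply(x, 2, max))
}

apply_scaler <- function(x, sc) {
  x <- as.matrix(x)
  if (!is.null(sc$xmin)) {
    lo <- matrix(sc$xmin, nrow(x), ncol(x), byrow = TRUE)
    hi <- matrix(sc$xmax, nrow(x), ncol(x), byrow = TRUE)
    x <- pmin(pmax(x, lo), hi)
  }
  sweep(sweep(x, 2, sc$center), 2, sc$scale, `/`)
}

amp_encode <- function(a, r) (a / r + 1) / 2
amp_decode <- function(y, r) (2 * y - 1) * r

#' Fit one submovement-parameter predictor on given reach sets
#'
#' Standardises features (z-score fitted on training rows only), encodes the
#' targets for the logistic outputs (amplitude: affine map from `[-r, r]`
#' with `r` the largest absolute normalised amplitude in the training fold;
#' duration: division by `d_scale`), and trains the [network_spec()]
#' architecture with [train_net()].
#'
#' @param table A `feature_table` from [build_training_tables()].
#' @param train_reaches,val_reaches Reach-index vectors.
#' @param cfg A [training_config()].
#' @param seed Weight seed.
#' @return Object of class `submove_predictor` carrying the weights, the
#'   scalers, the frozen feature order and the target encoding constants.
#' @export
fit_predictor <- function(table, train_reaches, val_reaches,
                          cfg = training_config(), seed = cfg$seed) {
  stopifnot(inherits(table, "feature_table"))
  spec <- network_spec(table$kind)
  if (ncol(table$x) != spec$n_inputs)
    stop("fit_predictor: expected ", spec$n_inputs, " features, got ",
         ncol(table$x), call. = FALSE)
  idx_tr <- which(table$reach %in% train_reaches)
  idx_va <- which(table$reach %in% val_reaches)
  stopifnot(length(idx_tr) > 0, length(idx_va) > 0)
  sc <- fit_scaler(table$x[idx_tr, , drop = FALSE])
  X <- apply_scaler(table$x, sc)
  y <- as.matrix(table$y)
  enc <- list()
  if (table$kind == "amplitude") {
    enc$r <- max(abs(y[idx_tr, ]))
    y <- amp_encode(y, enc$r)
  } else if (table$kind == "duration") {
    enc$d_scale <- cfg$d_scale
    y <- y / enc$d_scale
  }
  keep <- c(idx_tr, idx_va)
  net <- train_net(X[keep, , drop = FALSE], y[keep, , drop = FALSE],
                   spec$n_hidden,
                   val_idx = seq(length(idx_tr) + 1L, length(keep)),
                   cfg = cfg, seed = seed)
  structure(list(kind = table$kind, spec = spec, net = net, scaler = sc,
                 encoding = enc, feature_names = colnames(table$x)),
            class = "submove_predictor")
}

predictor_raw <- function(pred, x) {
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (ncol(x) != pred$spec$n_inputs)
    stop("predictor: feature length mismatch (expected ",
         pred$spec$n_inputs, ", got ", ncol(x), ")", call. = FALSE)
  mlp_forward(pred$net, apply_scaler(x, pred$scaler))$Y
}

#' Predict submovement-initiation probability
#'
#' @param pred An initiation `submove_predictor`.
#' @param x One 21-feature row or a matrix of rows.
#' @return Probabilities in `(0, 1)`.
#' @export
predict_initiation <- function(pred, x) {
  stopifnot(pred$kind == "initiation")
  as.numeric(predictor_raw(pred, x))
}

#' Decode the trigger time from a probability series
#'
#' The first timestep at which the probability strictly exceeds the
#' threshold; a value exactly at the threshold does not trigger.
#'
#' @param p Probability series.
#' @param threshold Decision threshold, default 0.5.
#' @return Index of the first crossing, or `NA_integer_` if none.
#' @export
decode_trigger <- function(p, threshold = 0.5) {
  i <- which(p > threshold)
  if (length(i) == 0L) NA_integer_ else i[1]
}

#' Predict a submovement amplitude vector
#'
#' Logistic outputs are inverse-mapped through the stored training-fold range
#' `r` and re-scaled by the current DTTAPS.
#'
#' @param pred An amplitude `submove_predictor`.
#' @param x One 24-feature row.
#' @param dttaps_k Current DTTAPS (cm).
#' @return Length-3 amplitude (cm).
#' @export
predict_amplitude <- function(pred, x, dttaps_k) {
  stopifnot(pred$kind == "amplitude", dttaps_k > 0)
  as.numeric(amp_decode(predictor_raw(pred, x), pred$encoding$r)) * dttaps_k
}

#' Predict a submovement duration
#'
#' Logistic output times `d_scale`, clamped at the 0.1 s minimum duration.
#'
#' @param pred A duration `submove_predictor`.
#' @param x One 12-feature row.
#' @return Duration (s), `>= 0.1`.
#' @export
predict_duration <- function(pred, x) {
  stopifnot(pred$kind == "duration")
  max(as.numeric(predictor_raw(pred, x)) * pred$encoding$d_scale, 0.1)
}

#' Train the three predictors on given reach sets
#'
#' @param tables Output of [build_training_tables()].
#' @param train_reaches,val_reaches Reach-index vectors.
#' @param cfg A [training_config()].
#' @return Object of class `trained_nets`: list with `initiation`,
#'   `amplitude`, `duration` predictors.
#' @export
train_submovement_nets <- function(tables, train_reaches, val_reaches,
                                   cfg = training_config()) {
  structure(list(
    initiation = fit_predictor(tables$initiation, train_reaches, val_reaches,
                               cfg, seed = cfg$seed + 1),
    amplitude = fit_predictor(tables$amplitude, train_reaches, val_reaches,
                              cfg, seed = cfg$seed + 2),
    duration = fit_predictor(tables$duration, train_reaches, val_reaches,
                             cfg, seed = cfg$seed + 3)),
    class = "trained_nets")
}

#' Serialise trained networks to a JSON file
#'
#' @param nets A `trained_nets` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(nets, path) {
  ser <- lapply(nets, function(p) list(
    kind = p$kind,
    spec = p$spec,
    W1 = p$net$W1, b1 = p$net$b1, W2 = p$net$W2, b2 = p$net$b2,
    scaler = p$scaler, encoding = p$encoding,
    feature_names = p$feature_names))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load trained networks from JSON
#'
#' @param path Path written by [save_model()].
#' @return A `trained_nets` object.
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  nets <- lapply(ser, function(p) {
    structure(list(kind = p$kind,
                   spec = as.list(p$spec),
                   net = list(W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
                              W2 = as.matrix(p$W2), b2 = as.numeric(p$b2)),
                   scaler = list(center = as.numeric(p$scaler$center),
                                 scale = as.numeric(p$scaler$scale),
                                 xmin = as.numeric(p$scaler$xmin),
                                 xmax = as.numeric(p$scaler$xmax)),
                   encoding = as.list(p$encoding),
                   feature_names = p$feature_names),
              class = "submove_predictor")
  })
  structure(nets, class = "trained_nets")
}
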