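# 10-fold cross-validated evaluation of the three predictors, pooling
# test-fold predictions across folds, with the per-submovement-index
# breakdown used to report performance, and (optionally) closed-loop
# simulation of every test reach with the fold's networks.

safe_vaf <- function(obs, pred) {
  if (NROW(obs) < 2) return(NA_real_)
  tryCatch(vaf(obs, pred), error = function(e) NA_real_)
}

#' Cross-validated evaluation of the submovement predictors
#'
#' For each fold, the three networks are trained on the 80% training reaches
#' (validated on the 10% validation reaches) and applied to the held-out 10%
#' test reaches; predictions from all folds are pooled. Offline metrics:
#' VAF/RMSE of amplitude (3D vectors, cm) and duration (s) per submovement
#' index and overall, VAF of initiation times (relative to the previous
#' submovement's onset, true-positive windows only), and
#' sensitivity/specificity of the trigger decision per feature window (a
#' window whose decomposition contains a next onset counts TP when the
#' network fires, FN otherwise; a final window counts FP when the network
#' fires, TN otherwise). If `sim_cfg` is given, every test reach is also
#' simulated closed-loop with its fold's networks.
#'
#' @param dataset Preprocessed `reach_dataset` (needed for closed-loop
#'   evaluation; may be `NULL` otherwise).
#' @param tables Output of [build_training_tables()].
#' @param cfg A [training_config()].
#' @param sim_cfg Optional [simulation_config()] enabling closed-loop
#'   evaluation.
#' @param feature_cfg A [feature_config()].
#' @return List of pooled metrics; see Details in the package vignette.
#' @export
crossval_evaluate <- function(dataset, tables, cfg = training_config(),
                              sim_cfg = NULL,
                              feature_cfg = feature_config()) {
  n_reaches <- length(unique(tables$initiation$reach))
  fl <- make_folds(n_reaches, cfg$n_folds, cfg$seed)
  amp <- list(); dur <- list(); init <- list()
  sims_obs <- list(); sims_pred <- list(); sims_per <- list()
  nets_by_fold <- list()
  for (f in seq_along(fl$folds)) {
    fold <- fl$folds[[f]]
    fcfg <- cfg; fcfg$seed <- cfg$seed + 100 * f
    nets <- train_submovement_nets(tables, fold$train, fold$validation, fcfg)
    nets_by_fold[[f]] <- nets

    ia <- which(tables$amplitude$reach %in% fold$test)
    if (length(ia) > 0) {
      raw <- predictor_raw(nets$amplitude, tables$amplitude$x[ia, , drop = FALSE])
      dk <- tables$amplitude$meta$dttaps[ia]
      amp[[f]] <- data.frame(
        k = tables$amplitude$meta$k[ia],
        true_x = tables$amplitude$y[ia, 1] * dk,
        true_y = tables$amplitude$y[ia, 2] * dk,
        true_z = tables$amplitude$y[ia, 3] * dk,
        pred_x = amp_decode(raw[, 1], nets$amplitude$encoding$r) * dk,
        pred_y = amp_decode(raw[, 2], nets$amplitude$encoding$r) * dk,
        pred_z = amp_decode(raw[, 3], nets$amplitude$encoding$r) * dk)
    }
    id <- which(tables$duration$reach %in% fold$test)
    if (length(id) > 0) {
      raw <- predictor_raw(nets$duration, tables$duration$x[id, , drop = FALSE])
      dur[[f]] <- data.frame(
        k = tables$duration$meta$k[id],
        true = as.numeric(tables$duration$y[id, 1]),
        pred = pmax(as.numeric(raw) * nets$duration$encoding$d_scale, 0.1))
    }
    ii <- which(tables$initiation$reach %in% fold$test)
    if (length(ii) > 0) {
      p <- predict_initiation(nets$initiation,
                              tables$initiation$x[ii, , drop = FALSE])
      mt <- tables$initiation$meta[ii, ]
      rch <- tables$initiation$reach[ii]
      grp <- split(seq_along(ii), interaction(rch, mt$k, drop = TRUE))
      rows <- lapply(grp, function(g) {
        g <- g[order(mt$t[g])]
        trig <- decode_trigger(p[g])
        t0w <- mt$t[g][1]
        t_next <- mt$t_next[g][1]
        data.frame(has_true = t_next >= 0,
                   fired = !is.na(trig),
                   t_pred = if (is.na(trig)) NA_real_ else mt$t[g][trig] - t0w,
                   t_true = if (t_next >= 0) t_next - t0w else NA_real_,
                   next_k = mt$k[g][1] + 1L)
      })
      init[[f]] <- do.call(rbind, rows)
    }
    if (!is.null(sim_cfg) && !is.null(dataset)) {
      ev <- evaluate_closed_loop(nets, dataset$trials[fold$test], sim_cfg,
                                 feature_cfg)
      for (i in seq_along(ev$sims)) {
        cmp <- compare_trajectories(ev$sims[[i]],
                                    dataset$trials[fold$test][[i]])
        sims_obs[[length(sims_obs) + 1L]] <- cmp$observed
        sims_pred[[length(sims_pred) + 1L]] <- cmp$predicted
      }
      sims_per[[f]] <- ev$per_trial
    }
  }
  amp <- do.call(rbind, amp); dur <- do.call(rbind, dur)
  init <- do.call(rbind, init)

  amp_vaf_k <- function(kk) {
    i <- if (is.null(kk)) seq_len(nrow(amp)) else which(amp$k == kk)
    safe_vaf(as.matrix(amp[i, c("true_x", "true_y", "true_z")]),
             as.matrix(amp[i, c("pred_x", "pred_y", "pred_z")]))
  }
  dur_vaf_k <- function(kk) {
    i <- if (is.null(kk)) seq_len(nrow(dur)) else which(dur$k == kk)
    safe_vaf(dur$true[i], dur$pred[i])
  }
  tp <- sum(init$has_true & init$fired)
  fn <- sum(init$has_true & !init$fired)
  fp <- sum(!init$has_true & init$fired)
  tn <- sum(!init$has_true & !init$fired)
  tpi <- init$has_true & init$fired
  init_vaf_k <- function(kk) {
    i <- if (is.null(kk)) which(tpi) else which(tpi & init$next_k == kk)
    safe_vaf(init$t_true[i], init$t_pred[i])
  }
  out <- list(
    folds = fl,
    nets_by_fold = nets_by_fold,
    initiation = list(
      vaf_2nd = init_vaf_k(2), vaf_3rd = init_vaf_k(3),
      vaf_overall = init_vaf_k(NULL),
      tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_),
    amplitude = list(vaf_1st = amp_vaf_k(1), vaf_2nd = amp_vaf_k(2),
                     vaf_3rd = amp_vaf_k(3), vaf_overall = amp_vaf_k(NULL)),
    duration = list(vaf_1st = dur_vaf_k(1), vaf_2nd = dur_vaf_k(2),
                    vaf_3rd = dur_vaf_k(3), vaf_overall = dur_vaf_k(NULL)),
    tables_rows = c(initiation = nrow(tables$initiation$x),
                    amplitude = nrow(tables$amplitude$x),
                    duration = nrow(tables$duration$x)))
  if (!is.null(sim_cfg) && length(sims_obs) > 0) {
    obs <- do.call(rbind, sims_obs); pred <- do.call(rbind, sims_pred)
    per <- do.call(rbind, sims_per)
    out$closed_loop <- list(
      acquisition_rate = 100 * mean(per$success),
      end_distance_mean = mean(per$end_distance),
      end_distance_sd = stats::sd(per$end_distance),
      end_distance_failed_mean = if (any(!per$success))
        mean(per$end_distance[!per$success]) else NA_real_,
      vaf = vaf(obs, pred), rmse = rmse(obs, pred),
      mean_submovements = mean(per$n_submovements),
      per_trial = per)
  }
  out
}
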