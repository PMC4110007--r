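# Performance metrics: variance accounted for, root-mean-squared error, and
# sensitivity/specificity accounting for predicted submovement events.

#' Variance accounted for (percent)
#'
#' `100 * (1 - sum((y - yhat)^2) / sum((y - mean(y))^2))`. For matrix input
#' (e.g. 3D trajectories) residuals are pooled across columns with per-column
#' observed means. May be negative for predictions worse than the mean.
#'
#' @param observed,predicted Equal-length vectors or equal-dimension
#'   matrices.
#' @return Percent VAF.
#' @export
#' @examples
#' vaf(c(0, 1, 2, 3), c(0, 1, 2, 5))  # 20
vaf <- function(observed, predicted) {
  observed <- as.matrix(observed); predicted <- as.matrix(predicted)
  stopifnot(all(dim(observed) == dim(predicted)), nrow(observed) >= 2)
  sst <- sum(sweep(observed, 2, colMeans(observed))^2)
  if (sst < .Machine$double.eps)
    stop("vaf: observed series is constant; VAF undefined", call. = FALSE)
  100 * (1 - sum((observed - predicted)^2) / sst)
}

#' Root-mean-squared error
#'
#' For matrix input the per-sample residual is the Euclidean distance across
#' columns, so for 3D trajectories the result is the RMS 3D error in cm.
#'
#' @inheritParams vaf
#' @return RMSE in the units of the input.
#' @export
rmse <- function(observed, predicted) {
  observed <- as.matrix(observed); predicted <- as.matrix(predicted)
  stopifnot(all(dim(observed) == dim(predicted)))
  sqrt(mean(rowSums((observed - predicted)^2)))
}

#' Event-matching configuration
#'
#' @param tolerance Maximum time between a predicted trigger and a decomposed
#'   onset for the pair to count as a true positive (s). Default 0.10 s, one
#'   minimum submovement duration.
#' @return Object of class `event_match_config`.
#' @export
event_match_config <- function(tolerance = 0.10) {
  stopifnot(tolerance > 0)
  structure(list(tolerance = tolerance), class = "event_match_config")
}

#' Sensitivity and specificity of submovement-event prediction
#'
#' Greedy one-to-one matching (closest pairs first) of predicted trigger
#' times to true corrective onsets within the tolerance. Matched pairs are
#' true positives; unmatched predictions false positives; unmatched true
#' onsets false negatives. Each reach in which neither the decomposition nor
#' the predictor produced a correction contributes one true negative.
#'
#' @param true_events List (one element per reach) of true corrective-onset
#'   times (s).
#' @param predicted_events List (same length) of predicted trigger times.
#' @param cfg An [event_match_config()].
#' @return List with counts `tp`, `fp`, `fn`, `tn` and percentages
#'   `sensitivity`, `specificity`.
#' @export
sensitivity_specificity <- function(true_events, predicted_events,
                                    cfg = event_match_config()) {
  stopifnot(length(true_events) == length(predicted_events))
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(true_events)) {
    tr <- sort(as.numeric(true_events[[i]]))
    pr <- sort(as.numeric(predicted_events[[i]]))
    if (length(tr) == 0L && length(pr) == 0L) { tn <- tn + 1L; next }
    used_t <- logical(length(tr)); used_p <- logical(length(pr))
    if (length(tr) > 0L && length(pr) > 0L) {
      d <- abs(outer(tr, pr, `-`))
      repeat {
        d[used_t, ] <- Inf; d[, used_p] <- Inf
        if (all(!is.finite(d)) || min(d) > cfg$tolerance) break
        ij <- arrayInd(which.min(d), dim(d))
        used_t[ij[1]] <- TRUE; used_p[ij[2]] <- TRUE
        tp <- tp + 1L
        if (all(used_t) || all(used_p)) break
      }
    }
    fp <- fp + sum(!used_p)
    fn <- fn + sum(!used_t)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}
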