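# Causal kinematic features for the three submovement-parameter predictors.
# All features are computable from the start/target positions, the
# submovements initiated so far, and the current fingertip state -- never
# from the future of the reach.

#' Feature configuration
#'
#' @param target_radius Radius of the virtual spherical target (cm).
#' @param dttaps_floor Lower floor applied to DTTAPS before it is used as a
#'   divisor (cm).
#' @param post_onset Minimum extent of the initiation feature window past the
#'   next submovement's onset (s), so that windows of short submovements
#'   whose correction arrives after they end still contain an uncensored run
#'   of positive rows.
#' @param decay_rate Rate of the exponential time transform `exp(-rate * t)`.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(target_radius = 1.27, dttaps_floor = 0.1,
                           post_onset = 0.2, decay_rate = 20) {
  structure(list(target_radius = target_radius, dttaps_floor = dttaps_floor,
                 post_onset = post_onset, decay_rate = decay_rate),
            class = "feature_config")
}

#' Distance To Target accounted for by All Prior Submovements (DTTAPS)
#'
#' The remaining start-to-target distance after summing the amplitudes of all
#' submovements initiated before the k-th one. For the first submovement of a
#' reach there are no prior submovements, so DTTAPS is simply the distance
#' from the start position to the target. The value is floored at
#' `dttaps_floor` so it can safely be used as a normalising divisor.
#'
#' @param start,target Length-3 positions (cm).
#' @param prior_subs List of submovements initiated before the current one
#'   (empty for the first submovement).
#' @param cfg A [feature_config()].
#' @return Scalar distance (cm), `>= dttaps_floor`.
#' @export
#' @examples
#' dttaps(c(0, 0, 0), c(30, 0, 40), list())  # 50
dttaps <- function(start, target, prior_subs, cfg = feature_config()) {
  acc <- as.numeric(start)
  for (s in prior_subs) acc <- acc + s$A
  max(sqrt(sum((as.numeric(target) - acc)^2)), cfg$dttaps_floor)
}

#' Sign-preserving 4th root
#'
#' `sign(x) * |x|^(1/4)` -- the power transform applied to velocity and
#' acceleration inputs to compress their dynamic range and skew while
#' preserving direction.
#'
#' @param x Numeric vector.
#' @return Transformed values.
#' @export
signed_fourth_root <- function(x) sign(x) * abs(x)^0.25

#' Exponential time-decay transform
#'
#' `exp(-rate * t)` of the time since the current submovement started;
#' emphasises the early period of each submovement, where early corrections
#' occur.
#'
#' @param t Time since submovement start (s), `>= 0`.
#' @param rate Decay rate (1/s), default 20.
#' @return Value in `(0, 1]`.
#' @export
time_decay <- function(t, rate = 20) exp(-rate * t)

# planned position of the initiated submovements at time t
planned_position <- function(subs, start, t)
  as.numeric(position_trajectory(subs, start, t))

pair_dist <- function(pts) {
  idx <- utils::combn(length(pts), 2)
  apply(idx, 2, function(ij) sqrt(sum((pts[[ij[2]]] - pts[[ij[1]]])^2)))
}

#' Initiation-time features (21 values)
#'
#' The 15 pairwise Euclidean distances among \{start, target, current
#' fingertip, current submovement start, current submovement end, end of all
#' initiated submovements\}, two binary in-target flags (fingertip now;
#' planned endpoint of all initiated submovements), the remaining time in the
#' current submovement (clamped at 0), the same normalised by its duration,
#' the time since the current submovement started, and its exponential decay
#' transform. "Current submovement" start/end positions are the planned
#' trajectory (start plus closed-form displacement of all initiated
#' submovements) evaluated at its `t0` and `t0 + D`.
#'
#' @param start,target Length-3 positions (cm).
#' @param fingertip Length-3 current fingertip position (cm).
#' @param initiated Non-empty list of submovements initiated at or before
#'   `t_now`, in onset order; the last is the current submovement.
#' @param t_now Current time (s), `>= t0` of the current submovement.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 21.
#' @export
build_initiation_features <- function(start, target, fingertip, initiated,
                                      t_now, cfg = feature_config()) {
  if (length(initiated) == 0L)
    stop("build_initiation_features: no initiated submovements", call. = FALSE)
  cur <- initiated[[length(initiated)]]
  S <- as.numeric(start); G <- as.numeric(target); Fp <- as.numeric(fingertip)
  CS <- planned_position(initiated, S, cur$t0)
  CE <- planned_position(initiated, S, cur$t0 + cur$D)
  EI <- S + Reduce(`+`, lapply(initiated, `[[`, "A"))
  pts <- list(S = S, G = G, F = Fp, CS = CS, CE = CE, EI = EI)
  d <- pair_dist(pts)
  idx <- utils::combn(names(pts), 2)
  names(d) <- paste0("dist_", idx[1, ], "_", idx[2, ])
  ts <- t_now - cur$t0
  if (ts < 0) stop("build_initiation_features: t_now before current onset",
                   call. = FALSE)
  rem <- max(cur$t0 + cur$D - t_now, 0)
  c(d,
    in_target_now = as.numeric(sqrt(sum((Fp - G)^2)) <= cfg$target_radius),
    in_target_planned = as.numeric(sqrt(sum((EI - G)^2)) <= cfg$target_radius),
    t_remaining = rem,
    t_remaining_norm = rem / cur$D,
    t_since_start = ts,
    t_decay = time_decay(ts, cfg$decay_rate))
}

#' Amplitude features (24 values) and their DTTAPS normaliser
#'
#' The six pairwise 3D differences among \{start, target, current submovement
#' start, end of all prior initiated submovements\} (18 values), each divided
#' by DTTAPS, plus the sign-preserving 4th roots of the three fingertip
#' velocity and three acceleration components. The training target for the
#' amplitude network is the true amplitude divided by the same DTTAPS.
#'
#' @param start,target Length-3 positions (cm).
#' @param v,a Length-3 fingertip velocity (cm/s) and acceleration (cm/s^2)
#'   at the prediction time.
#' @param prior_subs Submovements initiated before the one being predicted
#'   (empty for the first submovement of a reach).
#' @param t_now Prediction time, i.e. the onset of the submovement whose
#'   amplitude is being predicted (s).
#' @param cfg A [feature_config()].
#' @return List with `features` (named length-24 vector) and `dttaps` (cm).
#' @export
build_amplitude_features <- function(start, target, v, a, prior_subs, t_now,
                                     cfg = feature_config()) {
  S <- as.numeric(start); G <- as.numeric(target)
  CS <- planned_position(prior_subs, S, t_now)
  EI <- S + Reduce(`+`, lapply(prior_subs, `[[`, "A"), init = c(0, 0, 0))
  dk <- dttaps(S, G, prior_subs, cfg)
  pts <- list(S = S, G = G, CS = CS, EI = EI)
  idx <- utils::combn(names(pts), 2)
  diffs <- apply(idx, 2, function(ij) (pts[[ij[2]]] - pts[[ij[1]]]) / dk)
  f <- as.numeric(diffs)   # column-major: 3 values per pair, 6 pairs
  names(f) <- paste0("diff_", rep(paste0(idx[1, ], "_", idx[2, ]), each = 3),
                     c("_x", "_y", "_z"))
  f <- c(f, stats::setNames(signed_fourth_root(as.numeric(v)),
                            c("v4_x", "v4_y", "v4_z")),
         stats::setNames(signed_fourth_root(as.numeric(a)),
                         c("a4_x", "a4_y", "a4_z")))
  list(features = f, dttaps = dk)
}

#' Duration features (12 values)
#'
#' The 10 pairwise Euclidean distances among \{start, target, current
#' submovement start, current submovement end, end of all prior initiated
#' submovements\}, plus the 4th roots of the fingertip speed and acceleration
#' magnitudes. The current submovement's end position uses its amplitude,
#' which in the closed loop is predicted before its duration, so the feature
#' remains causal.
#'
#' @inheritParams build_amplitude_features
#' @param A_cur Length-3 amplitude of the submovement whose duration is being
#'   predicted (decomposed during training, network-predicted in the loop).
#' @return Named numeric vector of length 12.
#' @export
build_duration_features <- function(start, target, v, a, prior_subs, t_now,
                                    A_cur, cfg = feature_config()) {
  S <- as.numeric(start); G <- as.numeric(target)
  CS <- planned_position(prior_subs, S, t_now)
  CE <- CS + as.numeric(A_cur)
  EI <- S + Reduce(`+`, lapply(prior_subs, `[[`, "A"), init = c(0, 0, 0))
  pts <- list(S = S, G = G, CS = CS, CE = CE, EI = EI)
  d <- pair_dist(pts)
  idx <- utils::combn(names(pts), 2)
  names(d) <- paste0("dist_", idx[1, ], "_", idx[2, ])
  c(d,
    speed4 = signed_fourth_root(sqrt(sum(as.numeric(v)^2))),
    accel4 = signed_fourth_root(sqrt(sum(as.numeric(a)^2))))
}

at_index <- function(trial, t) {
  dt <- trial$t[2] - trial$t[1]
  min(max(1L, round(t / dt) + 1L), length(trial$t))
}

#' Build the three training tables from decomposed reaches
#'
#' For each reach, submovements are taken in onset order. The initiation
#' table gains one row per 0.01 s timestep of each submovement's feature
#' window -- from its onset to the later of its own end and the next onset
#' plus `post_onset` (trial end for the last submovement) -- labelled 0
#' strictly before the next submovement's onset and 1 at and after it. The amplitude and duration tables gain one row per
#' decomposed submovement, labelled with the DTTAPS-normalised amplitude and
#' the raw duration respectively.
#'
#' @param dataset A preprocessed, differentiated `reach_dataset`.
#' @param decomps List of `decomposition_result`, parallel to
#'   `dataset$trials`.
#' @param cfg A [feature_config()].
#' @return List of three `feature_table` objects (`initiation`, `amplitude`,
#'   `duration`), each a list with matrix `x`, label matrix `y`, integer
#'   `reach` (row-to-reach map) and a `meta` data frame.
#' @export
build_training_tables <- function(dataset, decomps, cfg = feature_config()) {
  stopifnot(length(dataset$trials) == length(decomps))
  ix <- list(); iy <- list(); ir <- list(); im <- list()
  ax <- list(); ay <- list(); ar <- list(); am <- list()
  dx <- list(); dy <- list(); dr <- list(); dm <- list()
  for (ri in seq_along(dataset$trials)) {
    tr <- dataset$trials[[ri]]
    subs <- decomps[[ri]]$submovements
    subs <- subs[order(vapply(subs, `[[`, 0, "t0"))]
    K <- length(subs)
    t_end <- tr$t[length(tr$t)]
    onsets <- vapply(subs, `[[`, 0, "t0")
    for (k in seq_len(K)) {
      t_next <- if (k < K) onsets[k + 1] else NA_real_
      w_end <- if (k < K)
        min(max(subs[[k]]$t0 + subs[[k]]$D, t_next + cfg$post_onset), t_end)
      else t_end
      steps <- tr$t[tr$t >= onsets[k] & tr$t <= w_end]
      for (tt in steps) {
        ii <- at_index(tr, tt)
        f <- build_initiation_features(tr$start, tr$target, tr$p[ii, ],
                                       subs[seq_len(k)], tt, cfg)
        ix[[length(ix) + 1L]] <- f
        iy[[length(iy) + 1L]] <- as.numeric(!is.na(t_next) && tt >= t_next)
        ir[[length(ir) + 1L]] <- ri
        im[[length(im) + 1L]] <- c(k = k, t = tt,
                                   t_next = if (is.na(t_next)) -1 else t_next)
      }
      # parameter rows at the submovement's own onset
      ii <- at_index(tr, onsets[k])
      prior <- subs[seq_len(k - 1)]
      af <- build_amplitude_features(tr$start, tr$target, tr$v[ii, ],
                                     tr$a[ii, ], prior, onsets[k], cfg)
      ax[[length(ax) + 1L]] <- af$features
      ay[[length(ay) + 1L]] <- subs[[k]]$A / af$dttaps
      ar[[length(ar) + 1L]] <- ri
      am[[length(am) + 1L]] <- c(k = k, dttaps = af$dttaps, t0 = onsets[k])
      dx[[length(dx) + 1L]] <- build_duration_features(
        tr$start, tr$target, tr$v[ii, ], tr$a[ii, ], prior, onsets[k],
        subs[[k]]$A, cfg)
      dy[[length(dy) + 1L]] <- subs[[k]]$D
      dr[[length(dr) + 1L]] <- ri
      dm[[length(dm) + 1L]] <- c(k = k, t0 = onsets[k])
    }
  }
  mk <- function(x, y, r, m, kind) {
    structure(list(x = do.call(rbind, x), y = do.call(rbind, y),
                   reach = unlist(r),
                   meta = as.data.frame(do.call(rbind, m)), kind = kind),
              class = "feature_table")
  }
  list(initiation = mk(ix, iy, ir, im, "initiation"),
       amplitude = mk(ax, ay, ar, am, "amplitude"),
       duration = mk(dx, dy, dr, dm, "duration"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d rows x %d features, %d reaches\n",
              x$kind, nrow(x$x), ncol(x$x), length(unique(x$reach))))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' @param table A `feature_table`.
#' @param path Output path. Label columns are suffixed `__label`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  y <- as.matrix(table$y)
  colnames(y) <- paste0(if (ncol(y) == 3) c("Ax", "Ay", "Az") else table$kind,
                        "__label")
  utils::write.csv(cbind(as.data.frame(table$x), as.data.frame(y),
                         reach = table$reach),
                   path, row.names = FALSE)
  invisible(path)
}
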