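# Reading/writing reach kinematics CSVs and the preprocessing chain:
# resample to a uniform 100 Hz grid, interpolate short marker occlusions,
# drop trials with long occlusions, zero-phase low-pass filter at 10 Hz.

#' Default CSV schema for reach datasets
#'
#' Column names for the reach-kinematics CSV dialect used by
#' [load_dataset()] and [export_corpus()]: a trial identifier, time in
#' seconds, fingertip x/y/z and target x/y/z in cm. Occluded samples are
#' encoded as empty/NA fingertip coordinates.
#'
#' @return Named list of column names.
#' @export
default_schema <- function() {
  list(trial = "trial", time = "t",
       fingertip = c("px", "py", "pz"),
       target = c("tx", "ty", "tz"))
}

#' Load a reach-kinematics dataset from CSV
#'
#' Reads a per-participant CSV of reach kinematics and segments it into
#' trials. The result is raw (unpreprocessed): positions may be non-uniformly
#' sampled and contain NA runs where the marker was occluded.
#'
#' @param path Path to a CSV file.
#' @param schema Column-name schema, see [default_schema()].
#' @param participant_id Optional label; defaults to the file name.
#' @return An object of class `reach_dataset`: list with `participant_id`,
#'   `trials` (list of `reach_trial`) and `provenance`.
#' @export
load_dataset <- function(path, schema = default_schema(),
                         participant_id = NULL) {
  if (!file.exists(path))
    stop("load_dataset: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("load_dataset: empty dataset: ", path, call. = FALSE)
  need <- c(schema$trial, schema$time, schema$fingertip, schema$target)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("load_dataset: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(participant_id)) participant_id <- basename(path)
  ids <- df[[schema$trial]]
  trials <- lapply(split(seq_len(nrow(df)), factor(ids, levels = unique(ids))),
                   function(idx) {
    d <- df[idx, , drop = FALSE]
    p <- as.matrix(d[, schema$fingertip])
    tgt_row <- which(stats::complete.cases(d[, schema$target]))[1]
    reach_trial(trial_id = d[[schema$trial]][1],
                t = d[[schema$time]],
                p = p,
                target = as.numeric(d[tgt_row, schema$target]))
  })
  names(trials) <- NULL
  structure(list(participant_id = participant_id, trials = trials,
                 provenance = list(source = path, log = character())),
            class = "reach_dataset")
}

#' Construct a reach trial
#'
#' @param trial_id Identifier.
#' @param t Sample times (s).
#' @param p `length(t) x 3` fingertip positions (cm); NA rows mark occlusions.
#' @param target Length-3 target position (cm).
#' @param start Optional length-3 start position; defaults to the mean of the
#'   first three non-occluded samples.
#' @param v,a Optional velocity / acceleration matrices.
#' @return Object of class `reach_trial`.
#' @export
reach_trial <- function(trial_id, t, p, target, start = NULL,
                        v = NULL, a = NULL) {
  p <- as.matrix(p)
  if (length(t) != nrow(p))
    stop("reach_trial: length(t) != nrow(p)", call. = FALSE)
  if (is.null(start)) {
    ok <- which(stats::complete.cases(p))
    start <- colMeans(p[ok[seq_len(min(3L, length(ok)))], , drop = FALSE])
  }
  structure(list(trial_id = trial_id, t = as.numeric(t), p = p,
                 start = as.numeric(start), target = as.numeric(target),
                 v = v, a = a),
            class = "reach_trial")
}

#' @export
print.reach_trial <- function(x, ...) {
  cat(sprintf("reach_trial %s: %d samples, %.2f s, start-target distance %.1f cm\n",
              as.character(x$trial_id), length(x$t), diff(range(x$t)),
              sqrt(sum((x$target - x$start)^2))))
  invisible(x)
}

# Longest run of consecutive NA samples (by row).
longest_na_run <- function(p) {
  bad <- !stats::complete.cases(p)
  if (!any(bad)) return(0L)
  r <- rle(bad)
  max(r$lengths[r$values])
}

#' Design the 10 Hz zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (via
#' [signal::filtfilt()]) so the net filter has zero phase lag and the
#' effective magnitude response is the square of the single-pass response.
#'
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order (single pass).
#' @return A `signal` filter object.
#' @keywords internal
lowpass_filter <- function(fs = 100, cutoff = 10, order = 4) {
  signal::butter(order, cutoff / (fs / 2), type = "low")
}

# Forward-backward filtering with odd-symmetric edge padding (as in the
# standard filtfilt implementations) so step-like signal ends do not produce
# edge transients.
zero_phase_filter <- function(x, fs = 100, cutoff = 10, order = 4) {
  bf <- lowpass_filter(fs, cutoff, order)
  n <- length(x)
  # the pad must outlast the filter transient (no matched initial conditions
  # in signal::filtfilt), so use ten characteristic lengths
  L <- min(n - 1L, as.integer(10 * round(fs / cutoff)))
  if (L < 1L) return(signal::filtfilt(bf, x))
  head_pad <- 2 * x[1] - x[(L + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - L)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(L + 1):(L + n)]
}

#' Preprocess a reach trial
#'
#' Applies the standard motion-capture cleanup chain: (1) marker occlusions
#' of more than `gap_max` consecutive samples (> 50 ms at 100 Hz) exclude the
#' trial; (2) shorter occlusions are filled by cubic-spline interpolation;
#' (3) the samples are resampled onto a uniform `fs` grid; (4) positions are
#' smoothed with a zero-phase low-pass Butterworth filter at `cutoff` Hz.
#'
#' Exclusion is a result, not an error: an excluded trial is returned as a
#' list with `excluded = TRUE` and a `reason` code.
#'
#' @param trial A [reach_trial()].
#' @param fs Target sampling rate (Hz).
#' @param gap_max Maximum interpolatable occlusion length, samples.
#' @param cutoff Low-pass cutoff (Hz).
#' @return A preprocessed `reach_trial`, or a list
#'   `list(excluded = TRUE, reason = ..., trial_id = ...)`.
#' @export
preprocess <- function(trial, fs = 100, gap_max = 5, cutoff = 10) {
  stopifnot(inherits(trial, "reach_trial"))
  if (diff(range(trial$t)) < 0.5)
    return(list(excluded = TRUE, reason = "too-short",
                trial_id = trial$trial_id))
  if (longest_na_run(trial$p) > gap_max)
    return(list(excluded = TRUE, reason = "occlusion>50ms",
                trial_id = trial$trial_id))
  dt <- 1 / fs
  t0 <- trial$t[1]
  grid <- seq(0, trial$t[length(trial$t)] - t0, by = dt)
  ok <- stats::complete.cases(trial$p)
  p_new <- sapply(1:3, function(d) {
    # spline through observed samples handles both gap filling and resampling
    y <- stats::spline(trial$t[ok] - t0, trial$p[ok, d], xout = grid,
                       method = "natural")$y
    zero_phase_filter(y, fs = fs, cutoff = cutoff)
  })
  reach_trial(trial_id = trial$trial_id, t = grid, p = p_new,
              target = trial$target)
}

#' Differentiate a preprocessed trial
#'
#' Central differences on the filtered positions (one-sided at the ends) for
#' velocity, and the same scheme applied to velocity for acceleration.
#'
#' @param trial A preprocessed [reach_trial()].
#' @return The trial with `v` (cm/s) and `a` (cm/s^2) populated.
#' @export
differentiate <- function(trial) {
  stopifnot(inherits(trial, "reach_trial"))
  n <- length(trial$t)
  if (n < 3L) stop("differentiate: trial too short (<3 samples)", call. = FALSE)
  dt <- trial$t[2] - trial$t[1]
  cd <- function(x) {
    d <- numeric(length(x))
    d[1] <- (x[2] - x[1]) / dt
    d[length(x)] <- (x[length(x)] - x[length(x) - 1]) / dt
    i <- 2:(length(x) - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (2 * dt)
    d
  }
  trial$v <- apply(trial$p, 2, cd)
  trial$a <- apply(trial$v, 2, cd)
  trial
}

#' Preprocess every trial of a dataset
#'
#' @param dataset A `reach_dataset`.
#' @param ... Passed to [preprocess()].
#' @return The dataset with preprocessed, differentiated trials; excluded
#'   trials are dropped and logged in `provenance$log` and
#'   `provenance$excluded`.
#' @export
preprocess_dataset <- function(dataset, ...) {
  stopifnot(inherits(dataset, "reach_dataset"))
  out <- list(); excl <- list()
  for (tr in dataset$trials) {
    r <- preprocess(tr, ...)
    if (inherits(r, "reach_trial")) out[[length(out) + 1L]] <- differentiate(r)
    else excl[[length(excl) + 1L]] <- r
  }
  dataset$trials <- out
  dataset$provenance$excluded <- excl
  dataset$provenance$log <- c(dataset$provenance$log,
    sprintf("preprocessed: %d retained, %d excluded", length(out), length(excl)))
  dataset
}

#' Write a dataset (or synthetic corpus) to CSV
#'
#' Inverse of [load_dataset()] for the same schema; occluded samples are
#' written with empty fingertip fields.
#'
#' @param dataset A `reach_dataset`.
#' @param path Output CSV path.
#' @param schema Column schema.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, schema = default_schema()) {
  rows <- lapply(dataset$trials, function(tr) {
    d <- data.frame(trial = tr$trial_id, t = tr$t,
                    px = tr$p[, 1], py = tr$p[, 2], pz = tr$p[, 3],
                    tx = tr$target[1], ty = tr$target[2], tz = tr$target[3])
    names(d) <- c(schema$trial, schema$time, schema$fingertip, schema$target)
    d
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
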