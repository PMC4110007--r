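#' submovekit: minimum-jerk submovement modelling of 3D arm reaches
#'
#' Decomposes target-directed 3D reaching movements into overlapping
#' minimum-jerk submovements, trains feed-forward networks to predict
#' submovement initiation time, amplitude and duration from causal kinematic
#' features, and chains the predictors into a closed-loop simulator of
#' corrective reaches.
#'
#' @importFrom stats approx spline optim runif rnorm sd setNames
#' @importFrom utils read.csv write.csv combn head tail
#' @keywords internal
"_PACKAGE"

# Units used throughout: positions in cm, time in seconds, velocity cm/s,
# acceleration cm/s^2.

#' Construct a submovement
#'
#' A submovement is one minimum-jerk basis element of a reach: it begins at
#' `t0`, lasts `D` seconds and contributes a net 3D displacement `A` (cm).
#' The minimum duration of 0.1 s reflects the approximate duration of the
#' force transient of a single muscle twitch.
#'
#' @param t0 Initiation time in seconds, `>= 0`.
#' @param D Duration in seconds, `>= 0.1`.
#' @param A Numeric length-3 amplitude vector (cm).
#' @return An object of class `submovement` (a named list).
#' @export
#' @examples
#' submovement(0, 0.6, c(30, 0, 0))
submovement <- function(t0, D, A) {
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("submovement: t0 must be a finite scalar >= 0", call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0.1)
    stop("submovement: duration D must be a finite scalar >= 0.1 s",
         call. = FALSE)
  A <- as.numeric(A)
  if (length(A) != 3L || any(!is.finite(A)))
    stop("submovement: amplitude A must be a finite 3-vector", call. = FALSE)
  structure(list(t0 = t0, D = D, A = A), class = "submovement")
}

#' @export
print.submovement <- function(x, ...) {
  cat(sprintf("submovement: t0 = %.3f s, D = %.3f s, A = (%.2f, %.2f, %.2f) cm\n",
              x$t0, x$D, x$A[1], x$A[2], x$A[3]))
  invisible(x)
}

#' Construct a uniform time grid
#'
#' @param t_end End time in seconds (grid spans `[0, t_end]`).
#' @param dt Uniform step, default 0.01 s (100 Hz).
#' @return Numeric vector of sample times.
#' @export
time_grid <- function(t_end, dt = 0.01) {
  if (dt <= 0) stop("time_grid: dt must be > 0", call. = FALSE)
  if (t_end < 0) stop("time_grid: t_end must be >= 0", call. = FALSE)
  seq(0, t_end, by = dt)
}

# Dimensionless minimum-jerk speed shape 30*tau^2*(1-tau)^2 on [0,1],
# zero outside. Integrates to 1 so A is the net displacement.
mj_shape <- function(tau) {
  s <- numeric(length(tau))
  i <- tau > 0 & tau < 1
  ti <- tau[i]
  s[i] <- 30 * ti^2 * (1 - ti)^2
  s
}

# Closed-form displacement fraction 10*tau^3 - 15*tau^4 + 6*tau^5, clamped
# to 0 below support and 1 above.
mj_displacement_frac <- function(tau) {
  f <- numeric(length(tau))
  f[tau >= 1] <- 1
  i <- tau > 0 & tau < 1
  ti <- tau[i]
  f[i] <- 10 * ti^3 - 15 * ti^4 + 6 * ti^5
  f
}

# Dimensionless acceleration shape d/dtau of the speed shape:
# 60*tau*(1-tau)*(1-2*tau).
mj_accel_shape <- function(tau) {
  s <- numeric(length(tau))
  i <- tau > 0 & tau < 1
  ti <- tau[i]
  s[i] <- 60 * ti * (1 - ti) * (1 - 2 * ti)
  s
}

#' Minimum-jerk velocity of a single submovement
#'
#' Evaluates the canonical minimum-jerk (Flash--Hogan) velocity profile
#' \deqn{v_d(t) = \frac{A_d}{D}\,30\,\tau^2(1-\tau)^2,\qquad
#'       \tau = (t - t_0)/D \in [0, 1],}
#' per dimension, zero outside the support `[t0, t0 + D]` (the polynomial
#' vanishes at both boundaries, so support is closed and the profile is C1).
#'
#' @param sub A [submovement()].
#' @param t Numeric vector of sample times (s).
#' @return A `length(t) x 3` matrix of velocities (cm/s).
#' @export
#' @examples
#' minjerk_velocity(submovement(0, 1, c(10, 0, 0)), 0.5)  # peak 18.75 cm/s
minjerk_velocity <- function(sub, t) {
  stopifnot(inherits(sub, "submovement"))
  tau <- (t - sub$t0) / sub$D
  outer(mj_shape(tau) / sub$D, sub$A)
}

#' Minimum-jerk acceleration of a single submovement
#'
#' @inheritParams minjerk_velocity
#' @return A `length(t) x 3` matrix of accelerations (cm/s^2).
#' @export
minjerk_acceleration <- function(sub, t) {
  stopifnot(inherits(sub, "submovement"))
  tau <- (t - sub$t0) / sub$D
  outer(mj_accel_shape(tau) / sub$D^2, sub$A)
}

#' Superpose submovement velocities
#'
#' The reconstructed reach velocity is the pointwise sum of the minimum-jerk
#' velocities of all submovements. An empty set yields the all-zero velocity.
#'
#' @param subs A list of [submovement()] objects (possibly empty).
#' @param t Numeric vector of sample times (s).
#' @return A `length(t) x 3` velocity matrix (cm/s).
#' @export
superpose <- function(subs, t) {
  v <- matrix(0, length(t), 3)
  for (s in subs) v <- v + minjerk_velocity(s, t)
  v
}

#' Superposed acceleration of a submovement set
#'
#' @inheritParams superpose
#' @return A `length(t) x 3` acceleration matrix (cm/s^2).
#' @export
superpose_acceleration <- function(subs, t) {
  a <- matrix(0, length(t), 3)
  for (s in subs) a <- a + minjerk_acceleration(s, t)
  a
}

#' Closed-form position trajectory of a submovement set
#'
#' Position is the start point plus the closed-form minimum-jerk displacement
#' \eqn{A_d (10\tau^3 - 15\tau^4 + 6\tau^5)} summed over submovements.
#' After all submovements end, the position equals `start + sum(A)` exactly
#' (displacement conservation).
#'
#' @param subs List of [submovement()] objects.
#' @param start Length-3 start position (cm).
#' @param t Numeric vector of sample times (s).
#' @return A `length(t) x 3` position matrix (cm).
#' @export
position_trajectory <- function(subs, start, t) {
  p <- matrix(rep(as.numeric(start), each = length(t)), length(t), 3)
  for (s in subs) {
    tau <- (t - s$t0) / s$D
    p <- p + outer(mj_displacement_frac(tau), s$A)
  }
  p
}
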