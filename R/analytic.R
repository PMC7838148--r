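#' Fisher-KPP closed-form machinery
#'
#' The co-moving limit solution of the one-dimensional, nondimensional
#' Fisher-KPP equation, its gradient and inverse, and the amplitude-dependent
#' wave-pinning ("stationalization") penalty derived from them.  These pure
#' functions are the analytic backbone of the stationary tumor-extent
#' estimator: the penalty replaces the co-moving advection term \eqn{v \nabla u}
#' with a closed-form function of the local density alone, which turns the
#' forward growth model into a stationary boundary-value problem.
#'
#' All constants (\eqn{\sqrt 6}, \eqn{\sqrt{2/3}}, \eqn{5/\sqrt 6}) are
#' computed from library square roots, never hard-coded decimals.
#'
#' @name fisher-analytic
NULL

#' Special wave speed of the closed-form Fisher-KPP profile
#'
#' The dimensionless wave speed \eqn{\tilde v = 5/\sqrt 6 \approx 2.0412} for
#' which the Fisher-KPP equation admits an exact traveling-wave solution in
#' closed form.  It is the default penalty magnitude of the nondimensional
#' stationary model.
#'
#' @return A length-one numeric, \eqn{5/\sqrt 6}.
#' @export
#' @examples
#' fisher_wave_speed()
fisher_wave_speed <- function() 5 / sqrt(6)

#' Co-moving limit profile of the Fisher-KPP front
#'
#' Evaluates the closed-form traveling-wave profile
#' \deqn{U(\tilde x) = (1 + e^{\tilde x/\sqrt 6})^{-2},}
#' the shape the Fisher-KPP front converges to in the co-moving frame at the
#' special speed \eqn{\tilde v = 5/\sqrt 6}.  Strictly decreasing, with
#' \eqn{U(-\infty) = 1} (fully invaded tissue) and \eqn{U(+\infty) = 0}.
#'
#' @param x_tilde Numeric vector of dimensionless co-moving coordinates.
#' @return Densities in \eqn{(0, 1)}, same length as `x_tilde`.
#' @seealso [limit_gradient()], [limit_inverse()], [penalty()]
#' @export
#' @examples
#' limit_profile(0)            # 0.25
#' limit_profile(sqrt(6) * log(3))  # 1/16
limit_profile <- function(x_tilde) {
  stopifnot(is.numeric(x_tilde))
  (1 + exp(x_tilde / sqrt(6)))^-2
}

#' Gradient of the co-moving limit profile
#'
#' The exact spatial derivative of [limit_profile()]:
#' \deqn{U'(\tilde x) = -\sqrt{2/3}\; e^{\tilde x/\sqrt 6}
#'                      (1 + e^{\tilde x/\sqrt 6})^{-3}.}
#' Strictly negative with flat tails at \eqn{\pm\infty}.
#'
#' @inheritParams limit_profile
#' @return Slopes (dimensionless), same length as `x_tilde`.
#' @export
#' @examples
#' limit_gradient(0)  # -sqrt(2/3)/8
limit_gradient <- function(x_tilde) {
  stopifnot(is.numeric(x_tilde))
  a <- x_tilde / sqrt(6)
  # overflow-safe: for a > 0 divide through by exp(3a)
  out <- numeric(length(a))
  neg <- a <= 0
  e <- exp(a[neg])
  out[neg] <- -sqrt(2 / 3) * e / (1 + e)^3
  em <- exp(-a[!neg])
  out[!neg] <- -sqrt(2 / 3) * em^2 / (1 + em)^3
  out
}

#' Second derivative of the co-moving limit profile
#'
#' Exact curvature of [limit_profile()],
#' \eqn{U''(\tilde x) = -\tfrac13 e (1 - 2e)(1+e)^{-4}} with
#' \eqn{e = e^{\tilde x/\sqrt 6}}.  Used to verify analytically that the
#' profile solves the stationary co-moving equation.
#'
#' @inheritParams limit_profile
#' @return Second derivatives, same length as `x_tilde`.
#' @export
limit_curvature <- function(x_tilde) {
  stopifnot(is.numeric(x_tilde))
  a <- x_tilde / sqrt(6)
  out <- numeric(length(a))
  neg <- a <= 0
  e <- exp(a[neg])
  out[neg] <- -(1 / 3) * e * (1 - 2 * e) / (1 + e)^4
  em <- exp(-a[!neg])
  out[!neg] <- -(1 / 3) * (em^3 - 2 * em^2) / (1 + em)^4
  out
}

#' Residual of the stationary co-moving traveling-wave equation
#'
#' Evaluates \eqn{U'' + U(1-U) + \tilde v\, U'} with the exact derivatives of
#' the closed-form profile.  The residual vanishes identically precisely at
#' the special wave speed \eqn{\tilde v = 5/\sqrt 6}; for any other speed it
#' equals \eqn{(\tilde v - 5/\sqrt 6)\,U'(\tilde x)}.
#'
#' @inheritParams limit_profile
#' @param v_tilde Dimensionless wave speed.
#' @return Residual values, same length as `x_tilde`.
#' @export
#' @examples
#' max(abs(traveling_wave_residual(seq(-20, 20, 0.1), fisher_wave_speed())))
traveling_wave_residual <- function(x_tilde, v_tilde) {
  limit_curvature(x_tilde) +
    limit_profile(x_tilde) * (1 - limit_profile(x_tilde)) +
    v_tilde * limit_gradient(x_tilde)
}

#' Inverse of the co-moving limit profile
#'
#' Maps a density amplitude \eqn{U \in (0,1)} to the co-moving coordinate at
#' which the limit profile attains it:
#' \deqn{\tilde x(U) = \sqrt 6 \, \ln(1/\sqrt U - 1).}
#'
#' @param U Numeric vector of densities, each strictly inside \eqn{(0, 1)}.
#' @return Dimensionless coordinates, same length as `U`.
#' @export
#' @examples
#' limit_inverse(0.25)   # 0
#' limit_inverse(0.16)   # sqrt(6) * log(1.5)
limit_inverse <- function(U) {
  stopifnot(is.numeric(U))
  if (any(!is.finite(U)) || any(U <= 0) || any(U >= 1)) {
    stop("amplitude outside the invertible range (0, 1)", call. = FALSE)
  }
  sqrt(6) * log(1 / sqrt(U) - 1)
}

#' Wave-pinning penalty (stationalization term)
#'
#' The closed-form amplitude-dependent penalty
#' \deqn{p(u) = |v|\,\sqrt{2/3}\,(1 - \sqrt u)\,u,}
#' obtained by composing the gradient of the co-moving limit profile with its
#' inverse: \eqn{p(u) = -|v| \, U'(\tilde x(u))}.  Substituting it for the
#' co-moving advection term stationalizes the forward growth model.  Vanishes
#' at \eqn{u = 0} and \eqn{u = 1} and is linear in the penalty magnitude.
#'
#' Inputs outside \eqn{[0,1]} are a domain error here; out-of-range iterates
#' inside the solvers are handled by [positivity_guard()] instead.
#'
#' @param u Numeric vector of densities in \eqn{[0, 1]}.
#' @param v_mag Penalty magnitude \eqn{|v| \ge 0}; defaults to the special
#'   wave speed \eqn{5/\sqrt 6}.
#' @return Reaction rates, same length as `u`.
#' @export
#' @examples
#' penalty(0.25, 5 / sqrt(6))  # 5/24
penalty <- function(u, v_mag = fisher_wave_speed()) {
  stopifnot(is.numeric(u), is.numeric(v_mag), all(v_mag >= 0))
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("density outside [0, 1]; the solvers handle such iterates via the positivity guard",
         call. = FALSE)
  }
  abs(v_mag) * sqrt(2 / 3) * (1 - sqrt(u)) * u
}

# d/du of penalty; the u -> 0+ one-sided limit is finite (= |v| sqrt(2/3)),
# which keeps Newton Jacobians well defined at vanishing densities.
penalty_deriv <- function(u, v_mag = fisher_wave_speed()) {
  abs(v_mag) * sqrt(2 / 3) * (1 - 1.5 * sqrt(pmax(u, 0)))
}

#' Effective reaction of the stationalized model
#'
#' Logistic growth minus the wave-pinning penalty,
#' \eqn{\rho u (1-u) - p(u)}.  With \eqn{\rho = 1} and
#' \eqn{v = 5/\sqrt 6} it is negative (penalizing) on \eqn{0 < u < 4/9} and
#' positive (growing) on \eqn{4/9 < u < 1}; the imaging-visibility threshold
#' 0.16 lies inside the penalizing regime, which is what makes small initial
#' guesses converge to the outwards-moving solution branch.
#'
#' @inheritParams penalty
#' @param rho Logistic growth rate (1/time), > 0.
#' @return Net reaction rates, same length as `u`.
#' @export
#' @examples
#' effective_reaction(4 / 9, 1, 5 / sqrt(6))  # 0: the interior root
effective_reaction <- function(u, rho, v_mag = fisher_wave_speed()) {
  stopifnot(is.numeric(rho), all(rho > 0))
  rho * u * (1 - u) - penalty(u, v_mag)
}

#' Positivity guard for out-of-range amplitudes
#'
#' Surrogate reaction applied wherever a numerical iterate leaves the
#' physical range \eqn{[0, 1]}:
#' \deqn{n(\omega) = -\rho\omega \;(\omega < 0), \qquad
#'       n(\omega) = \rho(1-\omega) \;(\omega > 1),}
#' pushing the amplitude back toward the admissible interval.  A logistic
#' term would instead amplify small negative overshoots.  For in-range
#' amplitudes the guard is inactive and `NA` is returned — the model's own
#' reaction term applies there.
#'
#' @param omega Numeric vector of raw amplitudes.
#' @param rho Growth rate, > 0.
#' @return Numeric vector: replacement rates where the guard is active,
#'   `NA` where it is inactive.
#' @export
#' @examples
#' positivity_guard(c(-0.1, 0.5, 1.2), 1)  # 0.1, NA, -0.2
positivity_guard <- function(omega, rho) {
  stopifnot(is.numeric(omega), is.numeric(rho), all(rho > 0))
  out <- rep(NA_real_, length(omega))
  out[omega < 0] <- -rho * omega[omega < 0]
  out[omega > 1] <- rho * (1 - omega[omega > 1])
  out
}

# Guarded reaction used by both solvers: model reaction inside [0,1], the
# positivity guard outside.  `pen` toggles the wave-pinning penalty
# (stationary model) on/off (forward model).  Returns value and derivative.
guarded_reaction <- function(u, rho, v_mag, pen = TRUE) {
  val <- numeric(length(u))
  der <- numeric(length(u))
  lo <- u < 0
  hi <- u > 1
  ok <- !(lo | hi)
  if (any(ok)) {
    uu <- u[ok]
    val[ok] <- rho * uu * (1 - uu)
    der[ok] <- rho * (1 - 2 * uu)
    if (pen) {
      val[ok] <- val[ok] - penalty(uu, v_mag)
      der[ok] <- der[ok] - penalty_deriv(uu, v_mag)
    }
  }
  val[lo] <- -rho * u[lo]
  der[lo] <- -rho
  val[hi] <- rho * (1 - u[hi])
  der[hi] <- -rho
  list(value = val, deriv = der)
}

#' Nondimensionalization of the Fisher-KPP model
#'
#' Construct the scaling defined by a growth rate and a scalar diffusivity,
#' and map dimensional quantities to the dimensionless co-moving frame:
#' \deqn{\tilde t = \rho t, \quad \tilde v = v/\sqrt{\rho D}, \quad
#'       \tilde x = \sqrt{\rho/D}\,x - \tilde v \tilde t.}
#'
#' @param rho Growth rate (1/time), > 0.
#' @param D Scalar diffusivity (length^2/time), > 0.
#' @return An object of class `nondim_scaling`.
#' @export
#' @examples
#' sc <- nondim_scaling(rho = 1e-6, D = 1e-10)
#' nondimensionalize(sc, t = 90 * 86400, x = 0.02, v = 2.04e-6)
nondim_scaling <- function(rho, D) {
  if (!is.numeric(rho) || !is.numeric(D) || rho <= 0 || D <= 0) {
    stop("invalid scaling: rho and D must be positive", call. = FALSE)
  }
  structure(list(rho = rho, D = D), class = "nondim_scaling")
}

#' @rdname nondim_scaling
#' @param scaling A `nondim_scaling` object.
#' @param t,x,v Dimensional time, position, speed.
#' @return For `nondimensionalize`, a list with `t_tilde`, `x_tilde`,
#'   `v_tilde`; for `redimensionalize`, a list with `t`, `x`, `v`.
#' @export
nondimensionalize <- function(scaling, t, x, v) {
  stopifnot(inherits(scaling, "nondim_scaling"))
  t_tilde <- scaling$rho * t
  v_tilde <- v / sqrt(scaling$rho * scaling$D)
  x_tilde <- sqrt(scaling$rho / scaling$D) * x - v_tilde * t_tilde
  list(t_tilde = t_tilde, x_tilde = x_tilde, v_tilde = v_tilde)
}

#' @rdname nondim_scaling
#' @param t_tilde,x_tilde,v_tilde Dimensionless time, co-moving position,
#'   speed.
#' @export
redimensionalize <- function(scaling, t_tilde, x_tilde, v_tilde) {
  stopifnot(inherits(scaling, "nondim_scaling"))
  t <- t_tilde / scaling$rho
  v <- v_tilde * sqrt(scaling$rho * scaling$D)
  x <- (x_tilde + v_tilde * t_tilde) / sqrt(scaling$rho / scaling$D)
  list(t = t, x = x, v = v)
}
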