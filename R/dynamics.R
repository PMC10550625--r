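# Transient settling dynamics.
#
# Nondimensional governing equation (velocity scaled by v_Stokes, time by the
# relaxation time t_r):
#
#   (1 + chi/2) dups/dtau = 1 - ups cD(ups Re_St)
#       - B int_{max(0, tau - tau_H)}^{tau} (dups/dtau') / sqrt(tau-tau') dtau'
#
# with ups(0) = 0, B = 3 sqrt(chi/(2 pi)) and history horizon
# tau_H = 18 chi / (0.502 ups Re_St + 0.123)^2 (window model; the horizon
# shrinks as the instantaneous Reynolds number grows). The dimensional solver
# integrates the unscaled force balance with the same scheme; the two agree to
# rounding after rescaling, which pins the nondimensional history coefficient.

# nondimensional history coefficient, from the dimensional Basset kernel
# (3/2) d_p^2 sqrt(pi rho_f mu_f) scaled by 3 pi mu_f d_p v_Stokes sqrt(t_r)
history_coefficient <- function(chi) 3 * sqrt(chi / (2 * pi))

#' Dimensionless settling system
#'
#' Bundles the parameters of the nondimensional equation of motion: density
#' ratio `chi = rho_f / rho_p`, specific Reynolds number `Re_St`, drag model,
#' inertia coefficient `A = 1 + chi/2` (particle plus added mass) and history
#' coefficient `B = 3 sqrt(chi / (2 pi))`. `chi = 0` (massless fluid limit)
#' switches both the added-mass and history terms off.
#'
#' @param chi density ratio `rho_f / rho_p` (>= 0).
#' @param re_st specific Reynolds number at the Stokes velocity (>= 0).
#' @param model a [drag_model()].
#' @return an object of class `dimensionless_system`.
#' @export
dimensionless_system <- function(chi, re_st, model = drag_model()) {
  check_positive(chi, "chi", strict = FALSE)
  check_positive(re_st, "re_st", strict = FALSE)
  stopifnot(inherits(model, "drag_model"))
  structure(list(chi = chi, re_st = re_st, model = model,
                 A = 1 + chi / 2, B = history_coefficient(chi)),
            class = "dimensionless_system")
}

#' History horizon of the Basset window model
#'
#' Dimensionless length of the history window,
#' `tau_H = 18 chi / (0.502 upsilon Re_St + 0.123)^2`. The window shrinks as
#' the instantaneous Reynolds number `upsilon Re_St` grows: fast flow erases
#' the influence of old accelerations. The denominator is bounded below by
#' `0.123^2`, so the horizon is always finite and positive.
#'
#' @param chi density ratio (> 0).
#' @param upsilon instantaneous dimensionless velocity (>= 0).
#' @param re_st specific Reynolds number (>= 0).
#' @return dimensionless horizon `tau_H`.
#' @examples
#' history_horizon(0.9524, 0.749, 4.30)  # ~5.67
#' @export
history_horizon <- function(chi, upsilon, re_st) {
  check_positive(chi, "chi")
  if (any(upsilon < 0)) stop("'upsilon' must be >= 0", call. = FALSE)
  18 * chi / (0.502 * upsilon * re_st + 0.123)^2
}

new_trajectory <- function(t, v, l, scales = NULL, meta = list()) {
  df <- data.frame(t = t, v = v, l = l)
  if (!is.null(scales)) {
    df$tau <- t / scales$t_r
    df$upsilon <- v / scales$v_Stokes
    df$ell <- l / (scales$v_Stokes * scales$t_r)
  }
  structure(df, class = c("settling_trajectory", "data.frame"),
            scales = scales, meta = meta)
}

new_trajectory_nondim <- function(tau, upsilon, ell, scales = NULL,
                                  meta = list()) {
  df <- data.frame(tau = tau, upsilon = upsilon, ell = ell)
  if (!is.null(scales)) {
    df$t <- tau * scales$t_r
    df$v <- upsilon * scales$v_Stokes
    df$l <- ell * scales$v_Stokes * scales$t_r
  }
  structure(df, class = c("settling_trajectory", "data.frame"),
            scales = scales, meta = meta)
}

#' @export
print.settling_trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Settling trajectory (%d samples", nrow(x)))
  if (!is.null(meta$model)) cat(sprintf(", drag model '%s'", meta$model))
  if (!is.null(meta$window)) cat(sprintf(", history window %s",
                                         if (meta$window) "on" else "off"))
  cat(")\n")
  if ("tau" %in% names(x))
    cat(sprintf("  tau in [0, %g]; final upsilon = %.6g\n",
                max(x$tau), x$upsilon[nrow(x)]))
  if ("t" %in% names(x))
    cat(sprintf("  t in [0, %g] s; final v = %.6g m/s; l = %.6g m\n",
                max(x$t), x$v[nrow(x)], x$l[nrow(x)]))
  invisible(x)
}

#' @export
plot.settling_trajectory <- function(x, which = c("velocity", "distance"),
                                     ...) {
  which <- match.arg(which)
  if ("tau" %in% names(x)) {
    if (which == "velocity")
      plot(x$tau, x$upsilon, type = "l", xlab = expression(tau),
           ylab = expression(upsilon), ...)
    else
      plot(x$tau, x$ell, type = "l", xlab = expression(tau),
           ylab = expression(l), ...)
  } else {
    if (which == "velocity")
      plot(x$t, x$v, type = "l", xlab = "t [s]", ylab = "v [m/s]", ...)
    else
      plot(x$t, x$l, type = "l", xlab = "t [s]", ylab = "l [m]", ...)
  }
  invisible(x)
}

#' Simulate nondimensional settling from rest
#'
#' Integrates the nondimensional equation of motion on a uniform grid with
#' the particle starting at rest. The scheme is Crank-Nicolson on the
#' quasi-steady drag, exact product integration of the singular Abel kernel
#' in the history term (piecewise-constant acceleration per step), and Picard
#' fixed-point iteration within each step. The velocity rises monotonically
#' towards the relative terminal velocity `upsilon_s`
#' ([relative_terminal_velocity()]); with the window disabled the history
#' integral runs from `tau = 0`.
#'
#' @param system a [dimensionless_system()].
#' @param tau_end end of the integration interval (dimensionless, > 0).
#' @param step uniform step `dtau` (default 1e-3).
#' @param window logical: apply the history-horizon window (default `TRUE`).
#' @param scales optional [particle_scales()] used to attach dimensional
#'   columns to the returned trajectory.
#' @param picard_tol,picard_max Picard stopping tolerance (absolute, in
#'   `upsilon`) and iteration cap per step.
#' @return a `settling_trajectory` data.frame with columns `tau`, `upsilon`,
#'   `ell` (cumulative dimensionless distance), plus dimensional views when
#'   `scales` is given.
#' @examples
#' sys <- dimensionless_system(chi = 0.9524, re_st = 4.30, drag_model("sn"))
#' traj <- simulate_settling(sys, tau_end = 20, step = 5e-3)
#' @export
simulate_settling <- function(system, tau_end, step = 1e-3, window = TRUE,
                              scales = NULL, picard_tol = 1e-10,
                              picard_max = 50L) {
  stopifnot(inherits(system, "dimensionless_system"))
  check_positive(tau_end, "tau_end")
  check_positive(step, "step")
  m <- system$model
  res <- settle_core_cpp(Acoef = system$A, F0 = 1, Dcoef = 1,
                         alpha = system$re_st, Bh = system$B,
                         window = window && system$chi > 0,
                         wscale = 18 * system$chi, t_end = tau_end, h = step,
                         drag_id = m$id,
                         cd_const = if (is.na(m$cd_const)) 1 else m$cd_const,
                         picard_tol = picard_tol, picard_max = picard_max)
  new_trajectory_nondim(res$t, res$v, res$l, scales = scales,
                        meta = list(model = m$name, window = window,
                                    chi = system$chi, re_st = system$re_st,
                                    step = step))
}

#' Simulate dimensional settling from rest
#'
#' Integrates the dimensional force balance (weight minus buoyancy, drag,
#' added mass, windowed Basset history) directly in SI units, with no
#' nondimensionalization. After rescaling by `(t_r, v_Stokes)` the result
#' agrees with [simulate_settling()] to rounding error; this dual-formulation
#' agreement is the arbiter for the nondimensional history coefficient.
#'
#' @param particle a [spherical_particle()].
#' @param fluid a [fluid_medium()].
#' @param model a [drag_model()].
#' @param t_end end time, s (> 0).
#' @param dt time step, s (> 0).
#' @param window logical: apply the history-horizon window.
#' @param picard_tol Picard tolerance in velocity, m/s. Default scales the
#'   nondimensional 1e-10 by `v_Stokes`.
#' @param picard_max Picard iteration cap per step.
#' @return a `settling_trajectory` data.frame with columns `t`, `v`, `l` and
#'   the nondimensional views `tau`, `upsilon`, `ell`.
#' @export
simulate_settling_dimensional <- function(particle, fluid,
                                          model = drag_model(), t_end, dt,
                                          window = TRUE, picard_tol = NULL,
                                          picard_max = 50L) {
  sc <- particle_scales(particle, fluid)
  check_positive(t_end, "t_end")
  check_positive(dt, "dt")
  if (is.null(picard_tol))
    picard_tol <- 1e-10 * max(sc$v_Stokes, .Machine$double.eps)
  chi <- sc$chi
  Acoef <- sc$m_p * (1 + chi / 2)
  F0 <- (sc$m_p - sc$V_p * fluid$rho_f) * fluid$g
  Dcoef <- 3 * pi * fluid$mu_f * sc$d_p
  alpha <- fluid$rho_f * sc$d_p / fluid$mu_f
  Bh <- 1.5 * sc$d_p^2 * sqrt(pi * fluid$rho_f * fluid$mu_f)
  wscale <- fluid$rho_f * sc$d_p^2 / fluid$mu_f
  res <- settle_core_cpp(Acoef = Acoef, F0 = F0, Dcoef = Dcoef,
                         alpha = alpha, Bh = Bh, window = window,
                         wscale = wscale, t_end = t_end, h = dt,
                         drag_id = model$id,
                         cd_const = if (is.na(model$cd_const)) 1
                                    else model$cd_const,
                         picard_tol = picard_tol, picard_max = picard_max)
  sc_attach <- if (sc$v_Stokes > 0) sc else NULL
  new_trajectory(res$t, res$v, res$l, scales = sc_attach,
                 meta = list(model = model$name, window = window,
                             chi = chi, re_st = sc$Re_St, step = dt))
}

#' Traveled distance along a sampled trajectory
#'
#' Cumulative trapezoidal integral of velocity over time,
#' `l(t) = int_0^t v dt'`. Starts at zero and is non-decreasing for
#' non-negative velocities. Works on a `settling_trajectory` or on raw
#' `(times, velocities)` vectors.
#'
#' @param times sample times (strictly increasing) or a
#'   `settling_trajectory`.
#' @param velocities velocities at `times` (ignored when a trajectory is
#'   given; the trajectory's dimensionless columns are used when it has no
#'   dimensional ones).
#' @return numeric vector of cumulative distances, same length as `times`.
#' @export
trajectory_distance <- function(times, velocities = NULL) {
  if (inherits(times, "settling_trajectory")) {
    tr <- times
    if ("t" %in% names(tr)) {
      times <- tr$t; velocities <- tr$v
    } else {
      times <- tr$tau; velocities <- tr$upsilon
    }
  }
  if (length(times) != length(velocities))
    stop("'times' and 'velocities' must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  n <- length(times)
  c(0, cumsum(0.5 * diff(times) * (velocities[-1] + velocities[-n])))
}
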