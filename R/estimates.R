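# A-priori settling time and distance estimates.
#
# From the algebraic tail V ~ ups_s (1 - B ups_s / sqrt(tau)) of the
# linearized solution, the dimensionless time to come within n% of terminal
# velocity is
#   tau_n = (100 B ups_s / n)^2 = 45000 chi ups_s^2 / (pi n^2),
# so the dimensional settling time is
#   t_n = t_r tau_n = (2500 / (pi n^2)) (rho_f d_p^2 / mu_f) ups_s^2.
# The particle density cancels exactly (t_r carries rho_p, tau_n carries
# chi = rho_f/rho_p), and g enters only through ups_s: the duration of the
# transient is governed by the fluid's viscous properties.
#
# Integrating the same tail gives the settling distance
#   l_n = v_Stokes t_r ups_s (sqrt(tau_n) - sqrt(tau_0))^2,
#   tau_0 = B^2 ups_s^2  (so sqrt(tau_0/tau_n) = n/100),
# which collapses to
#   l_n = (2500 / (pi n^2)) (1 - n/100)^2 Re_St ups_s^3 d_p.
# At n = 1 the prefactors are 2500/pi ~ 796 (time) and
# (2500/pi)(0.99)^2 ~ 780 (distance). Both estimates are conservative upper
# bounds for the nonlinear dynamics: the linearized velocity under-runs the
# nonlinear one at every tau (Tchaplygin), so the true velocity enters the
# n% band no later than t_n.

settling_estimate_prefactor <- function(n_percent) 2500 / (pi * n_percent^2)

new_settling_estimate <- function(scales, upsilon_s, model_name, n_percent) {
  B <- history_coefficient(scales$chi)
  tau_n <- (100 * B * upsilon_s / n_percent)^2
  t_n <- scales$t_r * tau_n
  tau_0 <- (B * upsilon_s)^2
  l_n <- settling_estimate_prefactor(n_percent) * (1 - n_percent / 100)^2 *
    scales$Re_St * upsilon_s^3 * scales$d_p
  structure(list(n_percent = n_percent, tau_n = tau_n, t_n = t_n,
                 l_n = l_n, tau_0 = tau_0, upsilon_s = upsilon_s,
                 v_s = upsilon_s * scales$v_Stokes, model = model_name,
                 scales = scales),
            class = "settling_estimate")
}

#' @export
print.settling_estimate <- function(x, ...) {
  cat(sprintf("Settling estimate (n = %g%%, drag model '%s'):\n",
              x$n_percent, x$model))
  cat(sprintf("  upsilon_s = %.4f, v_s = %.4g m/s (Re_St = %.4g)\n",
              x$upsilon_s, x$v_s, x$scales$Re_St))
  cat(sprintf("  settling time     t_%g%% = %.4g s (tau = %.4g)\n",
              x$n_percent, x$t_n, x$tau_n))
  cat(sprintf("  settling distance l_%g%% = %.4g m\n", x$n_percent, x$l_n))
  invisible(x)
}

check_n_percent <- function(n_percent) {
  if (!is.numeric(n_percent) || any(n_percent <= 0) || any(n_percent >= 100))
    stop("'n_percent' is a percentage and must lie in (0, 100)",
         call. = FALSE)
  invisible(n_percent)
}

#' A-priori settling time estimate
#'
#' Time after which the settling velocity is within `n_percent` of terminal:
#' `t_n = (2500 / (pi n^2)) (rho_f d_p^2 / mu_f) upsilon_s^2`, a conservative
#' upper bound including the Basset history retardation. Scales as `1/n^2`
#' (relaxing accuracy from 1% to 2% cuts the required time fourfold) and is
#' independent of the particle density and of `g` at fixed `upsilon_s`.
#'
#' @param particle a [spherical_particle()].
#' @param fluid a [fluid_medium()].
#' @param model a [drag_model()] used for the relative terminal velocity.
#' @param n_percent accuracy level in percent, in (0, 100). `n_percent = 5`
#'   means "within 5% of terminal velocity".
#' @return a `settling_estimate` object (also carries the distance `l_n` and
#'   the supporting scales).
#' @examples
#' water <- fluid_medium()
#' p <- spherical_particle(microns(500), delta_rho = 0.05 * 997, fluid = water)
#' settling_time(p, water, drag_model("sn"), n_percent = 5)  # ~5 s
#' @export
settling_time <- function(particle, fluid, model = drag_model(),
                          n_percent = 5) {
  check_n_percent(n_percent)
  tv <- terminal_velocity(particle, fluid, model)
  new_settling_estimate(tv$scales, tv$upsilon_s, model$name, n_percent)
}

#' A-priori settling distance estimate
#'
#' Fall distance needed before the velocity is within `n_percent` of
#' terminal: `l_n = (2500/(pi n^2)) (1 - n/100)^2 Re_St upsilon_s^3 d_p`,
#' linear in the diameter at fixed `Re_St` and `upsilon_s`. This is the
#' minimum vessel depth for a valid terminal-velocity reading at the chosen
#' accuracy.
#'
#' @inheritParams settling_time
#' @return a `settling_estimate` object.
#' @export
settling_distance <- function(particle, fluid, model = drag_model(),
                              n_percent = 5) {
  settling_time(particle, fluid, model, n_percent)
}

#' Bernhardt's conservative t99 estimate
#'
#' The classical rule of thumb `t99 ~ 800 rho_f d_p^2 / mu_f` for the time to
#' reach 99% of terminal velocity. Since `2500/pi < 800` and
#' `upsilon_s <= 1`, the package's `t_1%` estimate never exceeds it.
#'
#' @param fluid a [fluid_medium()].
#' @param d_p particle diameter, m.
#' @return time, s.
#' @export
bernhardt_t99 <- function(fluid, d_p) {
  stopifnot(inherits(fluid, "fluid_medium"))
  check_positive(d_p, "d_p")
  800 * fluid$rho_f * d_p^2 / fluid$mu_f
}

#' Design sweep over diameter, density contrast and accuracy
#'
#' Evaluates terminal velocity, Reynolds numbers and the settling time and
#' distance estimates over a grid of particle diameters, relative density
#' contrasts and accuracy levels — the numbers an experimenter needs to size
#' a sedimentation vessel and a recording duration. Rows whose inputs are
#' invalid (e.g. Reynolds number outside a strict model's validity) are
#' flagged, not dropped.
#'
#' @param fluid a [fluid_medium()].
#' @param delta_rho_rel numeric vector of relative density contrasts
#'   `delta_rho / rho_f`.
#' @param d_p numeric vector of diameters, m.
#' @param n_percent numeric vector of accuracy levels in percent.
#' @param model a [drag_model()].
#' @return a long-format data.frame with columns `delta_rho_rel`, `d_p`, `n`,
#'   `Re_St`, `Re_s`, `upsilon_s`, `v_s`, `t_n`, `l_n`, `ok`, `note`.
#' @examples
#' design_sweep(fluid_medium(), delta_rho_rel = 0.05,
#'              d_p = microns(c(300, 500, 1000)), n_percent = 5)
#' @export
design_sweep <- function(fluid, delta_rho_rel, d_p, n_percent = 5,
                         model = drag_model()) {
  stopifnot(inherits(fluid, "fluid_medium"))
  grid <- expand.grid(delta_rho_rel = delta_rho_rel, d_p = d_p,
                      n = n_percent, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    out <- data.frame(row, Re_St = NA_real_, Re_s = NA_real_,
                      upsilon_s = NA_real_, v_s = NA_real_, t_n = NA_real_,
                      l_n = NA_real_, ok = FALSE, note = "")
    tryCatch({
      p <- spherical_particle(row$d_p, delta_rho = row$delta_rho_rel *
                                fluid$rho_f, fluid = fluid)
      est <- settling_time(p, fluid, model, n_percent = row$n)
      out$Re_St <- est$scales$Re_St
      out$Re_s <- est$upsilon_s * est$scales$Re_St
      out$upsilon_s <- est$upsilon_s
      out$v_s <- est$v_s
      out$t_n <- est$t_n
      out$l_n <- est$l_n
      out$ok <- TRUE
    }, error = function(e) out$note <<- conditionMessage(e))
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
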