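# Steady-state force balance: terminal velocity and its inversion.
#
# The dimensional balance  (4/3)(rho_p - rho_f) d_p g = rho_f v^2 CD(v)
# nondimensionalizes (v = upsilon v_Stokes) to the scalar root problem
#   upsilon_s cD(upsilon_s Re_St) = 1,  upsilon_s in (0, 1] for cD >= 1.
# The Flemmer-Banks fit can dip below cD = 1 at small Re (its documented
# artifact), so the bracket is widened above 1 when needed.

#' Relative terminal velocity
#'
#' Solves `upsilon_s cD(upsilon_s Re_St) = 1` for the relative terminal
#' velocity `upsilon_s = v_s / v_Stokes`. Equals 1 exactly for the Stokes
#' model or `Re_St = 0`, and decreases with `Re_St` for the standard-curve
#' correlations (drag grows superlinearly with velocity).
#'
#' @param re_st specific Reynolds number at the Stokes velocity (>= 0).
#' @param model a [drag_model()].
#' @param tol absolute root tolerance in `upsilon` (default 1e-12).
#' @return the relative terminal velocity (dimensionless scalar).
#' @examples
#' relative_terminal_velocity(4.30, drag_model("sn"))  # ~0.749
#' @export
relative_terminal_velocity <- function(re_st, model = drag_model(),
                                       tol = 1e-12) {
  stopifnot(inherits(model, "drag_model"))
  if (!is.numeric(re_st) || length(re_st) != 1L || re_st < 0)
    stop("'re_st' must be a scalar >= 0", call. = FALSE)
  if (re_st == 0 || model$name == "stokes") return(1)
  f <- function(u) u * cd_eval_cpp(model$id, u * re_st,
                                   if (is.na(model$cd_const)) 1
                                   else model$cd_const) - 1
  # range check once at the bracket top (covers the whole iteration range)
  check_drag_range(model, re_st, context = "Re during terminal solve")
  upper <- 1
  fu <- f(upper)
  while (fu < 0) {            # cD < 1 region (Flemmer-Banks artifact)
    upper <- upper * 2
    if (upper > 64) stop("no sign change while bracketing upsilon_s",
                         call. = FALSE)
    fu <- f(upper)
  }
  if (fu == 0) return(upper)
  uniroot(f, c(1e-12, upper), tol = tol)$root
}

#' Terminal settling velocity
#'
#' Computes the terminal velocity `v_s = upsilon_s v_Stokes` and the
#' associated terminal Reynolds number `Re_s = upsilon_s Re_St` for a
#' particle/fluid pair under a chosen drag correlation. The result satisfies
#' the dimensional force balance
#' `(4/3)(rho_p - rho_f) d_p g = rho_f v_s^2 CD(Re_s)`.
#'
#' @param particle a [spherical_particle()] with `rho_p > rho_f`.
#' @param fluid a [fluid_medium()].
#' @param model a [drag_model()].
#' @return a list with `v_s` (m/s), `re_s`, `upsilon_s`, and the supporting
#'   `scales` ([particle_scales()]).
#' @examples
#' water <- fluid_medium()
#' p <- spherical_particle(microns(500), delta_rho = 0.05 * 997, fluid = water)
#' terminal_velocity(p, water, drag_model("sn"))$v_s   # ~5.75e-3 m/s
#' @export
terminal_velocity <- function(particle, fluid, model = drag_model()) {
  sc <- particle_scales(particle, fluid)
  if (sc$delta_rho <= 0)
    stop("terminal velocity requires rho_p > rho_f", call. = FALSE)
  us <- relative_terminal_velocity(sc$Re_St, model)
  list(v_s = us * sc$v_Stokes, re_s = us * sc$Re_St, upsilon_s = us,
       scales = sc)
}

#' Density contrast from a measured terminal velocity
#'
#' Inverts the steady-state balance algebraically:
#' `delta_rho = 3 rho_f v_s^2 CD(Re_s) / (4 g d_p)` with
#' `Re_s = rho_f d_p v_s / mu_f`. No iteration is needed because `CD` is
#' evaluated at the measured Reynolds number directly. For the Stokes model
#' this reduces to the classical `delta_rho = 18 mu_f v_s / (g d_p^2)`, and
#' it is the exact inverse of [terminal_velocity()] for any model.
#'
#' @param v_s measured terminal velocity, m/s (> 0).
#' @param d_p particle diameter, m.
#' @param fluid a [fluid_medium()].
#' @param model a [drag_model()].
#' @return density contrast `delta_rho`, kg/m^3.
#' @export
density_from_terminal_velocity <- function(v_s, d_p, fluid,
                                           model = drag_model()) {
  stopifnot(inherits(fluid, "fluid_medium"))
  check_positive(v_s, "v_s")
  check_positive(d_p, "d_p")
  re_s <- reynolds(fluid, d_p, v_s)
  cd <- drag_coefficient(model, re_s)
  3 * fluid$rho_f * v_s^2 * cd / (4 * fluid$g * d_p)
}
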