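#' Fluid medium properties
#'
#' Container for the fluid properties entering the settling problem. Defaults
#' are water at laboratory conditions: density 997 kg/m^3, dynamic viscosity
#' 0.89e-3 Pa s, gravitational acceleration 9.87 m/s^2.
#'
#' @param rho_f fluid mass density, kg/m^3.
#' @param mu_f dynamic viscosity, Pa s.
#' @param g gravitational acceleration, m/s^2.
#' @return an object of class `fluid_medium` (list with `rho_f`, `mu_f`, `g`).
#' @examples
#' water <- fluid_medium()
#' fluid_medium(rho_f = g_per_cm3(0.986), mu_f = mPa_s(1.2), g = 9.81)
#' @export
fluid_medium <- function(rho_f = 997, mu_f = 0.89e-3, g = 9.87) {
  check_positive(rho_f, "rho_f")
  check_positive(mu_f, "mu_f")
  check_positive(g, "g")
  structure(list(rho_f = rho_f, mu_f = mu_f, g = g), class = "fluid_medium")
}

#' @export
print.fluid_medium <- function(x, ...) {
  cat("Fluid medium:\n")
  cat(sprintf("  rho_f = %g kg/m^3   mu_f = %g Pa s   g = %g m/s^2\n",
              x$rho_f, x$mu_f, x$g))
  invisible(x)
}

#' Spherical particle
#'
#' A rigid sphere specified by its diameter and either its mean density
#' `rho_p` or its density contrast `delta_rho = rho_p - rho_f` against a given
#' fluid. Both specifications normalize to the same object. Buoyant particles
#' (`rho_p < rho_f`) are rejected: the package uses a downward-positive
#' convention and models settling only.
#'
#' @param d_p particle diameter, m.
#' @param rho_p mean particle density, kg/m^3. Give either this or
#'   `delta_rho`.
#' @param delta_rho density contrast `rho_p - rho_f`, kg/m^3 (requires
#'   `fluid`).
#' @param fluid a [fluid_medium()]; required when `delta_rho` is used.
#' @return an object of class `spherical_particle` with fields `d_p`, `rho_p`.
#' @examples
#' spherical_particle(microns(500), rho_p = 1046.85)
#' spherical_particle(microns(500), delta_rho = 49.85, fluid = fluid_medium())
#' @export
spherical_particle <- function(d_p, rho_p = NULL, delta_rho = NULL,
                               fluid = NULL) {
  check_positive(d_p, "d_p")
  if (is.null(rho_p) == is.null(delta_rho))
    stop("give exactly one of 'rho_p' or 'delta_rho'", call. = FALSE)
  if (!is.null(delta_rho)) {
    if (is.null(fluid))
      stop("'fluid' is required when the particle is specified by 'delta_rho'",
           call. = FALSE)
    stopifnot(inherits(fluid, "fluid_medium"))
    check_positive(delta_rho, "delta_rho", strict = FALSE)
    rho_p <- fluid$rho_f + delta_rho
  }
  check_positive(rho_p, "rho_p")
  if (!is.null(fluid) && rho_p < fluid$rho_f)
    stop("buoyant particle (rho_p < rho_f): rising particles are not modelled",
         call. = FALSE)
  structure(list(d_p = d_p, rho_p = rho_p), class = "spherical_particle")
}

#' @export
print.spherical_particle <- function(x, ...) {
  cat(sprintf("Spherical particle: d_p = %g um, rho_p = %g kg/m^3\n",
              x$d_p * 1e6, x$rho_p))
  invisible(x)
}

#' Derived particle and fluid scales
#'
#' Computes the derived quantities that parameterize the settling problem:
#' particle volume `V_p = (pi/6) d_p^3`, mass `m_p = V_p rho_p`, projected
#' area `A_p = (pi/4) d_p^2`, relaxation time `t_r = m_p / (3 pi mu_f d_p)`,
#' density ratio `chi = rho_f / rho_p`, Stokes terminal velocity
#' `v_Stokes = g (rho_p - rho_f) d_p^2 / (18 mu_f)` and the specific Reynolds
#' number `Re_St = rho_f d_p v_Stokes / mu_f` evaluated at the Stokes
#' velocity. `Re_St` admits the equivalent product decomposition
#' `(rho_f^2 g / (18 mu_f^2)) * (delta_rho / rho_f) * d_p^3`, which separates
#' the fluid factor, the relative density contrast, and the particle volume
#' factor.
#'
#' @param particle a [spherical_particle()].
#' @param fluid a [fluid_medium()].
#' @return an object of class `particle_scales`: list with `V_p`, `m_p`,
#'   `A_p`, `t_r`, `chi`, `v_Stokes`, `Re_St`, plus the inputs `d_p`,
#'   `rho_p`, `delta_rho` and the `fluid`.
#' @examples
#' water <- fluid_medium()
#' p <- spherical_particle(microns(500), delta_rho = 0.05 * 997, fluid = water)
#' particle_scales(p, water)
#' @export
particle_scales <- function(particle, fluid) {
  stopifnot(inherits(particle, "spherical_particle"),
            inherits(fluid, "fluid_medium"))
  if (particle$rho_p < fluid$rho_f)
    stop("buoyant particle (rho_p < rho_f): rising particles are not modelled",
         call. = FALSE)
  d_p <- particle$d_p
  rho_p <- particle$rho_p
  delta_rho <- rho_p - fluid$rho_f
  V_p <- pi / 6 * d_p^3
  m_p <- V_p * rho_p
  A_p <- pi / 4 * d_p^2
  t_r <- m_p / (3 * pi * fluid$mu_f * d_p)
  chi <- fluid$rho_f / rho_p
  v_Stokes <- fluid$g * delta_rho * d_p^2 / (18 * fluid$mu_f)
  Re_St <- fluid$rho_f * d_p * v_Stokes / fluid$mu_f
  structure(list(V_p = V_p, m_p = m_p, A_p = A_p, t_r = t_r, chi = chi,
                 v_Stokes = v_Stokes, Re_St = Re_St, d_p = d_p,
                 rho_p = rho_p, delta_rho = delta_rho, fluid = fluid),
            class = "particle_scales")
}

#' @export
print.particle_scales <- function(x, ...) {
  cat("Particle/fluid scales:\n")
  cat(sprintf("  d_p = %g um, rho_p = %g kg/m^3, delta_rho = %g kg/m^3\n",
              x$d_p * 1e6, x$rho_p, x$delta_rho))
  cat(sprintf("  V_p = %.4g m^3, m_p = %.4g kg, A_p = %.4g m^2\n",
              x$V_p, x$m_p, x$A_p))
  cat(sprintf("  t_r = %.4g s, chi = %.4f\n", x$t_r, x$chi))
  cat(sprintf("  v_Stokes = %.4g m/s, Re_St = %.4g\n", x$v_Stokes, x$Re_St))
  invisible(x)
}

#' Particle Reynolds number
#'
#' `Re = rho_f d_p v / mu_f` with the downward-positive velocity convention;
#' negative velocities are rejected.
#'
#' @param fluid a [fluid_medium()].
#' @param d_p particle diameter, m.
#' @param v particle velocity, m/s (>= 0).
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(fluid, d_p, v) {
  stopifnot(inherits(fluid, "fluid_medium"))
  check_positive(d_p, "d_p")
  if (any(v < 0))
    stop("negative velocity: the downward-positive convention requires v >= 0",
         call. = FALSE)
  fluid$rho_f * d_p * v / fluid$mu_f
}

#' Upper diameter limit for Stokes-regime settling
#'
#' The largest diameter for which the Stokes terminal velocity keeps the
#' terminal Reynolds number at or below `re_max`:
#' `d_p = (18 re_max mu_f^2 / (g rho_f delta_rho))^(1/3)`. With the classical
#' choice `re_max = 0.5` this is the applicability bound of the Stokes-law
#' density formula. The limit scales as `re_max^(1/3)` and `delta_rho^(-1/3)`.
#'
#' @param fluid a [fluid_medium()].
#' @param delta_rho density contrast, kg/m^3 (> 0).
#' @param re_max maximum admissible terminal Reynolds number (default 0.5).
#' @return limit diameter, m.
#' @examples
#' # swollen starch microspheres in water: limit is ~331 um
#' stokes_diameter_limit(fluid_medium(), delta_rho = g_per_cm3(0.02)) * 1e6
#' @export
stokes_diameter_limit <- function(fluid, delta_rho, re_max = 0.5) {
  stopifnot(inherits(fluid, "fluid_medium"))
  if (!is.numeric(delta_rho) || delta_rho <= 0)
    stop("'delta_rho' must be > 0: no settling without a density contrast",
         call. = FALSE)
  check_positive(re_max, "re_max")
  (18 * re_max * fluid$mu_f^2 / (fluid$g * fluid$rho_f * delta_rho))^(1 / 3)
}
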