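#' Laboratory unit helpers
#'
#' Sedimentation work mixes unit systems: densities are quoted in g/cm^3,
#' viscosities in mPa s (= cP), particle diameters in micrometres or
#' millimetres. All package internals are SI base units (kg/m^3, Pa s, m);
#' these helpers convert at the boundary.
#'
#' @param x numeric vector in the source unit.
#' @return numeric vector in the SI base unit (kg/m^3, Pa s or m).
#' @examples
#' g_per_cm3(0.997)   # water density, kg/m^3
#' mPa_s(0.89)        # water viscosity, Pa s
#' microns(500)       # 500 um particle, m
#' @name units
NULL

#' @rdname units
#' @export
g_per_cm3 <- function(x) x * 1000

#' @rdname units
#' @export
mPa_s <- function(x) x * 1e-3

#' @rdname units
#' @export
microns <- function(x) x * 1e-6

#' @rdname units
#' @export
mm <- function(x) x * 1e-3

# internal: positive scalar check with a field-naming error message
check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  if (!strict && x < 0)
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}
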