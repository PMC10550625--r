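# Drag-correlation registry.
#
# Every correlation is exposed through two equivalent views:
#   CD(Re)            the drag coefficient, and
#   cD(Re) = Re/24 CD the drag-correction factor (ratio to Stokes drag),
# linked by cD = (Re/24) CD. cD -> 1 as Re -> 0 for the standard-curve fits.
# Coefficient values are kept exactly as used throughout this package (single
# source of truth lives in src/settle.cpp, shared with the transient solver):
#   Schiller-Naumann       cD = 1 + 0.15 Re^0.687
#   Clift-Grace-Weber      cD = 1 + Re/128                       (Re <= 0.01)
#                          cD = 1 + 0.131 Re^(0.82-0.05 log10 Re) (0.01,20]
#                          cD = 1 + 0.193 Re^0.6305              (20, 260]
#   Brown-Lawler           cD = 1 + 0.150 Re^0.681 + 0.40 Re^2/(24 (Re+8710))
#   Flemmer-Banks          cD = 10^E, E = 0.261 Re^0.369 - 0.105 Re^0.431
#                                       - 0.124/(1+(log10 Re)^2)
#   Terfous-Hazzab-Ghenaim CD = 2.689 + 21.683/Re + 0.131/Re^2
#                               - 10.616/Re^0.1 + 12.216/Re^0.2
#   Oseen                  CD = (24/Re)(1 + 3 Re/16)
#   Stokes                 cD = 1
# Note the deliberate 0.131/0.193/0.40 (not the 0.1315/0.1935/0.407 sometimes
# seen elsewhere). CGW branch edges are half-open exactly as written; the tiny
# jumps at the edges are accepted, not smoothed.

.drag_ids <- c(constant = 0L, stokes = 1L, oseen = 2L, schiller_naumann = 3L,
               clift_grace_weber = 4L, brown_lawler = 5L, flemmer_banks = 6L,
               terfous_hazzab_ghenaim = 7L)

.drag_aliases <- c(sn = "schiller_naumann", cgw = "clift_grace_weber",
                   bl = "brown_lawler", fb = "flemmer_banks",
                   thg = "terfous_hazzab_ghenaim")

# declared validity in Re; outside it the range policy applies
.drag_validity <- list(
  constant = c(0, Inf),
  stokes = c(0, 0.5),
  oseen = c(0, 1),
  schiller_naumann = c(0, 800),
  clift_grace_weber = c(0, 260),
  brown_lawler = c(0, 2e5),
  flemmer_banks = c(0, 3e5),
  terfous_hazzab_ghenaim = c(0.1, 5e4)
)

#' Drag-correlation model
#'
#' Constructs a named drag correlation exposing the drag-correction factor
#' `cD(Re)` and the drag coefficient `CD(Re) = 24 cD(Re) / Re`, with a
#' declared Reynolds-number validity range. Available models: `stokes`,
#' `oseen`, `schiller_naumann` (`sn`), `clift_grace_weber` (`cgw`),
#' `brown_lawler` (`bl`), `flemmer_banks` (`fb`) and
#' `terfous_hazzab_ghenaim` (`thg`, defined through `CD` directly). See
#' [constant_drag()] for a frozen-drag diagnostic model.
#'
#' @param name model name or alias (see above).
#' @param range_policy what to do when `Re` falls outside the validity range:
#'   `"warn"` (default) evaluates the printed formula anyway with a warning;
#'   `"strict"` throws an error naming the interval.
#' @return an object of class `drag_model`.
#' @examples
#' sn <- drag_model("sn")
#' drag_correction(sn, 1)        # 1.15
#' drag_coefficient(sn, 10)      # ~4.151
#' @export
drag_model <- function(name = "clift_grace_weber",
                       range_policy = c("warn", "strict")) {
  range_policy <- match.arg(range_policy)
  name <- tolower(name)
  if (name %in% names(.drag_aliases)) name <- .drag_aliases[[name]]
  if (!name %in% names(.drag_ids) || name == "constant")
    stop(sprintf("unknown drag model '%s'; available: %s", name,
                 paste(setdiff(names(.drag_ids), "constant"), collapse = ", ")),
         call. = FALSE)
  structure(list(name = name, id = .drag_ids[[name]],
                 validity = .drag_validity[[name]], cd_const = NA_real_,
                 range_policy = range_policy),
            class = "drag_model")
}

#' Constant (frozen) drag-correction model
#'
#' A diagnostic model with `cD(Re) == value` for all `Re`. Freezing
#' `cD = 1/upsilon_s` turns the transient solver into the linearized settling
#' equation, which is how the time-stepping scheme is cross-checked against
#' the closed-form [analytic_velocity()].
#'
#' @param value the constant drag-correction factor (> 0).
#' @inheritParams drag_model
#' @return an object of class `drag_model`.
#' @export
constant_drag <- function(value, range_policy = c("warn", "strict")) {
  range_policy <- match.arg(range_policy)
  check_positive(value, "value")
  structure(list(name = "constant", id = 0L, validity = c(0, Inf),
                 cd_const = value, range_policy = range_policy),
            class = "drag_model")
}

#' @export
print.drag_model <- function(x, ...) {
  cat(sprintf("Drag model '%s' (validity Re in [%g, %g], policy '%s')\n",
              x$name, x$validity[1], x$validity[2], x$range_policy))
  if (x$name == "constant") cat(sprintf("  cD == %g\n", x$cd_const))
  invisible(x)
}

check_drag_range <- function(model, re, context = "Re") {
  out <- re < model$validity[1] | re > model$validity[2]
  if (any(out)) {
    msg <- sprintf(
      "%s = %g outside validity range [%g, %g] of drag model '%s'",
      context, re[which(out)[1]], model$validity[1], model$validity[2],
      model$name)
    if (model$range_policy == "strict") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  invisible(NULL)
}

#' Drag-correction factor cD(Re)
#'
#' The ratio of the correlation's drag to Stokes drag, `cD = (Re/24) CD`.
#' Equals 1 identically for the Stokes model and tends to 1 as `Re -> 0` for
#' the standard-curve fits; it is an increasing function of `Re` for all
#' models except Flemmer-Banks, whose single-formula fit dips slightly below
#' 1 at low `Re` (a known artifact, reproduced as printed).
#'
#' @param model a [drag_model()].
#' @param re particle Reynolds number(s), >= 0.
#' @return `cD(re)`, vectorized over `re`.
#' @export
drag_correction <- function(model, re) {
  stopifnot(inherits(model, "drag_model"))
  if (any(re < 0)) stop("'re' must be >= 0", call. = FALSE)
  check_drag_range(model, re)
  if (model$id == .drag_ids[["terfous_hazzab_ghenaim"]] && any(re == 0))
    stop("cD of the Terfous-Hazzab-Ghenaim model is undefined at Re = 0 ",
         "(the model is defined through CD only)", call. = FALSE)
  cd_eval_cpp(model$id, as.numeric(re),
              if (is.na(model$cd_const)) 1 else model$cd_const)
}

#' Drag coefficient CD(Re)
#'
#' `CD(Re) = 24 cD(Re) / Re` for correction-defined models; the
#' Terfous-Hazzab-Ghenaim model evaluates its printed five-term formula
#' directly. `CD` diverges at `Re = 0`, which is rejected.
#'
#' @inheritParams drag_correction
#' @param re particle Reynolds number(s), > 0.
#' @return `CD(re)`, vectorized over `re`.
#' @export
drag_coefficient <- function(model, re) {
  stopifnot(inherits(model, "drag_model"))
  if (any(re <= 0))
    stop("'re' must be > 0: CD diverges at Re = 0", call. = FALSE)
  check_drag_range(model, re)
  24 * cd_eval_cpp(model$id, as.numeric(re),
                  if (is.na(model$cd_const)) 1 else model$cd_const) / re
}

#' Tabulate a drag correlation
#'
#' Evaluates `cD` and `CD` on a log-spaced Reynolds grid; the backing table of
#' the `drag-table` command-line tool.
#'
#' @inheritParams drag_correction
#' @param re_min,re_max grid limits (Re > 0).
#' @param points number of log-spaced points.
#' @return a data.frame with columns `re`, `c_d`, `C_D`.
#' @export
drag_table <- function(model, re_min = 0.1, re_max = 100, points = 50) {
  check_positive(re_min, "re_min")
  check_positive(re_max, "re_max")
  re <- exp(seq(log(re_min), log(re_max), length.out = points))
  data.frame(re = re, c_d = drag_correction(model, re),
             C_D = drag_coefficient(model, re))
}
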