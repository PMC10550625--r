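# Closed-form solution of the linearized settling equation.
#
# Linearizing the drag term by freezing the drag-correction factor at its
# terminal value, cD = C = 1/upsilon_s, gives
#
#   A dV/dtau = 1 - C V - B int_0^tau (dV/dtau') / sqrt(tau - tau') dtau',
#   V(0) = 0,  A = 1 + chi/2,  B = 3 sqrt(chi/(2 pi)).
#
# Its Laplace transform is Vhat(s) = 1 / (s [A s + B sqrt(pi s) + 1/ups_s]),
# a rational function of sqrt(s) whose roots in sqrt(s) are
#   s_{1,2} = ( -sqrt(pi) B +/- i sqrt(4 A / ups_s - pi B^2) ) / (2 A).
# Inverting term by term yields
#   V(tau) = 1/(A (s2 - s1)) { 1/s1 - 1/s2
#            + (1/s2) exp(s2^2 tau) erfc(-s2 sqrt(tau))
#            - (1/s1) exp(s1^2 tau) erfc(-s1 sqrt(tau)) },
# evaluated through the Faddeeva function w(z) = exp(-z^2) erfc(-i z):
# exp(s^2 tau) erfc(-s sqrt(tau)) = w(-i s sqrt(tau)), whose argument lies in
# the upper half-plane (Re s < 0), so the evaluation never overflows even for
# tau ~ 1e8. By Tchaplygin's differential-inequality argument V(tau) bounds
# the nonlinear solution from below at every tau, and both share the limit
# upsilon_s; the large-tau tail is algebraic,
# V ~ ups_s (1 - B ups_s / sqrt(tau)).

# ---- Faddeeva function ----------------------------------------------------

.faddeeva_env <- new.env(parent = emptyenv())

weideman_coefs <- function(n = 64L) {
  key <- as.character(n)
  if (!is.null(.faddeeva_env[[key]])) return(.faddeeva_env[[key]])
  m <- 2L * n
  m2 <- 2L * m
  k <- seq(-m + 1L, m - 1L)
  L <- sqrt(n / sqrt(2))
  theta <- k * pi / m
  tt <- L * tan(theta / 2)
  f <- c(0, exp(-tt^2) * (L^2 + tt^2))
  # fftshift of the length-2m vector, then real FFT coefficients
  f <- c(f[(m + 1L):m2], f[1L:m])
  a <- Re(fft(f)) / m2
  a <- rev(a[2L:(n + 1L)])
  out <- list(a = a, L = L)
  .faddeeva_env[[key]] <- out
  out
}

#' Faddeeva function w(z)
#'
#' `w(z) = exp(-z^2) erfc(-i z)`, computed by Weideman's rational
#' approximation (default 64 terms), which is uniformly accurate over the
#' upper half-plane and decays correctly as `i/(sqrt(pi) z)` for large `|z|`.
#' The lower half-plane is reached through the reflection
#' `w(-z) = 2 exp(-z^2) - w(z)`.
#'
#' @param z complex (or numeric) vector.
#' @param n number of expansion terms.
#' @return complex vector `w(z)`.
#' @export
faddeeva_w <- function(z, n = 64L) {
  z <- as.complex(z)
  co <- weideman_coefs(n)
  L <- co$L
  a <- co$a
  wcalc <- function(zz) {
    iz <- complex(real = -Im(zz), imaginary = Re(zz))  # i*z
    Z <- (L + iz) / (L - iz)
    p <- 0 + 0i
    for (ak in a) p <- p * Z + ak   # Horner
    2 * p / (L - iz)^2 + (1 / sqrt(pi)) / (L - iz)
  }
  out <- complex(length(z))
  up <- Im(z) >= 0
  if (any(up)) out[up] <- wcalc(z[up])
  if (any(!up)) out[!up] <- 2 * exp(-z[!up]^2) - wcalc(-z[!up])
  out
}

# ---- linear model ---------------------------------------------------------

#' Linearized settling model
#'
#' Builds the coefficients and Laplace-domain roots of the linearized
#' settling equation for a given density ratio and relative terminal
#' velocity: `A = 1 + chi/2`, `B = 3 sqrt(chi/(2 pi))`, `C = 1/upsilon_s`,
#' and the roots `s1, s2` (values of `sqrt(s)` at the poles). In the usual
#' complex-pair regime the identity `A |s1|^2 upsilon_s = 1` holds, which is
#' what forces `V(tau) -> upsilon_s`.
#'
#' @param chi density ratio `rho_f / rho_p` (>= 0).
#' @param upsilon_s relative terminal velocity, in (0, 1].
#' @return an object of class `linear_settling_model` with fields `A`, `B`,
#'   `C`, `s1`, `s2`, `upsilon_s`, `chi`, `degenerate`.
#' @examples
#' lm <- linear_system(chi = 0.9524, upsilon_s = 0.749)
#' analytic_velocity(lm, c(0, 1, 10))
#' @export
linear_system <- function(chi, upsilon_s) {
  check_positive(chi, "chi", strict = FALSE)
  if (!is.numeric(upsilon_s) || upsilon_s <= 0 || upsilon_s > 1 + 1e-12)
    stop("'upsilon_s' must lie in (0, 1]", call. = FALSE)
  new_linear_model(1 + chi / 2, history_coefficient(chi), upsilon_s,
                   chi = chi)
}

# raw-coefficient constructor (A, B free): the Laplace-domain machinery does
# not care where A and B came from, and tests exercise it with detached
# coefficients
new_linear_model <- function(A, B, upsilon_s, chi = NA_real_) {
  C <- 1 / upsilon_s
  disc <- 4 * A / upsilon_s - pi * B^2
  degenerate <- abs(disc) < 1e-12 * (4 * A / upsilon_s)
  root <- if (disc >= 0) complex(real = 0, imaginary = sqrt(disc))
          else complex(real = sqrt(-disc), imaginary = 0)
  s1 <- (-sqrt(pi) * B + root) / (2 * A)
  s2 <- (-sqrt(pi) * B - root) / (2 * A)
  structure(list(A = A, B = B, C = C, s1 = s1, s2 = s2,
                 upsilon_s = upsilon_s, chi = chi, degenerate = degenerate),
            class = "linear_settling_model")
}

#' @export
print.linear_settling_model <- function(x, ...) {
  cat("Linearized settling model:\n")
  cat(sprintf("  A = %.6g, B = %.6g, C = 1/upsilon_s = %.6g\n",
              x$A, x$B, x$C))
  cat(sprintf("  s1 = %.6g%+.6gi, s2 = %.6g%+.6gi%s\n",
              Re(x$s1), Im(x$s1), Re(x$s2), Im(x$s2),
              if (x$degenerate) " (degenerate pair)" else ""))
  invisible(x)
}

# exp(s^2 tau) erfc(-s sqrt(tau)) via the Faddeeva function; s complex scalar,
# tau vector. Argument -i s sqrt(tau) is in the upper half-plane for Re s < 0.
erfcx_scaled <- function(s, tau) {
  z <- -1i * s * sqrt(tau)
  faddeeva_w(z)
}

#' Linearized settling velocity V(tau)
#'
#' Evaluates the closed-form Laplace inversion of the linearized settling
#' equation. `V(0) = 0`, `V` increases monotonically to `upsilon_s`, and the
#' result is real up to rounding (the complex conjugate pair cancels). The
#' degenerate repeated-root case is handled by the analytic limit formula.
#'
#' @param lm a [linear_system()].
#' @param tau dimensionless times (>= 0), vector.
#' @return numeric vector `V(tau)`.
#' @export
analytic_velocity <- function(lm, tau) {
  stopifnot(inherits(lm, "linear_settling_model"))
  if (any(tau < 0)) stop("'tau' must be >= 0", call. = FALSE)
  if (lm$B == 0) {
    # history-free single-pole relaxation: A dV/dtau = 1 - C V
    return(lm$upsilon_s * (1 - exp(-lm$C * tau / lm$A)))
  }
  s1 <- lm$s1; s2 <- lm$s2; A <- lm$A
  if (lm$degenerate) {
    # repeated root s0: V = (1/A)[ 1/s0^2 - K/s0^2 + 2 tau K
    #                              + 2 sqrt(tau)/(sqrt(pi) s0) ],
    # K = exp(s0^2 tau) erfc(-s0 sqrt(tau)); limit s2 -> s1 of the generic
    # two-pole expression.
    s0 <- (s1 + s2) / 2
    K <- erfcx_scaled(s0, tau)
    V <- (1 / A) * (1 / s0^2 - K / s0^2 + 2 * tau * K +
                    2 * sqrt(tau) / (sqrt(pi) * s0))
  } else {
    K1 <- erfcx_scaled(s1, tau)
    K2 <- erfcx_scaled(s2, tau)
    V <- (1 / (A * (s2 - s1))) * (1 / s1 - 1 / s2 + K2 / s2 - K1 / s1)
  }
  if (max(abs(Im(V))) > 1e-9)
    warning("large imaginary residue in analytic velocity: ",
            max(abs(Im(V))))
  out <- Re(V)
  out[tau == 0] <- 0  # exact initial condition (kills the rounding residue)
  out
}

#' Large-time asymptotic settling velocity
#'
#' The algebraic tail of the linearized solution,
#' `V(tau) ~ upsilon_s (1 - B upsilon_s / sqrt(tau))` with
#' `B = 3 sqrt(chi/(2 pi))`: the relative deviation from terminal velocity
#' decays as `1/sqrt(tau)` (it halves when `tau` is quadrupled). This tail is
#' what the a-priori settling time and distance estimates are built on.
#'
#' @param chi density ratio (>= 0).
#' @param upsilon_s relative terminal velocity, in (0, 1].
#' @param tau dimensionless times (> 0).
#' @return numeric vector of asymptotic velocities.
#' @export
asymptotic_velocity <- function(chi, upsilon_s, tau) {
  check_positive(chi, "chi", strict = FALSE)
  if (any(tau <= 0))
    stop("'tau' must be > 0: the tail formula diverges at tau = 0",
         call. = FALSE)
  B <- history_coefficient(chi)
  upsilon_s * (1 - B * upsilon_s / sqrt(tau))
}

#' Trajectory of the linearized model
#'
#' Samples [analytic_velocity()] on a grid and accumulates the traveled
#' distance by trapezoidal integration on an 8-fold refined grid (the
#' velocity is smooth away from `tau = 0`, where it behaves like
#' `tau - O(tau^{3/2})`).
#'
#' @param lm a [linear_system()].
#' @param tau_grid strictly increasing grid starting at a value >= 0.
#' @param scales optional [particle_scales()] to attach dimensional columns.
#' @return a `settling_trajectory` data.frame (`tau`, `upsilon`, `ell`).
#' @export
analytic_trajectory <- function(lm, tau_grid, scales = NULL) {
  stopifnot(inherits(lm, "linear_settling_model"))
  if (any(diff(tau_grid) <= 0) || tau_grid[1] < 0)
    stop("'tau_grid' must be strictly increasing and non-negative",
         call. = FALSE)
  refine <- 8L
  if (tau_grid[1] > 0) tau_grid <- c(0, tau_grid)
  fine <- unique(sort(c(tau_grid,
                        approx(seq_along(tau_grid), tau_grid,
                               n = refine * length(tau_grid))$y)))
  Vf <- analytic_velocity(lm, fine)
  ellf <- c(0, cumsum(0.5 * diff(fine) * (Vf[-1] + Vf[-length(Vf)])))
  idx <- match(tau_grid, fine)
  new_trajectory_nondim(tau_grid, Vf[idx], ellf[idx], scales = scales,
                        meta = list(model = "linearized", window = FALSE,
                                    chi = lm$chi))
}
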