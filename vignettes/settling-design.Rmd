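---
title: "Planning gravimetric sedimentation assays: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning gravimetric sedimentation assays: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedsphere)
```

## The measurement problem

Gravimetric sedimentation infers the mean density of a single spherical
particle from its terminal settling velocity. For particles whose density is
close to that of the fluid — water-swollen starch microspheres are the
motivating case, with relative density contrasts of a few percent — two
complications make a naive Stokes-law reading unreliable:

1. **Finite Reynolds number.** For contrasts around 0.02 g/cm³ in water the
   Stokes-law inversion is valid only up to diameters of roughly 330 µm
   (`stokes_diameter_limit()`); swollen microspheres are routinely larger.
2. **A long unsteady transient.** Because the density ratio
   $\chi = \rho_f/\bar\rho_p$ is close to 1, the added-mass and Basset
   history forces are comparable to the net weight, and the velocity creeps
   towards its terminal value with an *algebraic* $1/\sqrt{t}$ tail rather
   than an exponential one. Reading the velocity too early biases the
   inferred density low.

The package provides the forward models (transient and steady), the inverse
step (density from measured terminal velocity), and — the design payoff —
closed-form a-priori estimates of how long and how far a particle must fall
before its velocity is terminal to within $n\%$.

## Dynamic model

Newton's second law for a sphere settling from rest in a quiescent fluid,
with downward positive:

$$m_p \frac{dv}{dt} = (m_p - V_p\rho_f)g - F_D - F_{AM} - F_H,$$

with quasi-steady drag $F_D = \tfrac12 \rho_f v^2 A_p C_D(\mathrm{Re})$,
added mass $F_{AM} = \tfrac12 \rho_f V_p \, dv/dt$, and the Basset history
force in its windowed form

$$F_H = \tfrac32 d_p^2 \sqrt{\pi\rho_f\mu_f}
  \int_{\max(0,\,t-t_H)}^{t} \frac{dv(t')}{dt'}\frac{dt'}{\sqrt{t-t'}},
\qquad
t_H = \frac{\rho_f d_p^2/\mu_f}{(0.502\,\mathrm{Re} + 0.123)^2}.$$

The window horizon $t_H$ (Dorgan–Loth model) shrinks as the instantaneous
Reynolds number grows: fast flow erases the influence of old accelerations.
The lower integration limit is $\max(0, t - t_H)$ — the window truncates
*old* history; a negative lower limit would be meaningless for a particle
started at rest at $t = 0$.

Scaling velocity by the Stokes terminal velocity
$v_{Stokes} = g\,\Delta\rho\, d_p^2/(18\mu_f)$ and time by the relaxation
time $t_r = m_p/(3\pi\mu_f d_p)$ gives

$$\Big(1+\frac{\chi}{2}\Big)\frac{d\upsilon}{d\tau}
 = 1 - \upsilon\, c_D(\upsilon\,\mathrm{Re}_{St})
 - B \int_{\max(0,\,\tau-\tau_H)}^{\tau}
     \frac{d\upsilon}{d\tau'}\frac{d\tau'}{\sqrt{\tau-\tau'}},
 \qquad \upsilon(0) = 0,$$

where $c_D(\mathrm{Re}) = (\mathrm{Re}/24)\,C_D(\mathrm{Re})$ is the
drag-correction factor (1 in the Stokes limit),
$\mathrm{Re}_{St}$ the Reynolds number at $v_{Stokes}$, and
$\tau_H = 18\chi/(0.502\,\upsilon\mathrm{Re}_{St}+0.123)^2$.

**The history coefficient.** Nondimensionalizing the Basset kernel gives

$$B = \frac{3}{2}\sqrt{\frac{2\chi}{\pi}} = 3\sqrt{\frac{\chi}{2\pi}},$$

i.e. $B^2 = 9\chi/(2\pi)$. The package treats the *dimensional* formulation
as ground truth: `simulate_settling_dimensional()` integrates the unscaled
force balance with the kernel coefficient
$\tfrac32 d_p^2\sqrt{\pi\rho_f\mu_f}$ taken directly from the force law,
and the test suite requires the rescaled result to coincide with the
nondimensional solver (it does, to ~1e-14 relative), which pins $B$. This
value of $B$ is also exactly the one under which the settling-time and
distance estimates below acquire their $2500/\pi$ and $780$ prefactors, so
the whole chain is internally consistent.

## Drag correlations

`drag_model()` registers the correlations with their printed coefficients
and validity ranges:

| model | form | validity (Re) |
|---|---|---|
| `stokes` | $c_D = 1$ | $\le 0.5$ |
| `oseen` | $c_D = 1 + 3\mathrm{Re}/16$ | $\le 1$ |
| `schiller_naumann` | $c_D = 1 + 0.15\,\mathrm{Re}^{0.687}$ | $\le 800$ |
| `clift_grace_weber` | three branches (see below) | $\le 260$ |
| `brown_lawler` | $c_D = 1 + 0.150\,\mathrm{Re}^{0.681} + 0.40\,\mathrm{Re}^2/(24(\mathrm{Re}+8710))$ | $\le 2\cdot10^5$ |
| `flemmer_banks` | $c_D = 10^E$ | $\le 3\cdot10^5$ |
| `terfous_hazzab_ghenaim` | five-term $C_D$ formula | $[0.1, 5\cdot10^4]$ |

CGW branches: $1 + \mathrm{Re}/128$ for $\mathrm{Re}\le0.01$;
$1 + 0.131\,\mathrm{Re}^{0.82-0.05\log_{10}\mathrm{Re}}$ for
$0.01<\mathrm{Re}\le20$; $1 + 0.193\,\mathrm{Re}^{0.6305}$ for
$20<\mathrm{Re}\le260$. Branch edges are half-open exactly as written and
the small jump discontinuities are accepted, not smoothed. Coefficients are
deliberately `0.131`/`0.193`/`0.40` even where the wider literature prints
an extra digit; the constant table in `src/settle.cpp` is the single source
of truth for both the registry and the transient solver.

Two behaviours worth knowing:

* **Range policy.** Outside a model's validity range the default policy is
  `"warn"` (evaluate the printed formula anyway); `"strict"` raises an
  error naming the interval. In particular, the CGW model evaluated above
  Re = 260 extrapolates its third branch. Our comparison of
  Schiller–Naumann against CGW stays within 6% over the CGW validity range;
  on the *extrapolated* branch the two fits drift apart (≈12% at Re = 800),
  which is a property of the extrapolation, not of the standard drag curve.
* **Flemmer–Banks artifact.** The single-formula FB fit dips below
  $c_D = 1$ at very low Re, which makes the relative terminal velocity
  $\upsilon_s(\mathrm{Re}_{St})$ non-monotonic for
  $\mathrm{Re}_{St} \lesssim 1$. The package reproduces the formula as
  printed and the tests assert the artifact instead of hiding it; FB is
  simply not recommended below $\mathrm{Re}_{St}\approx3$.

## Terminal velocity and density inversion

The steady balance reduces to the scalar root problem
$\upsilon_s\, c_D(\upsilon_s \mathrm{Re}_{St}) = 1$, solved by bracketed
root finding on $(10^{-12}, 1]$ with absolute tolerance $10^{-12}$ (the
bracket is guaranteed for $c_D \ge 1$ models; it is widened above 1 for
FB). The inverse path needs no iteration at all:
$\Delta\rho = 3\rho_f v_s^2 C_D(\mathrm{Re}_s)/(4 g d_p)$ with
$\mathrm{Re}_s$ evaluated at the measured velocity — algebraically exact,
and the forward/inverse round trip closes to 1e-8 relative in the tests.

## Transient solver numerics

* **Time stepping.** Uniform grid, Crank–Nicolson on the quasi-steady drag
  term, Picard fixed-point iteration within each step (absolute tolerance
  $10^{-10}$ in $\upsilon$, cap 50; the step nonlinearity is mild and 2–6
  iterations are typical). The $\chi = 0$, Stokes-drag limit has the exact
  solution $\upsilon = 1 - e^{-\tau}$ and the scheme reproduces it to
  ~3e-8 at the default step $\Delta\tau = 10^{-3}$.
* **History quadrature.** Product integration: $d\upsilon/d\tau$ is
  piecewise constant per step and the $1/\sqrt{\tau-\tau'}$ kernel is
  integrated exactly, giving lag weights
  $2\sqrt{h}(\sqrt{m}-\sqrt{m-1})$. This handles the endpoint singularity
  without special-casing and makes the history term a discrete convolution;
  the weights are unit-tested against closed-form Abel integrals.
* **Window truncation.** The horizon is evaluated at the current Picard
  iterate; the partially covered oldest interval gets the exact partial
  weight $2(\sqrt{\tau_H}-\sqrt{\cdot})$.
* **Degenerate inputs.** $\Delta\rho = 0$ yields the zero trajectory;
  $\chi = 0$ switches off added mass and history; a velocity iterate driven
  below zero (possible only at zero forcing) is clamped at rest.
* **Cost.** The windowed solver is $O(N \cdot W)$ with $W$ the window
  length in steps; the no-window solver is $O(N^2)$. Both are implemented
  in compiled code (`src/settle.cpp`). Test-suite runs use
  $\tau_{end} \le 400$ and steps of $10^{-3}$–$10^{-2}$, which keeps each
  simulated trajectory below a few seconds; the step is an accuracy knob,
  and halving it moves endpoints by well under $10^{-5}$.

`tau_end` has no default: a sensible horizon depends on the accuracy target
(use `settling_time()` to pick one; the CLI does exactly that).

## The linearized solution and its evaluation

Freezing the drag-correction factor at its terminal value
($C = 1/\upsilon_s$) linearizes the equation; by a Tchaplygin
differential-inequality argument the linearized velocity $V(\tau)$
under-runs the nonlinear $\upsilon(\tau)$ at every $\tau$ while sharing its
limit, so estimates built on $V$ are conservative. The Laplace transform

$$\hat V(s) = \frac{1}{s\,[A s + B\sqrt{\pi s} + 1/\upsilon_s]}$$

inverts in closed form through the roots $s_{1,2}$ (in $\sqrt{s}$) of
$A x^2 + \sqrt{\pi}B x + 1/\upsilon_s$:

$$V(\tau) = \frac{1}{A(s_2 - s_1)}\Big\{\frac{1}{s_1}-\frac{1}{s_2}
 + \frac{e^{s_2^2\tau}\operatorname{erfc}(-s_2\sqrt{\tau})}{s_2}
 - \frac{e^{s_1^2\tau}\operatorname{erfc}(-s_1\sqrt{\tau})}{s_1}\Big\}.$$

Each $e^{s^2\tau}\operatorname{erfc}(-s\sqrt{\tau})$ is evaluated as the
Faddeeva function $w(-is\sqrt{\tau})$, whose argument lies in the upper
half-plane because $\Re s_{1,2} < 0$ — so nothing overflows even at
$\tau = 10^8$. No installed R package provides a $w(z)$ that is stable at
large argument (complex-series implementations of the error function
overflow), so the package carries Weideman's 64-term rational
approximation; it is cross-checked in the tests against `pracma::erfz` at
moderate modulus, against the known asymptote at large modulus, and the
whole $V(\tau)$ against an independent fixed-Talbot numerical inverse
Laplace oracle (agreement ~5e-14). The repeated-root case
$4A/\upsilon_s = \pi B^2$ is handled by the analytic limit formula rather
than the generic two-pole expression.

For large times,

$$V(\tau) \sim \upsilon_s\Big(1 - \frac{B\,\upsilon_s}{\sqrt{\tau}}\Big):$$

the relative deviation from terminal velocity decays as $1/\sqrt{\tau}$ —
quadrupling the waiting time merely halves the error. This slow tail is the
quantitative reason early velocity readings are biased.

## A-priori settling time and distance

Setting the tail deviation to $n\%$ and converting back to dimensional
variables (the particle density and $g$ cancel identically):

$$t_{n\%} \simeq \frac{2500}{\pi n^2}\,
  \frac{\rho_f d_p^2}{\mu_f}\,\upsilon_s^2,
\qquad
l_{n\%} \simeq \frac{2500}{\pi n^2}\Big(1-\frac{n}{100}\Big)^2
  \mathrm{Re}_{St}\,\upsilon_s^3\, d_p.$$

At $n = 1$ the prefactors evaluate to $2500/\pi \approx 796$ and
$(2500/\pi)(0.99)^2 \approx 780$; since $796 < 800$ and
$\upsilon_s \le 1$, the time estimate is always at least as sharp as the
classical Bernhardt rule $t_{99} \approx 800\,\rho_f d_p^2/\mu_f$
(`bernhardt_t99()`). The $1/n^2$ scaling is the practical lever: accepting
2% instead of 1% accuracy cuts both the waiting time and the required
vessel depth roughly fourfold. The distance formula's $\upsilon_s^3$ power
is fixed by the identity $l_n \approx v_s\, t_n (1-n/100)^2$, which is also
what yields the printed 780 prefactor.

Because the estimates derive from an asymptotic tail, the tests check them
two ways: the $\tau$ at which the closed-form $V$ actually crosses
$(1-n/100)\upsilon_s$ agrees with $\tau_{n\%}$ within 15% across
$\chi \in [0.8, 1)$, $\mathrm{Re}_{St} \in [0.5, 50]$, $n \in \{1,2,5\}$;
and the full nonlinear, windowed dynamics reach the $n\%$ band strictly
*before* $t_{n\%}$ (conservatism). A caveat the tests respect: strictly,
$\upsilon_s$ itself depends on $g$ and $\Delta\rho$ through
$\mathrm{Re}_{St}$, so the "independent of $\bar\rho_p$ and $g$" statement
is exact only at fixed $\upsilon_s$; the test varies $g$ and $\Delta\rho$
jointly so that $\mathrm{Re}_{St}$ is held fixed while $\bar\rho_p$ and
$g$ both change.

## Synthetic measurements and the inverse path

`synthesize_measurement()` emulates a single-particle settling record: the
dimensional trajectory is simulated (window on, step $t_r/20$ by default),
sampled at a fixed rate, and Gaussian noise with standard deviation
`noise_rel * v_s` is added independently per velocity sample, with the
running integral of the velocity noise added to positions (what
dead-reckoning a noisy velocity signal produces). One RNG seed per record,
recorded in the metadata. What it deliberately does **not** emulate:
particle-tracking pixel quantization, drift or low-frequency bias in the
optics, wall and multi-particle hindrance, Brownian motion (negligible at
these sizes), or temperature drift of the viscosity. Passing the
inverse-path tests therefore demonstrates correctness of the estimator
chain under the stated noise model, not robustness to systematic
measurement error.

`fit_terminal_velocity()` fits a linear trend to the trailing 20% of the
record and accepts the plateau when the fitted relative velocity change
across that window is below 0.2% (`plateau_rel_slope = 0.002`). The window
is deliberately *not* shrunk on failure: the $1/\sqrt{t}$ creep of an
unsettled particle looks flat on any short window, so only the full tail
window is diagnostic. The threshold 0.002 was chosen to sit between the
creep signal of a record truncated at $t_{5\%}$ (≈0.5% change across the
tail window) and the trend-estimate noise floor of a settled record
sampled at a few Hz with 1% velocity noise (≈0.1%); records that fail are
still estimated but flagged unreliable, and the warning states the reason.

The end-to-end contract, exercised in the tests with 20 fixed seeds:
synthesize (1% noise, duration $10\,t_{1\%}$) → fit → invert recovers
$\Delta\rho$ within 3%, median within 1%. Truncating records earlier makes
the density error grow monotonically — the failure mode the settling-time
estimates exist to prevent.

## Interfaces

All computation is SI internally; `g_per_cm3()`, `mPa_s()`, `microns()`,
`mm()` convert laboratory units at the boundary, and YAML configs
(`read_sedimentation_config()`) accept per-field units. A thin command-line
tool (`inst/cli/sedsphere.R`) exposes `terminal`, `invert`, `simulate`,
`estimate`, `sweep`, `drag-table`, `synth` and `fit` over the same
functions, emitting CSV with `#`-prefixed metadata headers.

## Known limitations

* Spheres only; sphericity corrections are not implemented (a less
  spherical particle has higher drag and settles sooner, so the estimates
  stay conservative).
* No wall, finite-depth, or concentration (hindered settling) corrections.
* Newtonian fluid, constant temperature and viscosity.
* The drag registry stops at the printed correlations; the CGW model
  beyond Re = 260 is an extrapolation and is flagged as such.
* Rising (buoyant) particles are rejected rather than modelled.
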