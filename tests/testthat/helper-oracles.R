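# Independent numerical oracles, deliberately simpler (and slower) than the
# implementation paths they check.

# Fixed-Talbot numerical inverse Laplace transform. Node count ~24 is the
# double-precision sweet spot (the contour's exp(2N/5) factor amplifies
# round-off beyond that). Validated against known transform pairs in
# test-analytic.R before use.
talbot_inverse <- function(F, t, nodes = 24) {
  vapply(t, function(tt) {
    r <- 2 * nodes / (5 * tt)
    k <- seq_len(nodes - 1)
    th <- k * pi / nodes
    cotth <- 1 / tan(th)
    s <- r * th * (cotth + 1i)
    nu <- th + (th * cotth - 1) * cotth
    term <- Re(exp(tt * s) * F(s) * (1 + 1i * nu))
    (r / nodes) * (0.5 * exp(r * tt) * F(r) + sum(term))
  }, numeric(1))
}

# Laplace transform of the linearized settling velocity,
# Vhat(s) = 1 / (s (A s + B sqrt(pi s) + 1/upsilon_s))
settling_transform <- function(A, B, upsilon_s) {
  function(s) 1 / (s * (A * s + B * sqrt(pi * s) + 1 / upsilon_s))
}

# plain bisection for upsilon cD(upsilon Re_St) = 1, independent of uniroot
bisect_upsilon <- function(re_st, cd_fun, lo = 1e-12, hi = 1, iter = 60) {
  f <- function(u) u * cd_fun(u * re_st) - 1
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# product-integration weights for int_0^tau g(tau') / sqrt(tau-tau') dtau'
# with g piecewise constant on a uniform grid (same rule as the solver uses,
# rebuilt here from its defining integral for an independent check)
abel_weights <- function(j, h) {
  m <- seq_len(j)
  2 * sqrt(h) * (sqrt(m) - sqrt(m - 1))
}
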