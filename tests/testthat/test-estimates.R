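test_that("settling time and distance carry the printed design prefactors", {
  water <- water_ref()
  p <- particle_ref()
  sn <- drag_model("sn")
  est1 <- settling_time(p, water, sn, n_percent = 1)
  visc_scale <- water$rho_f * p$d_p^2 / water$mu_f
  pref_t <- est1$t_n / (visc_scale * est1$upsilon_s^2)
  expect_equal(round(pref_t), 796)
  expect_equal(pref_t, 2500 / pi, tolerance = 1e-12)
  expect_lt(pref_t, 800)   # never exceeds Bernhardt's conservative constant
  pref_l <- est1$l_n / (est1$scales$Re_St * est1$upsilon_s^3 * p$d_p)
  expect_equal(round(pref_l), 780)
  expect_equal(pref_l, 2500 / pi * 0.99^2, tolerance = 1e-12)
})

test_that("reference configuration yields ~5 s and ~2.6 cm at the 5% level", {
  est5 <- settling_time(particle_ref(), water_ref(), drag_model("sn"),
                        n_percent = 5)
  expect_equal(est5$t_n, 5.0, tolerance = 2e-3)
  expect_equal(est5$l_n, 2.6e-2, tolerance = 2e-2)
  expect_equal(est5$t_n, est5$scales$t_r * est5$tau_n, tolerance = 1e-12)
  # sqrt(tau_0 / tau_n) = n/100 links the distance offset to the accuracy
  expect_equal(sqrt(est5$tau_0 / est5$tau_n), 0.05, tolerance = 1e-12)
})

test_that("relaxing the accuracy from 1% to 2% cuts the settling time fourfold", {
  t1 <- settling_time(particle_ref(), water_ref(), drag_model("sn"), 1)$t_n
  t2 <- settling_time(particle_ref(), water_ref(), drag_model("sn"), 2)$t_n
  expect_equal(t1 / t2, 4, tolerance = 1e-12)
  expect_error(settling_time(particle_ref(), water_ref(), drag_model("sn"),
                             0), "n_percent")
  expect_error(settling_time(particle_ref(), water_ref(), drag_model("sn"),
                             100), "n_percent")
})

test_that("settling time is blind to particle density and to g at fixed upsilon_s", {
  water <- water_ref()
  sn <- drag_model("sn")
  d <- microns(400)
  drho <- 40
  base <- settling_time(spherical_particle(d, delta_rho = drho,
                                           fluid = water), water, sn, 5)
  # the dimensional estimate collapses to fluid properties and upsilon_s:
  # t_n = (2500/(pi n^2)) rho_f d_p^2 upsilon_s^2 / mu_f, with rho_p and g
  # cancelled (rho_p enters t_r and chi in compensating ways)
  expect_equal(base$t_n, 2500 / (pi * 25) * water$rho_f * d^2 *
                 base$upsilon_s^2 / water$mu_f, tolerance = 1e-12)
  # halve g while doubling delta_rho: g*delta_rho (hence Re_St, upsilon_s)
  # is fixed while rho_p and g both change -> t_n must not move
  water2 <- fluid_medium(rho_f = water$rho_f, mu_f = water$mu_f,
                         g = water$g / 2)
  p3 <- spherical_particle(d, delta_rho = 2 * drho, fluid = water2)
  est3 <- settling_time(p3, water2, sn, 5)
  expect_equal(est3$scales$Re_St, base$scales$Re_St, tolerance = 1e-12)
  expect_gt(est3$scales$rho_p, base$scales$rho_p)
  expect_equal(est3$t_n, base$t_n, tolerance = 1e-12)
})

test_that("tightening distance accuracy from 3% to 2% roughly doubles the vessel depth", {
  l2 <- settling_distance(particle_ref(), water_ref(), drag_model("sn"),
                          2)$l_n
  l3 <- settling_distance(particle_ref(), water_ref(), drag_model("sn"),
                          3)$l_n
  ratio <- l2 / l3
  expect_equal(ratio, 9 / 4 * (0.98 / 0.97)^2, tolerance = 1e-12)
  expect_gt(ratio, 2.0)
  expect_lt(ratio, 2.5)
})

test_that("Bernhardt's t99 rule is quadratic in diameter and bounds t_1%", {
  water <- water_ref()
  expect_equal(bernhardt_t99(water, microns(500)), 224, tolerance = 1e-3)
  expect_equal(bernhardt_t99(water, microns(1000)),
               4 * bernhardt_t99(water, microns(500)), tolerance = 1e-12)
  for (d in microns(c(100, 400, 900))) {
    p <- spherical_particle(d, delta_rho = 30, fluid = water)
    expect_lte(settling_time(p, water, drag_model("cgw"), 1)$t_n,
               bernhardt_t99(water, d))
  }
})

test_that("the settling-time estimate tracks the linearized solution's n% crossing", {
  sn <- drag_model("sn")
  for (chi in c(0.8, 0.95)) {
    for (re_st in c(0.5, 5, 50)) {
      us <- relative_terminal_velocity(re_st, sn)
      lm0 <- linear_system(chi, us)
      B <- lm0$B
      for (n in c(1, 2, 5)) {
        tau_n <- (100 * B * us / n)^2
        cross <- uniroot(function(tau)
          analytic_velocity(lm0, tau) - (1 - n / 100) * us,
          c(tau_n / 10, tau_n * 10), tol = 1e-8)$root
        expect_lt(abs(cross - tau_n) / tau_n, 0.15)
      }
    }
  }
})

test_that("the estimate is conservative: the nonlinear dynamics settle no later", {
  sn <- drag_model("sn")
  sc <- scales_ref()
  us <- relative_terminal_velocity(sc$Re_St, sn)
  sys <- dimensionless_system(sc$chi, sc$Re_St, sn)
  for (n in c(2, 5)) {
    est <- settling_time(particle_ref(), water_ref(), sn, n)
    tr <- simulate_settling(sys, tau_end = est$tau_n, step = 5e-3)
    cross_idx <- which(tr$upsilon >= (1 - n / 100) * us)[1]
    expect_false(is.na(cross_idx))
    expect_lt(tr$tau[cross_idx], est$tau_n)
  }
})

test_that("design sweep rows agree with the scalar operations and flag bad rows", {
  water <- water_ref()
  sn <- drag_model("sn")
  tab <- design_sweep(water, delta_rho_rel = 0.05,
                      d_p = microns(c(200, 500, 1000)), n_percent = 5,
                      model = sn)
  expect_true(all(tab$ok))
  i <- which(tab$d_p == microns(500))
  est <- settling_time(particle_ref(), water, sn, 5)
  expect_equal(tab$t_n[i], est$t_n, tolerance = 1e-12)
  expect_equal(tab$l_n[i], est$l_n, tolerance = 1e-12)
  expect_equal(tab$v_s[i], est$v_s, tolerance = 1e-12)
  # Re_St ~ d_p^3 at fixed contrast
  expect_equal(tab$Re_St[tab$d_p == microns(1000)] /
                 tab$Re_St[tab$d_p == microns(200)], 125,
               tolerance = 1e-10)
  # an unphysical contrast is flagged, not fatal
  tab2 <- design_sweep(water, delta_rho_rel = c(-0.01, 0.05),
                       d_p = microns(500), n_percent = 5, model = sn)
  expect_identical(tab2$ok, c(FALSE, TRUE))
  expect_match(tab2$note[1], "delta_rho|rho_p")
})
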