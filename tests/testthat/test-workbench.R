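test_that("synthetic records are deterministic and noiseless records track the simulation", {
  water <- water_ref()
  p <- particle_ref()
  sn <- drag_model("sn")
  r1 <- synthesize_measurement(p, water, sn, duration = 2, rate = 20,
                               noise_rel = 0.01, seed = 7)
  r2 <- synthesize_measurement(p, water, sn, duration = 2, rate = 20,
                               noise_rel = 0.01, seed = 7)
  expect_identical(r1$velocities, r2$velocities)
  expect_identical(r1$positions, r2$positions)
  r3 <- synthesize_measurement(p, water, sn, duration = 2, rate = 20,
                               noise_rel = 0.01, seed = 8)
  expect_false(identical(r1$velocities, r3$velocities))
  # noiseless record equals the simulated trajectory at the sample times
  tr <- simulate_settling_dimensional(p, water, sn, t_end = 2,
                                      dt = scales_ref()$t_r / 20)
  r0 <- synthesize_measurement(p, water, sn, duration = 2, rate = 20,
                               noise_rel = 0, seed = 1, trajectory = tr)
  expect_equal(r0$velocities,
               approx(tr$t, tr$v, xout = r0$times)$y, tolerance = 1e-14)
  expect_error(synthesize_measurement(p, water, sn, duration = 0.01,
                                      rate = 10), "sample interval")
})

test_that("a 30 s record of the reference particle is within 2% of terminal velocity", {
  rec <- synthesize_measurement(particle_ref(), water_ref(),
                                drag_model("sn"), duration = 30, rate = 10)
  last_sec <- rec$velocities[rec$times > 29]
  expect_equal(mean(last_sec), 5.75e-3, tolerance = 0.02)
})

test_that("plateau fitting recovers v_s on settled records and returns constants exactly", {
  rec_const <- measurement_record(seq(0.1, 10, by = 0.1),
                                  velocities = rep(3.2e-3, 100))
  fit <- fit_terminal_velocity(rec_const)
  expect_identical(fit$v_s, 3.2e-3)
  expect_true(fit$reliable)
  expect_identical(unname(coef(fit)), 3.2e-3)
  # noiseless record lasting 10x the 1% settling time: within 0.2%
  tr <- long_trajectory_ref()
  rec <- synthesize_measurement(particle_ref(), water_ref(),
                                drag_model("sn"), duration = 1250,
                                rate = 2, noise_rel = 0, trajectory = tr)
  fit2 <- fit_terminal_velocity(rec)
  v_true <- terminal_velocity(particle_ref(), water_ref(),
                              drag_model("sn"))$v_s
  expect_true(fit2$reliable)
  expect_equal(fit2$v_s, v_true, tolerance = 0.002)
})

test_that("records truncated before settling are flagged and biased low", {
  water <- water_ref()
  p <- particle_ref()
  sn <- drag_model("sn")
  sc <- scales_ref()
  v_true <- terminal_velocity(p, water, sn)$v_s
  tr <- nowindow_trajectory_ref()   # spans tau = 400 > tau_5% ~ 306
  est5 <- settling_time(p, water, sn, 5)
  rec5 <- synthesize_measurement(p, water, sn, duration = est5$t_n,
                                 rate = 50, noise_rel = 0, trajectory = tr)
  expect_warning(fit5 <- fit_terminal_velocity(rec5), "not settled")
  expect_false(fit5$reliable)
  expect_lt(fit5$v_s, v_true)                 # biased low ...
  expect_lt((v_true - fit5$v_s) / v_true, 0.06)  # ... by about <= 5%
  # error grows monotonically with earlier truncation
  errs <- sapply(c(0.25, 0.5, 1) * est5$t_n, function(dur) {
    rec <- synthesize_measurement(p, water, sn, duration = dur, rate = 50,
                                  noise_rel = 0, trajectory = tr)
    fit <- suppressWarnings(fit_terminal_velocity(rec))
    (v_true - fit$v_s) / v_true
  })
  expect_true(all(diff(errs) < 0))
})

test_that("position-only records are differenced before fitting", {
  tt <- seq(0.5, 60, by = 0.5)
  rec <- measurement_record(tt, positions = 2e-3 * tt)
  fit <- fit_terminal_velocity(rec)
  expect_equal(fit$v_s, 2e-3, tolerance = 1e-10)
})

test_that("end-to-end density recovery from noisy records stays within tolerance", {
  water <- water_ref()
  p <- particle_ref()
  sn <- drag_model("sn")
  drho_true <- p$rho_p - water$rho_f
  tr <- long_trajectory_ref()
  errs <- sapply(1:20, function(seed) {
    rec <- synthesize_measurement(p, water, sn, duration = 1250, rate = 5,
                                  noise_rel = 0.01, seed = seed,
                                  trajectory = tr)
    fit <- suppressWarnings(fit_terminal_velocity(rec))
    drho_hat <- density_from_terminal_velocity(fit$v_s, p$d_p, water, sn)
    abs(drho_hat - drho_true) / drho_true
  })
  expect_lt(max(errs), 0.03)
  expect_lt(median(errs), 0.01)
})

test_that("measurement CSV files round-trip values and metadata", {
  rec <- synthesize_measurement(particle_ref(), water_ref(),
                                drag_model("sn"), duration = 2, rate = 20,
                                noise_rel = 0.02, seed = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_measurement_csv(rec, path)
  rec2 <- read_measurement_csv(path)
  expect_equal(rec2$times, rec$times, tolerance = 1e-12)
  expect_equal(rec2$velocities, rec$velocities, tolerance = 1e-12)
  expect_equal(rec2$positions, rec$positions, tolerance = 1e-12)
  expect_equal(rec2$meta$d_p, rec$meta$d_p)
  expect_equal(rec2$meta$seed, 3)
  expect_identical(rec2$meta$model, "schiller_naumann")
})

test_that("YAML configuration files parse with laboratory units", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c(
    "fluid:",
    "  rho_f: 0.997", "  mu_f: 0.89", "  g: 9.87",
    "  units: {rho_f: g/cm3, mu_f: mPa.s}",
    "particle:",
    "  d_p: 500", "  delta_rho: 0.02",
    "  units: {d_p: um, delta_rho: g/cm3}"), path)
  cfg <- read_sedimentation_config(path)
  expect_equal(cfg$fluid$rho_f, 997)
  expect_equal(cfg$fluid$mu_f, 0.89e-3)
  expect_equal(cfg$particle$d_p, 5e-4)
  expect_equal(cfg$particle$rho_p, 997 + 20)
})

test_that("the command-line tool tabulates drag correlations", {
  cli <- system.file("cli", "sedsphere.R", package = "sedsphere")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out_file <- tempfile(fileext = ".csv")
  on.exit(unlink(out_file))
  res <- system2(rscript, c(cli, "drag-table", "--model", "sn",
                            "--re-min", "1", "--re-max", "10",
                            "--points", "5", "--out", out_file),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(out_file))
  tab <- read.csv(out_file, comment.char = "#")
  expect_named(tab, c("re", "c_d", "C_D"))
  expect_equal(tab$c_d[1], 1.15, tolerance = 1e-10)
})
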