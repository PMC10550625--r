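# Reference configuration used throughout: a water-swollen microsphere of
# 500 um diameter with 5% relative density contrast in water. Its derived
# scales (frozen from direct hand evaluation of the defining formulas):
#   v_Stokes ~ 7.678e-3 m/s, t_r ~ 1.634e-2 s, chi ~ 0.9524, Re_St ~ 4.30.

water_ref <- function() fluid_medium(rho_f = 997, mu_f = 0.89e-3, g = 9.87)

particle_ref <- function(fluid = water_ref())
  spherical_particle(microns(500), delta_rho = 0.05 * fluid$rho_f,
                     fluid = fluid)

scales_ref <- function() particle_scales(particle_ref(), water_ref())

# memoized long noiseless settling trajectory for the measurement-path tests
# (10x the 1% settling time ~ 1250 s); simulated once per test run
.fixture_env <- new.env(parent = emptyenv())

long_trajectory_ref <- function() {
  if (is.null(.fixture_env$long_traj)) {
    sc <- scales_ref()
    .fixture_env$long_traj <- simulate_settling_dimensional(
      particle_ref(), water_ref(), drag_model("sn"),
      t_end = 1250, dt = sc$t_r / 20, window = TRUE)
  }
  .fixture_env$long_traj
}

# no-window trajectory spanning the 5% settling time, for truncation-bias
# tests (the history tail is what biases an early reading)
nowindow_trajectory_ref <- function() {
  if (is.null(.fixture_env$nw_traj)) {
    sc <- scales_ref()
    .fixture_env$nw_traj <- simulate_settling_dimensional(
      particle_ref(), water_ref(), drag_model("sn"),
      t_end = 400 * sc$t_r, dt = 0.01 * sc$t_r, window = FALSE)
  }
  .fixture_env$nw_traj
}
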