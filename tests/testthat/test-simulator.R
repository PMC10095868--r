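test_that("soft wall: the cell expands exactly by the influx and turgor stays flat", {
  for (shape in c("mb_cdf", "sat_exp")) {
    tr <- run_default("soft", shape)
    st <- summarize_trajectory(tr)
    expect_identical(st$V_final, 4603)
    expect_true(all(tr$p == 0))
    expect_equal(tr$V_cell, 3691 + tr$W)
    expect_equal(st$vol_increase_pct, 100 * 912 / 3691)
  }
})

test_that("rigid wall: volume is fixed and turgor follows the compressed fluid", {
  tr <- run_default("rigid")
  expect_true(all(tr$V_cell == 3691))
  expect_equal(summarize_trajectory(tr)$p_final, 2200 * 912 / 4603,
               tolerance = 1e-12)
})

test_that("elastic endpoint is 1.3 MPa and independent of the influx family", {
  p_hand <- 912 / (4603 / 2200 + 3691 * 0.19)
  finals <- vapply(c("mb_cdf", "sat_exp", "logistic"), function(shape) {
    summarize_trajectory(run_default("elastic", shape))$p_final
  }, numeric(1))
  expect_equal(unname(finals), rep(p_hand, 3), tolerance = 1e-12)
  # elastic turgor is non-decreasing under monotone influx
  expect_true(all(diff(run_default("elastic")$p) >= 0))
})

test_that("trajectories satisfy their structural invariants", {
  for (model in c("rigid", "elastic", "viscoelastic")) {
    tr <- run_default(model)
    expect_equal(tr$t, seq(0, max(tr$t), by = 1))
    expect_identical(tr$V_cell[1], 3691)
    expect_identical(tr$p[1], 0)
    expect_true(all(diff(tr$W) >= 0))
    expect_lt(max(mass_balance_residual(tr, K = 2200)), 1e-6)
  }
})

test_that("pressure ordering rigid >= elastic >= soft holds at every step", {
  p_r <- run_default("rigid")$p
  p_e <- run_default("elastic")$p
  p_s <- run_default("soft")$p
  expect_true(all(p_r >= p_e))
  expect_true(all(p_e >= p_s))
  expect_true(all(p_s == 0))
})

test_that("fixed-point solver reproduces the closed form", {
  f <- default_fluid()
  cfg <- default_cfg("elastic")
  # single-step checks against hand closed forms
  expect_identical(
    step_fixed_point(912, 0, 0, wall_parameters("soft"), f, cfg), 0)
  expect_equal(
    step_fixed_point(912, 0, 0, wall_parameters("rigid"), f, cfg),
    2200 * 912 / 4603, tolerance = 1e-9)
  expect_equal(
    step_fixed_point(912, 0, 0, wall_parameters("elastic"), f, cfg),
    912 / (4603 / 2200 + 3691 * 0.19), tolerance = 1e-9)
  # whole-trajectory equivalence, elastic and viscoelastic
  for (model in c("elastic", "viscoelastic")) {
    t_cf <- run_default(model)
    t_fp <- run_simulation(default_cfg(model, solver = "fixed_point"),
                           default_schedule(), wall_parameters(model),
                           f)
    expect_lt(max(abs(t_cf$p - t_fp$p) / pmax(t_cf$p, 1)), 1e-9)
  }
  expect_error(
    step_fixed_point(912, 0, 0, wall_parameters("elastic"), f,
                     simulation_config(max_iter = 1)),
    "did not converge")
})

test_that("viscoelastic turgor rises then relaxes; elastic does not decay", {
  tr <- run_default("viscoelastic")
  st <- summarize_trajectory(tr)
  expect_lt(st$t_peak, max(tr$t))
  expect_lt(st$p_final, st$p_peak)
  expect_gt(st$p_peak, 0)
  # long-time turgor approaches the equilibrium-modulus endpoint
  p_eq <- 912 / (4603 / 2200 + 3691 * (10 * 3.8 / (4 * 0.5 * 77)))
  expect_equal(st$p_final, p_eq, tolerance = 1e-3)
  # elastic turgor plateaus once influx is complete; the peak is first
  # attained when the schedule clamps
  st_el <- summarize_trajectory(run_default("elastic"))
  expect_equal(st_el$t_peak, 3600)
})

test_that("viscoelastic peak is sensitive to the early influx rate", {
  pk <- function(shape) {
    summarize_trajectory(run_default("viscoelastic", shape))$p_peak
  }
  expect_gt(pk("sat_exp"), pk("mb_cdf"))
})

test_that("tau limits recover the elastic trajectories at the matching modulus", {
  f <- default_fluid()
  s <- default_schedule()
  cfg <- simulation_config(t_total = 7200)
  # tau -> infinity: only the instantaneous branch acts. The deviation decays
  # as 1/tau (creep accumulated over the horizon), so compare at a tau large
  # enough that the truncation term is negligible.
  w_inf <- wall_parameters("viscoelastic", tau = 1e12)
  p_el_inst <- run_simulation(cfg, s, wall_parameters("elastic", E = 10000), f)$p
  d_inf <- max(abs(run_simulation(cfg, s, w_inf, f)$p - p_el_inst))
  expect_lt(d_inf, 1e-3)
  # ... and the deviation shrinks proportionally to 1/tau
  w_mid <- wall_parameters("viscoelastic", tau = 1e9)
  d_mid <- max(abs(run_simulation(cfg, s, w_mid, f)$p - p_el_inst))
  expect_equal(d_mid / d_inf, 1e3, tolerance = 0.01)
  # tau -> 0: instantaneous equilibration at the equilibrium modulus
  w0 <- wall_parameters("viscoelastic", tau = 1e-3)
  p_el_eq <- run_simulation(cfg, s, wall_parameters("elastic", E = 77), f)$p
  expect_lt(max(abs(run_simulation(cfg, s, w0, f)$p - p_el_eq)), 1e-3)
})

test_that("halving dt leaves the viscoelastic trajectory unchanged to 0.1%", {
  f <- default_fluid()
  s <- default_schedule()
  w <- wall_parameters("viscoelastic")
  t1 <- run_simulation(simulation_config(t_total = 18000, dt = 1), s, w, f)
  t2 <- run_simulation(simulation_config(t_total = 18000, dt = 0.5), s, w, f)
  common <- seq(1, nrow(t2), by = 2)
  expect_lt(max(abs(t1$p - t2$p[common])) / max(t1$p), 1e-3)
})

test_that("baseline turgor offsets the reported pressures", {
  tr <- run_simulation(default_cfg("elastic"), default_schedule(),
                       wall_parameters("elastic"), default_fluid(), p0 = 0.4)
  expect_identical(tr$p[1], 0.4)
  tr0 <- run_default("elastic")
  expect_equal(tr$p, tr0$p + 0.4)
})

test_that("summaries extract peaks, finals and the volume increase", {
  tr <- run_default("soft")
  st <- summarize_trajectory(tr)
  expect_equal(st$vol_increase_pct, 24.7087, tolerance = 1e-4)
  expect_identical(st$p_peak, 0)
  expect_identical(st$t_peak, 0)
  expect_error(summarize_trajectory(tr[0, ]))
  # viscoelastic: peak exceeds final by a large factor
  stv <- summarize_trajectory(run_default("viscoelastic", "sat_exp"))
  expect_gt(stv$p_peak / stv$p_final, 5)
})

test_that("calibration inverts the elastic endpoint and the equilibrium modulus", {
  f <- default_fluid()
  s <- default_schedule()
  E_hat <- calibrate_modulus(1.3, "final_elastic", c(10, 1000),
                             default_cfg("elastic"), s,
                             wall_parameters("elastic"), f)
  # closed-form inversion: E = 19 * V0 / (W/1.3 - V0/K - ... )
  E_hand <- 3691 * 19 / (912 / 1.3 - 4603 / 2200)
  expect_equal(E_hat, E_hand, tolerance = 2e-3)
  st <- summarize_trajectory(run_simulation(
    default_cfg("elastic"), s, wall_parameters("elastic", E = E_hat), f))
  expect_equal(st$p_final, 1.3, tolerance = 0.01)
  # long-time standard linear solid == elastic at E_eq
  p_el <- summarize_trajectory(run_default("elastic"))$p_final
  Eeq_hat <- calibrate_modulus(p_el, "final_viscoelastic", c(10, 1000),
                               default_cfg("viscoelastic"), s,
                               wall_parameters("viscoelastic"), f)
  expect_equal(Eeq_hat, 100, tolerance = 5e-3)
})

test_that("calibration rejects unbracketed targets and model mismatches", {
  f <- default_fluid()
  s <- default_schedule()
  expect_error(
    calibrate_modulus(1e6, "final_elastic", c(10, 1000),
                      default_cfg("elastic"), s, wall_parameters("elastic"), f),
    "not bracketed")
  expect_error(
    calibrate_modulus(1.3, "final_elastic", c(10, 1000),
                      default_cfg("viscoelastic"), s,
                      wall_parameters("viscoelastic"), f),
    "elastic wall")
  expect_error(
    calibrate_modulus(1.3, "peak_viscoelastic", c(10, 1000),
                      default_cfg("elastic"), s, wall_parameters("elastic"), f),
    "viscoelastic wall")
})

test_that("config invariants are enforced at construction", {
  expect_error(simulation_config(v0 = 0), "v0")
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(t_total = 0.5, dt = 1), "t_total")
  expect_error(simulation_config(tol = 0), "tol")
  expect_error(simulation_config(max_iter = 0), "max_iter")
})
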