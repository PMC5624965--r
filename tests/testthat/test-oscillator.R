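test_that("forcing functions match their closed forms and windows", {
  per <- forcing_periodic()
  expect_equal(evaluate_forcing(per, pi), 0)            # before onset
  expect_equal(evaluate_forcing(per, 5 * pi / 2), 1)    # sine maximum in window
  expect_equal(evaluate_forcing(per, 21 * pi), 0)       # after turn-off
  ts <- c(3 * pi, 7, 30)
  expect_equal(evaluate_forcing(per, ts), sin(ts))
  imp <- forcing_impulsive()
  expect_equal(evaluate_forcing(imp, 20 * pi), 1)
  expect_equal(evaluate_forcing(imp, 20 * pi + 1), exp(-1))
  expect_equal(evaluate_forcing(forcing_none(), c(0, 5, 100)), c(0, 0, 0))
  cust <- forcing_custom(function(t) 2 * t)
  expect_equal(evaluate_forcing(cust, c(1, 2)), c(2, 4))
  expect_error(evaluate_forcing(forcing_custom(function(t) stop("boom")), 1), "boom")
  expect_error(forcing_periodic(t_on = 5, t_off = 2), "t_on")
  expect_error(forcing_impulsive(width = 0), "width")
})

test_that("parameter and state validation enforce the model invariants", {
  expect_error(oscillator_params(restitution_alpha = 0), "restitution")
  expect_error(oscillator_params(restitution_alpha = 1.2), "restitution")
  expect_error(oscillator_params(stiffness_q = -1), "stiffness")
  expect_error(oscillator_params(wall_x0 = 0), "wall_x0")
  expect_error(simulate_oscillator(oscillator_params(), forcing_none(),
                                   initial_conditions(x = 0.5)),
               "exceeds the wall")
  expect_error(impact_train(c(3, 1, 2)), "ordered")
})

test_that("unforced rest state stays at rest with no impacts", {
  traj <- simulate_oscillator(oscillator_params(), forcing_none(),
                              settings = solver_settings(t_end = 20))
  expect_equal(max(abs(traj$x)), 0)
  expect_equal(max(abs(traj$v)), 0)
  expect_equal(nrow(traj$impacts), 0L)
})

test_that("undamped sub-wall motion follows the cosine closed form", {
  params <- oscillator_params(damping_p = 0, stiffness_q = 0.3,
                              restitution_alpha = 0.8, wall_x0 = 0.2)
  traj <- simulate_oscillator(params, forcing_none(),
                              initial_conditions(x = 0.1, v = 0),
                              solver_settings(t_end = 40))
  expect_equal(traj$x, 0.1 * cos(sqrt(0.3) * traj$times), tolerance = 1e-7)
  expect_equal(nrow(traj$impacts), 0L)
})

test_that("adaptive impact trains match the frozen RK4+bisection oracle", {
  for (name in c("fig2-periodic", "fig2-impulsive")) {
    traj <- preset_trajectory(name)
    orc <- fig2_fixture(name)
    expect_equal(nrow(traj$impacts), nrow(orc))
    expect_lt(max(abs(traj$impacts$time - orc$time)), 1e-5)
    expect_lt(max(abs(traj$impacts$speed_in - orc$speed_in)), 1e-6)
  }
})

test_that("live RK4 oracle agrees with the adaptive solver on the impulsive preset", {
  live <- oracle_simulate(forcing_fn = oracle_forcing_impulsive)
  traj <- preset_trajectory("fig2-impulsive")
  expect_equal(nrow(live), nrow(traj$impacts))
  expect_lt(max(abs(live$time - traj$impacts$time)), 1e-5)
  # and the frozen fixture is still what the oracle produces
  expect_equal(live$time, fig2_fixture("fig2-impulsive")$time, tolerance = 1e-9)
})

test_that("wall constraint and exact restitution hold on both presets", {
  for (name in c("fig2-periodic", "fig2-impulsive")) {
    traj <- preset_trajectory(name)
    expect_lte(max(traj$x), traj$params$wall_x0 + 10 * traj$settings$abs_tol)
    expect_true(all(traj$impacts$speed_in >= 0))
    expect_lt(max(abs(traj$impacts$speed_out / traj$impacts$speed_in - 0.8)), 1e-12)
  }
})

test_that("energy is dissipated monotonically with forcing off", {
  params <- oscillator_params()
  traj <- simulate_oscillator(params, forcing_none(),
                              initial_conditions(x = 0, v = 2),
                              solver_settings(t_end = 30))
  expect_gt(nrow(traj$impacts), 0L)
  energy <- 0.5 * traj$v^2 + 0.5 * params$stiffness_q * traj$x^2
  expect_true(all(diff(energy) <= 1e-9))
  # kinetic energy drops by the factor alpha^2 across every impact
  expect_equal(traj$impacts$speed_out^2 / traj$impacts$speed_in^2,
               rep(0.8^2, nrow(traj$impacts)), tolerance = 1e-12)
})

test_that("halving solver tolerances moves impact times by less than 1e-6", {
  for (name in c("fig2-periodic", "fig2-impulsive")) {
    cfg <- fig2_preset(name)
    base <- preset_trajectory(name)
    tight <- simulate_oscillator(cfg$params, cfg$forcing, cfg$ic,
                                 solver_settings(t_end = cfg$settings$t_end,
                                                 rel_tol = cfg$settings$rel_tol / 2,
                                                 abs_tol = cfg$settings$abs_tol / 2))
    expect_equal(nrow(base$impacts), nrow(tight$impacts))
    expect_lt(max(abs(base$impacts$time - tight$impacts$time)), 1e-6)
  }
})

test_that("persistent wall contact terminates instead of chattering forever", {
  # constant push whose equilibrium lies beyond the wall: bounces decay to rest
  push <- forcing_custom(function(t) rep(0.07, length(t)))
  expect_no_error({
    traj <- suppressWarnings(
      simulate_oscillator(oscillator_params(), push,
                          settings = solver_settings(t_end = 200)))
  })
  expect_lt(nrow(traj$impacts), 1e4)
  expect_equal(traj$times[length(traj$times)], 200)
})

test_that("impact trains carry times, intervals and speeds consistently", {
  empty <- extract_impact_train(
    simulate_oscillator(oscillator_params(), forcing_none(),
                        settings = solver_settings(t_end = 5)))
  expect_length(empty$times, 0L)
  expect_length(empty$intervals, 0L)
  tr <- impact_train(c(1, 3, 6))
  expect_equal(tr$intervals, c(2, 3))
  fix <- fig2_fixture("fig2-periodic")
  tr2 <- extract_impact_train(preset_trajectory("fig2-periodic"))
  expect_equal(tr2$times, fix$time, tolerance = 1e-5)
  expect_equal(tr2$intervals, diff(fix$time), tolerance = 1e-5)
})

test_that("periodic and impulsive presets show the expected regimes", {
  per <- preset_trajectory("fig2-periodic")$impacts
  expect_true(all(per$time > 2 * pi))            # nothing before forcing onset
  expect_gte(sum(per$time > 20 * pi), 1L)        # transient after turn-off
  imp <- preset_trajectory("fig2-impulsive")$impacts
  expect_gte(nrow(imp), 2L)
  expect_true(all(diff(imp$speed_in) < 0))       # strictly decaying knocks
  expect_true(all(imp$time > 20 * pi - 3))
})

test_that("shipped YAML configs reproduce the named presets, unknown keys rejected", {
  for (name in c("fig2-periodic", "fig2-impulsive")) {
    cfg <- read_oscillator_config(system.file("extdata", paste0(name, ".yaml"),
                                              package = "woodknock"))
    preset <- fig2_preset(name)
    expect_equal(cfg$params, preset$params)
    expect_equal(unclass(cfg$forcing), unclass(preset$forcing), tolerance = 1e-12)
    expect_equal(cfg$settings$t_end, preset$settings$t_end, tolerance = 1e-12)
  }
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("oscillator:", "  damping_p: 0.2", "  bogus_key: 1",
               "forcing:", "  variant: none"), bad)
  expect_error(read_oscillator_config(bad), "bogus_key")
})

test_that("trajectory and impact CSV outputs use the documented headers", {
  traj <- preset_trajectory("fig2-impulsive")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f1)
  write_impacts_csv(traj, f2)
  expect_identical(readLines(f1, n = 1L), "t,x,v")
  expect_identical(readLines(f2, n = 1L), "time,speed_in,speed_out")
  expect_equal(nrow(utils::read.csv(f2)), nrow(traj$impacts))
})
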