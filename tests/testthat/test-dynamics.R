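test_that("the elastic-collision velocity jump follows the two-body formula", {
  v <- c(1.2, -0.5, 0.3); v0 <- c(-2, 0.1, 4)
  # m0 = m: full velocity exchange
  expect_equal(collision_delta_v(v, 7, v0, 7), v0 - v)
  # v0 = v: no jump
  expect_equal(collision_delta_v(v, 3, v, 11), c(0, 0, 0))
  # direct substitution
  expect_equal(collision_delta_v(c(0, 0, 0), 1, c(1, 0, 0), 2), c(4 / 3, 0, 0))
  expect_error(collision_delta_v(v, 0, v0, 1), "positive")
  expect_error(collision_delta_v(v, 1, v0, -2), "positive")
})

test_that("virtual-particle velocities are Maxwellian at the setpoint", {
  expect_equal(sample_virtual_velocity(0, 12), matrix(0, 1, 3))
  set.seed(1)
  v <- sample_virtual_velocity(300, 18, n = 1e5)
  want <- KB_MDU * 300 / 18
  expect_equal(var(as.vector(v)), want, tolerance = 0.02)
  expect_equal(mean(v), 0, tolerance = 0.01 * sqrt(want))
  set.seed(5); a <- sample_virtual_velocity(300, 18, n = 10)
  set.seed(5); b <- sample_virtual_velocity(300, 18, n = 10)
  expect_identical(a, b)
})

test_that("kinetic temperature is the equipartition readout", {
  sys <- atom_system(matrix(runif(30), 10, 3), rep("A", 10), c(50, 50, 50),
                     masses = rep(23, 10), periodic = c(FALSE, FALSE, FALSE))
  expect_equal(kinetic_temperature(sys), 0)
  big <- atom_system(matrix(0, 1e4, 3), rep("A", 1e4), c(50, 50, 50),
                     masses = rep(23, 1e4), periodic = c(FALSE, FALSE, FALSE))
  big$velocities <- make_velocity_ensemble(500, big$masses, seed = 3)
  t_base <- kinetic_temperature(big)
  expect_equal(t_base, 500, tolerance = 0.02)
  big$velocities <- 2 * big$velocities
  expect_equal(kinetic_temperature(big), 4 * t_base)
  expect_error(kinetic_temperature(
    atom_system(matrix(0, 0, 3), character(), c(1, 1, 1))), "empty")
})

test_that("free streaming: zero forces and zero collisions give straight lines", {
  sys <- atom_system(rbind(c(10, 10, 10), c(30, 30, 30)), c("G", "G"),
                     c(200, 200, 200), masses = c(10, 10),
                     periodic = c(FALSE, FALSE, FALSE))
  sys$velocities <- rbind(c(1, 2, 3), c(-1, 0, 2))
  ff <- force_field(species = list(G = list(charge = 0, mass = 10,
                                            epsilon = 0, sigma = 1)),
                    cutoff = Inf, shift = FALSE)
  tr <- run_nvt(sys, ff, 0, duration = 2,
                cfg = integrator_config(dt = 0.01, sample_interval = 1),
                thermostat = thermostat_config(collision_rate = 0), seed = 1)
  expect_equal(tr$frames[[3]], sys$positions + 2 * sys$velocities,
               tolerance = 1e-12)
})

test_that("NVE dynamics conserve energy and momentum on a two-body LJ system", {
  ta <- two_atom_lj(3.55)
  sys <- ta$sys
  sys$velocities <- rbind(c(0.05, 0.02, 0), c(-0.05, -0.02, 0))
  tr <- run_nvt(sys, ta$ff, 0, duration = 1,
                cfg = integrator_config(dt = 1e-4, sample_interval = 0.05),
                thermostat = thermostat_config(collision_rate = 0), seed = 1)
  E <- tr$e_pot + tr$e_kin
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-4)
  # exact momentum conservation up to floating error
  p_series <- t(vapply(tr$vel_frames, function(v) colSums(v * sys$masses),
                       numeric(3)))
  expect_equal(p_series[nrow(p_series), ], p_series[1, ], tolerance = 1e-10)
})

test_that("trajectories are bit-identical for a fixed seed and differ across seeds", {
  toy <- make_toy_crystal(4, 1, seed = 2)
  ff <- attr(toy, "force_field")
  toy$velocities <- make_velocity_ensemble(300, toy$masses, seed = 1)
  cfg <- integrator_config(dt = 5e-4, sample_interval = 0.1)
  a <- run_nvt(toy, ff, 300, 0.5, cfg, thermostat_config(), seed = 11)
  b <- run_nvt(toy, ff, 300, 0.5, cfg, thermostat_config(), seed = 11)
  expect_identical(a$frames, b$frames)
  c3 <- run_nvt(toy, ff, 300, 0.5, cfg, thermostat_config(), seed = 12)
  expect_equal(n_frames(c3), n_frames(a))
  expect_false(identical(a$frames, c3$frames))
})

test_that("zero-duration runs return the single input frame", {
  toy <- make_toy_crystal(4, 1, seed = 2)
  ff <- attr(toy, "force_field")
  tr <- run_nvt(toy, ff, 300, 0, integrator_config(dt = 5e-4, sample_interval = 5e-4),
                thermostat_config(), seed = 1)
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$frames[[1]], toy$positions)
})

test_that("the thermostat pulls the kinetic temperature to the setpoint", {
  toy <- make_toy_crystal(8, 1, seed = 2)
  ff <- attr(toy, "force_field")
  toy$velocities <- make_velocity_ensemble(350, toy$masses, seed = 4)
  tr <- run_nvt(toy, ff, 350, duration = 6,
                cfg = integrator_config(dt = 2e-4, sample_interval = 0.05),
                thermostat = thermostat_config(collision_rate = 10), seed = 3)
  tk <- tr$t_kin[tr$times > 1]
  sem <- sd(tk) / sqrt(length(tk) / 20)   # generous correlation discount
  expect_lt(abs(mean(tk) - 350), 3 * sem + 0.02 * 350)
})

test_that("a linear heating run records the scheduled setpoint each frame", {
  sch <- heating_schedule(T0 = 700, rate = 0.1, t_max = 7000)
  expect_equal(schedule_setpoint(sch, 0), 700)
  expect_equal(schedule_setpoint(sch, 7000), 1400)
  expect_error(schedule_setpoint(sch, 7001), "domain")
  toy <- make_toy_crystal(4, 1, seed = 2)
  ff <- attr(toy, "force_field")
  toy$velocities <- make_velocity_ensemble(300, toy$masses, seed = 1)
  tr <- run_linear_heating(toy, ff, heating_schedule(300, 100, 1),
                           cfg = integrator_config(dt = 5e-4, sample_interval = 0.25),
                           thermostat = thermostat_config(collision_rate = 10),
                           seed = 6)
  expect_equal(tr$t_ref, 300 + 100 * tr$times)
  # rate 0 reproduces the fixed-T setpoint sequence
  tr0 <- run_linear_heating(toy, ff, heating_schedule(300, 0, 1),
                            cfg = integrator_config(dt = 5e-4, sample_interval = 0.25),
                            thermostat = thermostat_config(collision_rate = 10),
                            seed = 6)
  trn <- run_nvt(toy, ff, 300, 1,
                 cfg = integrator_config(dt = 5e-4, sample_interval = 0.25),
                 thermostat = thermostat_config(collision_rate = 10), seed = 6)
  expect_identical(tr0$t_ref, trn$t_ref)
  expect_identical(tr0$frames, trn$frames)
})

test_that("md_step advances one timestep and respects the blow-up guard", {
  sys <- atom_system(rbind(c(10, 10, 10), c(30, 30, 30)), c("G", "G"),
                     c(200, 200, 200), masses = c(10, 10),
                     periodic = c(FALSE, FALSE, FALSE))
  sys$velocities <- rbind(c(1, 0, 0), c(0, 0, 0))
  ff <- force_field(species = list(G = list(charge = 0, mass = 10,
                                            epsilon = 0, sigma = 1)),
                    cutoff = Inf, shift = FALSE)
  out <- md_step(sys, ff, integrator_config(dt = 0.01, sample_interval = 0.01),
                 thermostat_config(collision_rate = 0))
  expect_equal(out$positions[1, ], c(10.01, 10, 10))
  sys$velocities[1, 1] <- 1e12
  expect_error(md_step(sys, ff,
                       integrator_config(dt = 1, sample_interval = 1,
                                         blowup_threshold = 1e4),
                       thermostat_config(collision_rate = 0)),
               "blew up")
})
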