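test_that("bootstrap_previous_position is a backward Taylor step", {
  sys <- toy_system(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)))
  z <- matrix(0, 2, 3)
  st <- bootstrap_previous_position(sys, z, z, dt = 1)
  expect_equal(st$prev_positions, sys$positions)

  f <- rbind(c(1, 0, 0), c(0, 0, 0))
  st <- bootstrap_previous_position(sys, f, z, dt = 2)
  acc <- unit_constants()$acc
  disp <- f / sys$masses * acc * 4 / 2
  expect_equal(st$prev_positions, sys$positions + disp)

  # harmonic oscillator: one Verlet step from the bootstrap matches the
  # analytic trajectory to O(dt^3)
  osc <- make_oscillator()
  dt <- osc$period / 1000
  f0 <- mm_forces(osc$system, osc$params)
  st <- bootstrap_previous_position(osc$system, f0, matrix(0, 2, 3), dt)
  st2 <- verlet_step(st, f0, osc$system$masses)
  omega <- 2 * pi / osc$period
  x_analytic <- osc$r0 + osc$amplitude * cos(omega * dt)
  expect_equal(st2$positions[2, 1], x_analytic, tolerance = 1e-9)
})

test_that("Verlet conserves energy and reproduces the oscillator period", {
  sys <- toy_system(c("C", "C"), rbind(c(0, 0, 0), c(5, 0, 0)))
  traj <- run_md(sys, force_field(), n_steps = 10,
                 velocities = rbind(c(0.01, 0, 0), c(0, 0, 0)), dt = 1)
  # zero force: straight-line motion
  expect_equal(traj$positions[11, 1, 1], 0.01 * 10, tolerance = 1e-10)

  osc <- make_oscillator(kb = 100, m = 12.011, amplitude = 0.2)
  dt <- osc$period / 1000
  traj <- run_md(osc$system, osc$params, n_steps = 2000, dt = dt)
  x <- traj$positions[, 2, 1] - osc$r0
  # period from linear interpolation of zero up-crossings
  s <- which(x[-1] > 0 & x[-length(x)] <= 0)
  tcross <- traj$times[s] + dt * (-x[s]) / (x[s + 1] - x[s])
  period <- mean(diff(tcross))
  expect_equal(period, osc$period, tolerance = 1e-3)

  drift <- abs(traj$energy - traj$energy[1]) / traj$energy[1]
  expect_lt(max(drift), 1e-4)
})

test_that("the thermostat is a fixed point at the target and decouples as tau grows", {
  set.seed(31)
  sys <- toy_system(rep("Ar", 8), matrix(runif(24, 0, 20), 8, 3))
  v <- maxwell_velocities(sys$masses, 300)
  f <- matrix(0, 8, 3)
  st <- bootstrap_previous_position(sys, f, v, dt = 2)
  t0 <- instantaneous_temperature(st, sys$masses)

  fixed <- thermostat_update(st, thermostat_settings(t0, tau = 100), sys$masses)
  expect_equal(fixed$prev_positions, st$prev_positions, tolerance = 1e-12)

  slow <- thermostat_update(st, thermostat_settings(2 * t0, tau = 1e12),
                            sys$masses)
  expect_equal(slow$prev_positions, st$prev_positions, tolerance = 1e-9)

  cold <- bootstrap_previous_position(sys, f, matrix(0, 8, 3), dt = 2)
  expect_error(thermostat_update(cold, thermostat_settings(300), sys$masses),
               "cold start")
})

test_that("a free gas relaxes toward the target as exp(-t/tau)", {
  set.seed(32)
  n <- 16
  sys <- toy_system(rep("Ar", n), matrix(runif(3 * n, 0, 50), n, 3))
  tau <- 200; dt <- 2
  traj <- run_md(sys, force_field(), n_steps = 500, dt = dt, seed = 32,
                 temperature = 600,
                 thermostat = thermostat_settings(300, tau = tau))
  t_inst <- traj$temperature
  # for force-free motion the relaxation is exact per step:
  # (T - 300) shrinks by (1 - dt/tau) each step
  expected <- 300 + (t_inst[1] - 300) * (1 - dt / tau)^(seq_along(t_inst) - 1)
  expect_equal(t_inst, expected, tolerance = 1e-6)
})

test_that("the barostat scales box and coordinates by the stated increment", {
  sys <- toy_system(rep("Ar", 4), matrix(runif(12, 0, 10), 4, 3),
                    box_length = 20)
  f <- matrix(0, 4, 3)
  st <- bootstrap_previous_position(sys, f, matrix(0.001, 4, 3), dt = 2)

  same <- barostat_update(st, barostat_settings(pressure = 1, w = 1000), 1)
  expect_equal(same$box_length, 20)
  expect_equal(same$positions, st$positions)

  grown <- barostat_update(st, barostat_settings(pressure = 1, w = 1000), 1.5)
  dh <- 2 / 1000 * 0.5 * 20
  expect_equal(grown$box_length, 20 + dh)
  expect_equal(grown$positions, st$positions * (20 + dh) / 20)

  # two small updates compose like one with summed increments to first order
  two <- barostat_update(grown, barostat_settings(pressure = 1, w = 1000), 1.5)
  onebig <- barostat_update(st, barostat_settings(pressure = 1, w = 500), 1.5)
  expect_equal(two$box_length, onebig$box_length, tolerance = 1e-4)

  nobox <- bootstrap_previous_position(
    toy_system("Ar", matrix(0, 1, 3)), matrix(0, 1, 3), matrix(0, 1, 3), 2)
  expect_error(barostat_update(nobox, barostat_settings(), 2), "box")
})

test_that("run_md is deterministic under a seed and keeps an LJ dimer bound", {
  dim <- make_lj_dimer()
  t0 <- run_md(dim$system, dim$params, n_steps = 0)
  expect_equal(n_frames(t0), 1)

  t1 <- run_md(dim$system, dim$params, n_steps = 200, seed = 5,
               temperature = 30)
  t2 <- run_md(dim$system, dim$params, n_steps = 200, seed = 5,
               temperature = 30)
  expect_identical(t1$positions, t2$positions)

  t3 <- run_md(dim$system, dim$params, n_steps = 2000, seed = 6,
               temperature = 30, dt = 2)
  r <- sqrt(rowSums((t3$positions[, 2, ] - t3$positions[, 1, ])^2))
  expect_true(all(r < 2 * dim$rmin))           # never dissociates
  expect_equal(mean(r), dim$rmin, tolerance = 0.05)

  expect_error(run_md(dim$system, dim$params, 10, temperature = 300),
               "seed")
})

test_that("RMSD is superposition-aware with the d/sqrt(N) closed form", {
  set.seed(33)
  n <- 6
  ref <- matrix(runif(3 * n, 0, 10), n, 3)
  pos <- array(0, c(3, n, 3))
  pos[1, , ] <- ref
  pos[2, , ] <- sweep(ref %*% random_rotation(), 2, c(3, -2, 1), `+`)
  moved <- ref; moved[4, ] <- moved[4, ] + c(2, 0, 0)
  pos[3, , ] <- moved
  traj <- md_trajectory(0:2, pos)

  r <- trajectory_rmsd(traj)
  expect_equal(r[1], 0, tolerance = 1e-10)
  expect_equal(r[2], 0, tolerance = 1e-8)      # rigid motion superposed away

  r_nosup <- trajectory_rmsd(traj, superpose = FALSE)
  expect_equal(r_nosup[3], 2 / sqrt(n), tolerance = 1e-12)

  expect_error(trajectory_rmsd(traj, selection = integer(0)), "selection")
})

test_that("RMSF matches two-state and Gaussian-jitter closed forms", {
  n <- 5
  base <- matrix(seq_len(3 * n), n, 3)
  # static trajectory
  pos <- array(rep(base, each = 4), c(4, n, 3))
  expect_equal(trajectory_rmsf(md_trajectory(1:4, pos)), rep(0, n))

  # balanced oscillation of atom 3 through its rest point (+a, 0, -a, 0):
  # deviations are (a, 0, a, 0), so RMSF = a / sqrt(2)
  a <- 0.8
  pos <- array(rep(base, each = 4), c(4, n, 3))
  pos[1, 3, 1] <- base[3, 1] + a
  pos[3, 3, 1] <- base[3, 1] - a
  rmsf <- trajectory_rmsf(md_trajectory(1:4, pos), superpose = FALSE)
  expect_equal(rmsf[3], a / sqrt(2), tolerance = 1e-12)
  expect_equal(rmsf[-3], rep(0, n - 1))

  # planted isotropic jitter: RMSF -> sigma * sqrt(3)
  set.seed(34)
  sj <- 0.1
  nf <- 4000
  pos <- array(rep(base, each = nf), c(nf, n, 3)) +
    array(rnorm(nf * n * 3, 0, sj), c(nf, n, 3))
  rmsf <- trajectory_rmsf(md_trajectory(seq_len(nf), pos), superpose = FALSE)
  expect_equal(mean(rmsf), sj * sqrt(3), tolerance = 0.03)

  expect_error(trajectory_rmsf(md_trajectory(1, array(0, c(1, n, 3)))),
               "single frame")
})
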