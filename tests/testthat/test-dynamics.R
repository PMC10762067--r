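test_that("forces vanish at rest configurations", {
  tbl <- interaction_table()
  # two monomers at the WCA minimum, no bond
  cfg <- nucleohns:::new_particle_config(
    positions = rbind(c(5, 5, 5), c(5 + 2^(1 / 6), 5, 5)),
    species = c(1L, 1L), molecule = c(1L, 2L),
    bonds = data.frame(i = integer(0), j = integer(0), kind = character(0)),
    angles = matrix(integer(0), ncol = 3), box = 20, n_monomers = 0
  )
  f <- compute_forces(cfg, tbl)
  expect_lt(max(abs(f$forces)), 1e-9)
  expect_lt(abs(f$energy), 1e-12)

  # isolated rest-configuration triplex
  tri <- build_hns_triplex(c(10, 10, 10), c(0, 1, 0) / 1)
  cfg2 <- nucleohns:::new_particle_config(
    positions = tri$positions, species = tri$species,
    molecule = rep(1L, 3), bonds = tri$bonds, angles = tri$angles,
    box = 20, n_monomers = 0
  )
  f2 <- compute_forces(cfg2, tbl)
  expect_lt(max(abs(f2$forces)), 1e-9)
  expect_lt(abs(f2$energy), 1e-12)
})

test_that("compute_forces energy matches the brute-force Hamiltonian", {
  cfg <- small_mixed_config(seed = 21)
  f <- compute_forces(cfg)
  expect_equal(f$energy, brute_force_energy(cfg), tolerance = 1e-9)
})

test_that("forces agree with finite differences of the energy", {
  cfg <- small_mixed_config(seed = 5, n_monomers = 12, n_hns = 2, phi_c = 0.01,
                            box = 10)
  f0 <- compute_forces(cfg)
  h <- 1e-6
  n <- nrow(cfg$positions)
  scale <- max(1, max(abs(f0$forces)))
  withr::with_seed(31, idx <- sample(n, 8))
  for (i in idx) {
    for (k in 1:3) {
      cp <- cfg
      cp$positions[i, k] <- cfg$positions[i, k] + h
      ep <- compute_forces(cp)$energy
      cm <- cfg
      cm$positions[i, k] <- cfg$positions[i, k] - h
      em <- compute_forces(cm)$energy
      fd <- -(ep - em) / (2 * h)
      expect_lt(abs(fd - f0$forces[i, k]) / scale, 1e-5)
    }
  }
})

test_that("cell-list and all-pairs forces are identical", {
  for (seed in 1:3) {
    spec <- system_spec(
      n_monomers = 30, box_side = 12, phi_c = 0.08, n_hns = 4, seed = seed
    )
    cfg <- assemble_system(spec)
    cfg <- propagate(cfg, integrator_settings(seed = seed), 500)$config
    fa <- compute_forces(cfg, method = "all")
    fc <- compute_forces(cfg, method = "cell")
    expect_lt(max(abs(fa$forces - fc$forces)), 1e-10)
    expect_lt(abs(fa$energy - fc$energy), 1e-10)
  }
})

test_that("energies are invariant under lattice translations", {
  cfg <- small_mixed_config(seed = 9)
  e0 <- compute_forces(cfg)$energy
  for (shift in list(c(14, 0, 0), c(0, -28, 14), c(14, 14, 14), c(3.7, -1.2, 9.9))) {
    cp <- cfg
    cp$positions <- sweep(cfg$positions, 2, -shift)
    expect_equal(compute_forces(cp)$energy, e0, tolerance = 1e-9)
  }
})

test_that("FENE domain violations are reported with the offending bond", {
  ring <- build_ring_polymer(3, 20)
  ring$positions[1, ] <- ring$positions[1, ] + c(2.5, 0, 0)
  expect_error(compute_forces(ring), "FENE.*particles [0-9]+ and [0-9]+")
})

test_that("free particles drift uniformly without forces or thermostat", {
  cfg <- nucleohns:::new_particle_config(
    positions = rbind(c(2, 2, 2), c(15, 15, 15)),
    species = c(4L, 4L), molecule = 1:2,
    bonds = data.frame(i = integer(0), j = integer(0), kind = character(0)),
    angles = matrix(integer(0), ncol = 3), box = 20, n_monomers = 0,
    velocities = rbind(c(0.3, -0.1, 0.2), c(-0.2, 0.4, 0))
  )
  s <- integrator_settings(dt = 0.01, thermostat = FALSE)
  out <- propagate(cfg, s, 100)
  unwrapped <- out$config$positions + out$config$images * cfg$box
  expect_equal(
    unwrapped, cfg$positions + cfg$velocities * 1.0,
    tolerance = 1e-10
  )
})

test_that("NVE dynamics conserves energy", {
  # a 50-particle mixed system: 30 ring monomers, 4 dimers, 8 crowders
  spec <- system_spec(
    n_monomers = 30, box_side = 14, phi_c = 8 * (pi / 6) * 8 / 14^3,
    n_hns = 4, seed = 13
  )
  cfg <- assemble_system(spec)
  expect_equal(nrow(cfg$positions), 50)
  cfg <- propagate(cfg, integrator_settings(seed = 13), 5000)$config
  out <- propagate(
    cfg, integrator_settings(dt = 0.001, thermostat = FALSE, seed = 1),
    10000,
    sample_every = 100
  )
  etot <- out$epot + out$ekin
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 1e-4)
})

test_that("the Langevin thermostat equipartitions kinetic energy", {
  spec <- system_spec(
    n_monomers = 20, box_side = 12, phi_c = 0.02, n_hns = 2, seed = 17
  )
  cfg <- assemble_system(spec)
  out <- propagate(cfg, integrator_settings(seed = 17), 150000)
  # mean kinetic temperature over >= 1e5 steps within 2% of T = 1
  expect_lt(abs(out$mean_kinetic_temperature - 1), 0.02)
})

test_that("trajectories are reproducible from the seed", {
  spec <- system_spec(
    n_monomers = 20, box_side = 12, phi_c = 0.05, n_hns = 2, seed = 23
  )
  t1 <- run_dynamics(spec, integrator_settings(seed = 23),
    run_schedule(500, 2000, 500))
  t2 <- run_dynamics(spec, integrator_settings(seed = 23),
    run_schedule(500, 2000, 500))
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$frame_images, t2$frame_images)
  t3 <- run_dynamics(spec, integrator_settings(seed = 24),
    run_schedule(500, 2000, 500))
  expect_false(identical(t1$frames, t3$frames))
})

test_that("run schedules control frame counts and sampling times", {
  expect_error(run_schedule(0, 100, 33), "production_steps")
  sch <- run_schedule(0, 100, 10)
  spec <- system_spec(n_monomers = 10, box_side = 10, seed = 2)
  traj <- run_dynamics(spec, integrator_settings(seed = 2), sch)
  expect_equal(n_frames(traj), 10)
  expect_equal(traj$times, seq(0.05, 0.5, by = 0.05), tolerance = 1e-12)

  sch2 <- run_schedule_tau(100, 500, 25, dt = 0.005)
  expect_equal(sch2$equilibration_steps, 20000)
  expect_equal(sch2$production_steps, 100000)
  expect_equal(sch2$sample_interval, 5000)
})

test_that("polymer-only runs are stationary after equilibration", {
  spec <- system_spec(n_monomers = 40, box_side = 20, seed = 29)
  traj <- run_dynamics(
    spec, integrator_settings(seed = 29),
    run_schedule_tau(1500, 3000, 15)
  )
  agg <- aggregate_observables(traj)
  rg <- agg$per_frame$rg
  half <- length(rg) %/% 2
  m1 <- mean(rg[1:half])
  m2 <- mean(rg[(half + 1):length(rg)])
  se <- sqrt(
    nucleohns:::block_bootstrap_se(rg[1:half])^2 +
      nucleohns:::block_bootstrap_se(rg[(half + 1):length(rg)])^2
  )
  expect_lt(abs(m1 - m2), max(4 * se, 0.1 * mean(rg)))
  # kinetic temperature also on target
  expect_lt(abs(traj$mean_kinetic_temperature - 1), 0.02)
})
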