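test_that("truncated-shifted LJ matches the tabulated calibration", {
  tbl <- interaction_table()
  p12 <- get_pair(tbl, 1, 2)

  # the patch-monomer well: about -8.65 kT at r ~ 0.6 sigma
  expect_lt(abs(pair_energy(0.6, p12) - (-8.65)), 0.05)
  # exactly zero at and beyond the cutoff
  expect_identical(pair_energy(p12$r_cut, p12), 0)
  expect_identical(pair_energy(1.5 * p12$r_cut, p12), 0)

  # WCA pairs: shifted minimum is zero at 2^(1/6) sigma
  p11 <- get_pair(tbl, 1, 1)
  expect_equal(pair_energy(2^(1 / 6), p11), 0, tolerance = 1e-12)

  # inactive pairs contribute exactly zero by contract
  p23 <- get_pair(tbl, 2, 3)
  expect_false(p23$active)
  expect_identical(pair_energy(0.1, p23), 0)
  expect_identical(pair_force(0.1, p23), 0)

  expect_error(pair_energy(0, p11), "positive")
  expect_error(pair_force(-1, p11), "positive")
})

test_that("interaction table reproduces the published parameter set", {
  tbl <- interaction_table()
  expected <- list(
    list(1, 1, 1.0, 1.0, 2^(1 / 6)),
    list(1, 2, 29.0, 0.535, 0.685),
    list(1, 3, 1.0, 1.0, 2^(1 / 6)),
    list(1, 4, 1.0, 1.5, 1.5 * 2^(1 / 6)),
    list(2, 2, 1.0, 0.178, 0.2),
    list(3, 3, 1.0, 1.0, 2^(1 / 6)),
    list(3, 4, 1.0, 1.5, 1.5 * 2^(1 / 6)),
    list(4, 4, 1.0, 2.0, 2.0 * 2^(1 / 6))
  )
  for (e in expected) {
    pp <- get_pair(tbl, e[[1]], e[[2]])
    expect_true(pp$active)
    expect_equal(pp$epsilon, e[[3]])
    expect_equal(pp$sigma, e[[4]])
    expect_equal(pp$r_cut, e[[5]])
  }
  # the N/A pairs are explicitly inactive
  expect_false(get_pair(tbl, 2, 3)$active)
  expect_false(get_pair(tbl, 2, 4)$active)
  # symmetry
  for (i in 1:4) {
    for (j in 1:4) {
      expect_identical(get_pair(tbl, i, j), get_pair(tbl, j, i))
    }
  }
  # sigma identities hold to the printed three decimals
  expect_equal(round(0.6 / 2^(1 / 6), 3), 0.535)
  expect_equal(round(0.2 / 2^(1 / 6), 3), 0.178)

  # N2000 geometry alternates
  t2 <- interaction_table("N2000")
  expect_equal(get_pair(t2, 1, 4)$sigma, 2.5)
  expect_equal(get_pair(t2, 3, 4)$sigma, 2.5)
  expect_equal(get_pair(t2, 4, 4)$sigma, 4.0)
  expect_equal(get_pair(t2, 4, 4)$r_cut, 4.0 * 2^(1 / 6))
  expect_identical(get_pair(t2, 1, 2), get_pair(tbl, 1, 2))

  # the permeable control switches off core-crowder only
  tp <- interaction_table(permeable_hns = TRUE)
  expect_false(get_pair(tp, 3, 4)$active)
  expect_true(get_pair(tp, 1, 4)$active)
  expect_true(get_pair(tp, 4, 4)$active)

  dt <- dump_table(tbl)
  expect_equal(nrow(dt), 10)
  expect_equal(sum(!dt$active), 2)
})

test_that("pair energy is continuous at the cutoff and WCA pairs repulsive", {
  tbl <- interaction_table()
  # continuity: the shifted energy vanishes linearly approaching the
  # cutoff (slope bounded by the local force), with no residual jump
  for (ij in list(c(1, 1), c(1, 2), c(1, 4), c(2, 2), c(4, 4))) {
    pp <- get_pair(tbl, ij[1], ij[2])
    d <- 1e-7
    u <- pair_energy(pp$r_cut - d, pp)
    slope <- abs(pair_force(pp$r_cut - d, pp))
    expect_lt(abs(u), slope * d * 1.01 + 1e-9)
  }
  # pairs cut exactly at the LJ minimum vanish quadratically there
  for (ij in list(c(1, 1), c(1, 4), c(4, 4))) {
    pp <- get_pair(tbl, ij[1], ij[2])
    expect_lt(abs(pair_energy(pp$r_cut - 1e-7, pp)), 1e-9)
  }
  # purely repulsive pairs never dip below zero
  for (ij in list(c(1, 1), c(1, 3), c(1, 4), c(3, 3), c(3, 4), c(4, 4))) {
    pp <- get_pair(tbl, ij[1], ij[2])
    r <- seq(0.3 * pp$sigma, 1.5 * pp$r_cut, length.out = 500)
    expect_true(all(pair_energy(r, pp) >= 0))
  }
  # the patch-monomer pair has a strictly negative well
  expect_lt(potential_minimum(get_pair(tbl, 1, 2))$u_min, -1)
})

test_that("pair force is minus the derivative of pair energy", {
  tbl <- interaction_table()
  h <- 1e-7
  withr::with_seed(42, {
    for (ij in list(c(1, 1), c(1, 2), c(1, 4), c(2, 2), c(4, 4))) {
      pp <- get_pair(tbl, ij[1], ij[2])
      r <- runif(100, 0.55 * pp$sigma, 1.2 * pp$r_cut)
      # keep clear of the cutoff where the derivative jumps
      r <- r[abs(r - pp$r_cut) > 1e-3]
      fd <- -(pair_energy(r + h, pp) - pair_energy(r - h, pp)) / (2 * h)
      f <- pair_force(r, pp)
      expect_lt(max(abs(f - fd) / pmax(1, abs(f))), 1e-6)
    }
  })
  # zero at the potential minimum and beyond the cutoff
  p11 <- get_pair(tbl, 1, 1)
  expect_equal(pair_force(2^(1 / 6), p11), 0, tolerance = 1e-10)
  expect_identical(pair_force(1.5 * p11$r_cut, p11), 0)
})

test_that("potential_minimum locates the well", {
  tbl <- interaction_table()
  p12 <- get_pair(tbl, 1, 2)
  pm <- potential_minimum(p12)
  expect_lt(abs(pm$r_min - 0.6), 0.01)

  # dense grid scan as the brute-force oracle
  r <- seq(1e-5, p12$r_cut, by = 1e-5)
  expect_lt(abs(pm$u_min - min(pair_energy(r, p12))), 0.05)

  # WCA pair: zero minimum at the cutoff
  pm11 <- potential_minimum(get_pair(tbl, 1, 1))
  expect_equal(pm11$u_min, 0)
  expect_equal(pm11$r_min, 2^(1 / 6), tolerance = 1e-9)

  expect_error(potential_minimum(get_pair(tbl, 2, 4)), "inactive")
})

test_that("FENE bond energy follows the closed form", {
  bp <- bonded_params()
  expect_identical(fene_energy(0, bp), 0)
  # -(1/2) 30 (1.5)^2 ln(1 - 0.36) = 33.75 * (-ln 0.64)
  expect_equal(fene_energy(0.9, bp), 33.75 * (-log(0.64)), tolerance = 1e-12)
  r <- seq(0, 1.45, by = 0.05)
  expect_true(all(diff(fene_energy(r, bp)) > 0))
  expect_error(fene_energy(1.5, bp), "overstretch")
  expect_error(fene_energy(2, bp), "overstretch")
})

test_that("H-NS internal energy matches its two-bond one-angle form", {
  bp <- bonded_params()
  core <- c(1, 2, 3)
  expect_equal(
    hns_internal_energy(core, core + c(0, 0, 0.4), core - c(0, 0, 0.4), bp), 0
  )
  # one patch stretched to 0.5 sigma: 120 * 0.1^2
  expect_equal(
    hns_internal_energy(core, core + c(0, 0, 0.5), core - c(0, 0, 0.4), bp),
    1.2,
    tolerance = 1e-12
  )
  # right angle between patches: 50 * (pi/2)^2
  expect_equal(
    hns_internal_energy(core, core + c(0.4, 0, 0), core + c(0, 0.4, 0), bp),
    50 * (pi / 2)^2,
    tolerance = 1e-12
  )
  expect_error(
    hns_internal_energy(core, core, core + c(0, 0, 0.4), bp), "coincide"
  )

  # invariance under rigid rotation + translation
  withr::with_seed(7, {
    pa <- c(0.1, 0.2, 0.45)
    pb <- c(-0.2, 0.1, -0.3)
    e0 <- hns_internal_energy(c(0, 0, 0), pa, pb, bp)
    for (k in 1:10) {
      rot <- random_rotation_matrix()
      shift <- rnorm(3, sd = 5)
      expect_equal(
        hns_internal_energy(
          shift, as.vector(rot %*% pa) + shift, as.vector(rot %*% pb) + shift,
          bp
        ),
        e0,
        tolerance = 1e-9
      )
    }
  })
})
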