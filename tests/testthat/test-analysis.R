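make_bare_ring <- function(pos, box) {
  n <- nrow(pos)
  nucleohns:::new_particle_config(
    positions = pos, species = rep(1L, n), molecule = rep(1L, n),
    bonds = data.frame(
      i = seq_len(n), j = c(seq_len(n)[-1], 1L), kind = "fene",
      stringsAsFactors = FALSE
    ),
    angles = matrix(integer(0), ncol = 3), box = box, n_monomers = n
  )
}

test_that("radius of gyration matches closed forms", {
  # two monomers at distance d: Rg = d/2
  cfg <- make_bare_ring(rbind(c(5, 5, 5), c(5, 5, 6.4)), 20)
  expect_equal(radius_of_gyration(cfg), 0.7, tolerance = 1e-12)

  # 8 monomers on the corners of a unit cube (ordered as a ring walk):
  # every corner is sqrt(3)/2 from the centre
  corners <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 1, 1), c(1, 1, 1), c(1, 0, 1), c(0, 0, 1)
  ) + 5
  expect_equal(
    radius_of_gyration(make_bare_ring(corners, 20)), sqrt(3) / 2,
    tolerance = 1e-12
  )

  # circle fixture: Rg equals the radius
  fx <- make_fixture("known_rg", radius = 10, n_monomers = 100)
  expect_equal(radius_of_gyration(fx$config), 10, tolerance = 1e-9)
})

test_that("radius of gyration is invariant under PBC wrapping and rotation", {
  fx <- make_fixture("known_rg", radius = 10, n_monomers = 64)
  cfg <- fx$config
  rg0 <- radius_of_gyration(cfg)

  # lattice translation with wrapping: the ring straddles the boundary
  cp <- cfg
  cp$positions <- sweep(cfg$positions, 2, -c(cfg$box * 0.6, 0, cfg$box))
  cp$positions <- cp$positions - cfg$box * floor(cp$positions / cfg$box)
  expect_equal(radius_of_gyration(cp), rg0, tolerance = 1e-9)

  # rigid rotation (unwrapped frame)
  withr::with_seed(3, rot <- random_rotation_matrix())
  cr <- cfg
  centre <- colMeans(cfg$positions)
  cr$positions <- sweep(
    sweep(cfg$positions, 2, centre) %*% t(rot), 2, -centre
  )
  expect_equal(radius_of_gyration(cr), rg0, tolerance = 1e-9)

  # independence of the starting monomer of the bond walk
  for (s in c(10, 33, 60)) {
    cs <- cp
    idx <- c(s:64, 1:(s - 1))
    cs$positions <- cp$positions[idx, ]
    expect_lt(abs(radius_of_gyration(cs) - rg0), 1e-9)
  }
})

test_that("broken rings are detected", {
  # a walk that closes only through a nonzero lattice vector: ten beads
  # marching +x by one sigma each in a 10-sigma box
  pos <- cbind(0:9 + 0.5, rep(5, 10), rep(5, 10))
  expect_error(radius_of_gyration(make_bare_ring(pos, 10)), "broken ring")
  # a bond longer than half the box is ambiguous
  pos2 <- rbind(c(1, 1, 1), c(5.9, 5.9, 5.9), c(1, 1, 2))
  expect_error(radius_of_gyration(make_bare_ring(pos2, 10)), "broken ring")
})

test_that("binding classification matches constructed ground truth", {
  fx <- make_fixture("mixed_binding", n_dangling = 3, n_bridging = 2,
                     n_free = 5)
  b <- classify_binding(fx$config)
  expect_equal(b$theta, 0.5)
  expect_equal(b$frac_dangling, 0.3)
  expect_equal(b$frac_bridging, 0.2)
  expect_equal(b$theta, b$frac_dangling + b$frac_bridging)
  expect_equal(sum(b$records$mode == "unbound"), 5)

  # brute-force distance scan confirms every contact set
  cfg <- fx$config
  lay <- nucleohns:::hns_layout(cfg$species)
  mon <- which(cfg$species == 1L)
  for (k in seq_len(lay$n_hns)) {
    for (side in c("a", "b")) {
      patch <- if (side == "a") lay$patch_a[k] else lay$patch_b[k]
      d <- sqrt(colSums(
        (t(cfg$positions[mon, ]) - cfg$positions[patch, ])^2
      ))
      expected <- which(d < 0.685)
      got <- if (side == "a") b$contacts_a[[k]] else b$contacts_b[[k]]
      expect_identical(sort(as.integer(got)), sort(as.integer(expected)))
    }
  }

  # saturated case: no free dimers
  fx2 <- make_fixture("mixed_binding", n_dangling = 4, n_bridging = 4,
                      n_free = 0)
  expect_equal(classify_binding(fx2$config)$theta, 1)

  # far-from-ring fixture: nothing is bound
  fx3 <- make_fixture("clustered", sizes = c(3, 2))
  expect_equal(classify_binding(fx3$config)$theta, 0)

  # undefined binding probability is an explicit error
  fx4 <- make_fixture("known_rg")
  expect_error(classify_binding(fx4$config), "undefined")
})

test_that("bridge spans use minimal ring distance and the trans threshold", {
  rec <- function(a, b) list(contacts_a = a, contacts_b = b, mode = "bridging")
  expect_equal(bridge_span(rec(5, 9), 200), list(span = 4L, label = "trans"))
  expect_equal(bridge_span(rec(1, 199), 200), list(span = 2L, label = "cis"))
  expect_equal(bridge_span(rec(7, 7), 200), list(span = 0L, label = "cis"))
  # minimal distance across full contact sets
  expect_equal(
    bridge_span(rec(c(5, 100), c(9, 180)), 200)$span, 4L
  )
  expect_error(
    bridge_span(list(contacts_a = 1, contacts_b = integer(0), mode = "dangling"), 200),
    "not bridging"
  )
})

test_that("cluster detection matches chain and separation geometry", {
  place_cores <- function(coords, box = 50) {
    parts <- NULL
    for (k in seq_len(nrow(coords))) {
      tri <- build_hns_triplex(coords[k, ], c(0, 0, 1))
      if (is.null(parts)) {
        parts <- list(
          positions = tri$positions, species = tri$species,
          molecule = rep(k, 3),
          bonds = data.frame(i = tri$bonds$i, j = tri$bonds$j,
                             kind = tri$bonds$kind),
          angles = tri$angles
        )
      } else {
        off <- nrow(parts$positions)
        parts$positions <- rbind(parts$positions, tri$positions)
        parts$species <- c(parts$species, tri$species)
        parts$molecule <- c(parts$molecule, rep(k, 3))
      }
    }
    nucleohns:::new_particle_config(
      positions = parts$positions, species = parts$species,
      molecule = parts$molecule, bonds = parts$bonds,
      angles = parts$angles, box = box, n_monomers = 0
    )
  }
  # three cores in a line at 2.9 sigma spacing: one chain-connected cluster
  c1 <- place_cores(rbind(c(10, 10, 10), c(12.9, 10, 10), c(15.8, 10, 10)))
  r1 <- detect_clusters(c1)
  expect_equal(r1$n_clusters, 1)
  expect_equal(r1$sizes, 3L)

  # mutual spacing 3.1 sigma: all singletons
  c2 <- place_cores(rbind(c(10, 10, 10), c(13.1, 10, 10), c(10, 13.1, 10)))
  r2 <- detect_clusters(c2)
  expect_equal(r2$n_clusters, 3)
  expect_equal(r2$sizes, rep(1L, 3))

  # the fixture's prescribed partition is recovered
  fx <- make_fixture("clustered", sizes = c(24, 3, 2, 1))
  rep1 <- detect_clusters(fx$config)
  expect_equal(sort(rep1$sizes, decreasing = TRUE), c(24L, 3L, 2L, 1L))
  expect_equal(rep1$histogram$count[match(c(1, 2, 3, 24), rep1$histogram$size)],
               rep(1L, 4))
})

test_that("cluster partition equals the brute-force BFS oracle", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      n <- 50
      box <- 25
      pos <- matrix(runif(3 * n, 0, box), n, 3)
    })
    got <- nucleohns:::detect_clusters_raw(pos, box, 3)
    want <- brute_force_clusters(pos, box, 3)
    # same partition up to label permutation: co-membership must agree
    expect_identical(
      outer(got$labels, got$labels, "=="), outer(want, want, "==")
    )
    # partition property: sizes sum to n
    expect_equal(sum(got$sizes), n)
  }
})

test_that("aggregation pools frames, histograms and bootstrap errors", {
  fx1 <- make_fixture("clustered", sizes = c(3, 1))
  fx2 <- make_fixture("clustered", sizes = c(2, 2))
  traj <- configs_to_trajectory(list(fx1$config, fx2$config),
                                times = c(0, 25))
  agg <- aggregate_observables(traj)
  expect_equal(agg$histogram$size, c(1L, 2L, 3L))
  expect_equal(agg$histogram$count, c(1L, 2L, 1L))
  # pooled mean cluster size: 8 dimers in 4 clusters
  expect_equal(agg$summary$mean_cluster_size, 2)

  # single-frame summary equals the frame's values
  t1 <- configs_to_trajectory(list(fx1$config))
  a1 <- aggregate_observables(t1)
  expect_equal(a1$summary$mean_rg, radius_of_gyration(fx1$config))
  expect_equal(a1$summary$mean_theta, classify_binding(fx1$config)$theta)

  # identical frames have zero bootstrap error
  tid <- configs_to_trajectory(rep(list(fx1$config), 12))
  aid <- aggregate_observables(tid)
  expect_equal(aid$summary$se_rg, 0)

  # compaction ratio uses the supplied baseline
  a2 <- aggregate_observables(t1, rg0 = 2 * a1$summary$mean_rg)
  expect_equal(a2$summary$mean_rg_ratio, 0.5)

  expect_error(
    aggregate_observables(structure(list(frames = numeric(0)),
      class = "md_trajectory")),
    "no frames"
  )
})

test_that("theta decomposition is exact count arithmetic on real dynamics", {
  spec <- system_spec(
    n_monomers = 30, box_side = 15, phi_c = 0.05, n_hns = 6, seed = 37
  )
  traj <- run_dynamics(spec, integrator_settings(seed = 37),
                       run_schedule(2000, 20000, 1000))
  agg <- aggregate_observables(traj)
  pf <- agg$per_frame
  expect_true(all(pf$theta >= 0 & pf$theta <= 1))
  expect_equal(pf$theta, pf$frac_dangling + pf$frac_bridging)
  # counts: theta * n_hns is an integer for every frame
  expect_equal(pf$theta * 6, round(pf$theta * 6), tolerance = 1e-12)
})

test_that("ideal rings obey Gaussian ring-size scaling", {
  # with every nonbonded pair switched off the ring is a phantom FENE
  # chain; <Rg^2> should grow linearly in N
  tbl <- interaction_table()
  tbl$active[] <- FALSE
  msd <- sapply(c(50, 100, 200), function(n) {
    spec <- system_spec(n_monomers = n, box_side = 60, seed = 41)
    cfg <- assemble_system(spec, table = tbl)
    relax <- max(2000, round(n^2 / 6)) # a few Rouse times, in tau
    eq <- propagate(cfg, integrator_settings(seed = 41), round(relax / 0.005),
      table = tbl
    )
    out <- propagate(eq$config, integrator_settings(seed = 43),
      round(4 * relax / 0.005),
      sample_every = 2000, table = tbl
    )
    nf <- dim(out$frames)[1]
    mean(sapply(seq_len(nf), function(k) {
      ck <- cfg
      ck$positions <- matrix(out$frames[k, , ], ncol = 3)
      ck$images <- matrix(out$frame_images[k, , ], ncol = 3)
      radius_of_gyration(ck)^2
    }))
  })
  fit <- lm(log(msd) ~ log(c(50, 100, 200)))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
})
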