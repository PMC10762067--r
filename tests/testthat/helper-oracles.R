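# Independent oracles used across the suite. These deliberately avoid the
# package's C++ kernels and neighbour lists: plain R, all pairs, direct
# formulas.

min_image_r <- function(d, box) d - box * round(d / box)

# total potential energy by direct summation over all particle pairs,
# bonds and angles
brute_force_energy <- function(config, table = interaction_table(),
                               bp = bonded_params()) {
  pos <- config$positions
  n <- nrow(pos)
  box <- config$box
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pp <- get_pair(table, config$species[i], config$species[j])
      if (!pp$active) next
      d <- min_image_r(pos[i, ] - pos[j, ], box)
      r <- sqrt(sum(d^2))
      e <- e + pair_energy(r, pp)
    }
  }
  for (b in seq_len(nrow(config$bonds))) {
    i <- config$bonds$i[b]
    j <- config$bonds$j[b]
    d <- min_image_r(pos[i, ] - pos[j, ], box)
    r <- sqrt(sum(d^2))
    e <- e + switch(config$bonds$kind[b],
      fene = fene_energy(r, bp),
      hns = bp$hns_K * (r - bp$hns_r0)^2,
      anchor = bp$anchor_k * (r - bp$anchor_r0)^2
    )
  }
  if (nrow(config$angles) > 0) {
    for (a in seq_len(nrow(config$angles))) {
      pa <- pos[config$angles[a, 1], ]
      pc <- pos[config$angles[a, 2], ]
      pb <- pos[config$angles[a, 3], ]
      d1 <- min_image_r(pa - pc, box)
      d2 <- min_image_r(pb - pc, box)
      cth <- sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
      e <- e + bp$hns_kb * (acos(min(1, max(-1, cth))) - pi)^2
    }
  }
  e
}

# connected components by breadth-first search on the all-pairs adjacency
brute_force_clusters <- function(pos, box, cutoff) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- min_image_r(pos[i, ] - pos[j, ], box)
      adj[i, j] <- sqrt(sum(d^2)) <= cutoff
    }
  }
  label <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (label[s] > 0) next
    cur <- cur + 1L
    queue <- s
    label[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & label == 0L)
      label[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  label
}

# small equilibrated mixed system for force/energy checks
small_mixed_config <- function(seed = 1, n_monomers = 30, n_hns = 4,
                               phi_c = 0.02, box = 14) {
  spec <- system_spec(
    n_monomers = n_monomers, box_side = box, phi_c = phi_c,
    n_hns = n_hns, seed = seed
  )
  cfg <- assemble_system(spec)
  # brief thermalization so configurations are generic, not lattice-like
  propagate(cfg, integrator_settings(seed = seed), 2000)$config
}

random_rotation_matrix <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# hand-rolled trajectory object wrapping a list of configurations
configs_to_trajectory <- function(configs, times = NULL) {
  n <- nrow(configs[[1]]$positions)
  nf <- length(configs)
  arr <- array(NA_real_, c(nf, n, 3))
  for (k in seq_len(nf)) arr[k, , ] <- configs[[k]]$positions
  cfg <- configs[[1]]
  structure(
    list(
      frames = arr, frame_images = array(0L, c(nf, n, 3)),
      times = if (is.null(times)) seq_len(nf) else times,
      epot = rep(NA_real_, nf), box = cfg$box, species = cfg$species,
      molecule = cfg$molecule, bonds = cfg$bonds, angles = cfg$angles,
      n_monomers = cfg$n_monomers, spec = cfg$spec, settings = NULL,
      schedule = NULL, mean_kinetic_temperature = NULL, final = NULL
    ),
    class = "md_trajectory"
  )
}
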