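#' Simulation system specification
#'
#' Describes one simulated system: a ring polymer of `n_monomers` beads in
#' a cubic periodic box, `n_hns` mobile H-NS dimers, and spherical crowders
#' at volume fraction `phi_c`. Two control variants are supported:
#' `hns_permeable_to_crowders` switches off the core-crowder repulsion
#' (H-NS then feels no depletion force from crowders), and `n_anchored`
#' tethers that many dimers permanently to randomly chosen monomers.
#'
#' @param n_monomers number of ring monomers (N).
#' @param box_side cubic box side L, in \eqn{\sigma}.
#' @param phi_c crowder volume fraction, in \eqn{[0, 0.5)}.
#' @param n_hns number of H-NS dimers.
#' @param crowder_diameter crowder diameter \eqn{\sigma_c}, in
#'   \eqn{\sigma}.
#' @param hns_permeable_to_crowders logical; see Description.
#' @param n_anchored number of dimers to anchor (0 = off).
#' @param seed integer seed controlling the (deterministic) assembly.
#' @return An object of class `system_spec`.
#' @examples
#' system_spec(n_monomers = 200, box_side = 50, phi_c = 0.32, n_hns = 30)
#' @export
system_spec <- function(n_monomers = 200, box_side = 50, phi_c = 0,
                        n_hns = 0, crowder_diameter = 2,
                        hns_permeable_to_crowders = FALSE,
                        n_anchored = 0, seed = 1) {
  stopifnot(
    n_monomers >= 3, box_side > 0,
    phi_c >= 0, phi_c < 0.5,
    n_hns >= 0, crowder_diameter > 0,
    n_anchored >= 0, n_anchored <= n_hns
  )
  structure(
    list(
      n_monomers = as.integer(n_monomers), box_side = box_side,
      phi_c = phi_c, n_hns = as.integer(n_hns),
      crowder_diameter = crowder_diameter,
      hns_permeable_to_crowders = isTRUE(hns_permeable_to_crowders),
      n_anchored = as.integer(n_anchored), seed = as.integer(seed)
    ),
    class = "system_spec"
  )
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "system_spec: N = %d monomers, L = %g sigma, phi_c = %g ",
      "(%d crowders of %g sigma), %d H-NS%s%s, seed %d\n"
    ),
    x$n_monomers, x$box_side, x$phi_c,
    crowder_count(x$phi_c, x$box_side, x$crowder_diameter),
    x$crowder_diameter, x$n_hns,
    if (x$hns_permeable_to_crowders) " (permeable to crowders)" else "",
    if (x$n_anchored > 0) sprintf(" (%d anchored)", x$n_anchored) else "",
    x$seed
  ))
  invisible(x)
}

#' Number of crowders at a target volume fraction
#'
#' The crowder count realizing volume fraction `phi_c` in a cubic box:
#' \eqn{\mathrm{round}(\phi_c L^3 / (\pi \sigma_c^3 / 6))}. Rounding is to
#' the nearest integer so the realized fraction is unbiased and within half
#' a particle volume of the target.
#'
#' @param phi_c target crowder volume fraction.
#' @param box_side box side, in \eqn{\sigma}.
#' @param sigma_c crowder diameter, in \eqn{\sigma}.
#' @return Integer particle count.
#' @examples
#' crowder_count(0.32, 50, 2) # 9549
#' @export
crowder_count <- function(phi_c, box_side, sigma_c) {
  stopifnot(phi_c >= 0, box_side > 0, sigma_c > 0)
  as.integer(round(phi_c * box_side^3 / (pi / 6 * sigma_c^3)))
}

#' Molar concentration of a particle count in a cubic box
#'
#' Converts a particle count in a cube of given physical side length to a
#' molar concentration in micromolar. With the mapping
#' \eqn{\sigma = 2.5\,\mathrm{nm}}, 200 monomers in a
#' \eqn{(125\,\mathrm{nm})^3} box are about 170 uM and 30 H-NS dimers
#' about 25.5 uM.
#'
#' @param count particle count.
#' @param box_side_nm box side, in nanometres.
#' @return Concentration in micromolar.
#' @examples
#' molar_concentration(30, 125) # ~25.5 uM
#' @export
molar_concentration <- function(count, box_side_nm) {
  stopifnot(count >= 0, box_side_nm > 0)
  avogadro <- 6.02214076e23
  vol_litre <- (box_side_nm * 1e-8)^3 # 1 nm = 1e-8 dm; dm^3 = L
  count / (avogadro * vol_litre) * 1e6
}

#' Physical length of one sigma, in nanometres
#' @return 2.5 (each monomer coarse-grains ~7.35 bp of B-DNA).
#' @export
sigma_nm <- function() 2.5

# closed, knot-free, overlap-free initial curve for the ring.
# A planar circle is used whenever it fits the box; otherwise the ring is
# wound p times around a torus (still an unknot) so a long chain can start
# inside a small periodic box without crossing its own periodic images.
ring_curve <- function(n, box, bond_length) {
  circ <- n * bond_length
  max_extent <- 0.92 * box
  if (circ / pi <= max_extent) {
    # radius chosen so the chord between neighbours equals the bond length
    radius <- bond_length / (2 * sin(pi / n))
    t <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(radius * cos(t), radius * sin(t), rep(0, n)))
  }
  # toroidal winding: r(t) = ((R + rho cos(pt)) cos t, ..., rho sin(pt))
  for (p in 2:40) {
    for (rho in c(0.12, 0.10, 0.08, 0.06) * box) {
      rsq <- (circ / (2 * pi))^2 - (p * rho)^2
      if (rsq <= (1.2 * rho)^2) next # need R comfortably above rho
      bigR <- sqrt(rsq)
      if (2 * (bigR + rho) > max_extent) next
      if (2 * pi * (bigR - rho) / p < 2.0) next # winding-winding spacing
      tt <- seq(0, 2 * pi, length.out = 40 * n + 1)
      xyz <- cbind(
        (bigR + rho * cos(p * tt)) * cos(tt),
        (bigR + rho * cos(p * tt)) * sin(tt),
        rho * sin(p * tt)
      )
      seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
        xyz[-nrow(xyz), , drop = FALSE])^2))
      arc <- c(0, cumsum(seg))
      total <- arc[length(arc)]
      targets <- total * (seq_len(n) - 1) / n
      idx <- findInterval(targets, arc, all.inside = TRUE)
      w <- (targets - arc[idx]) / pmax(seg[idx], 1e-12)
      pts <- xyz[idx, , drop = FALSE] +
        (xyz[idx + 1, , drop = FALSE] - xyz[idx, , drop = FALSE]) * w
      # verify the curve does not approach itself
      dmin <- min_nonneighbor_distance(pts)
      if (dmin > 0.95) {
        return(pts)
      }
    }
  }
  stop(sprintf(
    "build_ring_polymer: no non-self-intersecting closed curve of length %g sigma fits a box of side %g sigma",
    circ, box
  ))
}

min_nonneighbor_distance <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  ringsep <- abs(outer(seq_len(n), seq_len(n), "-"))
  ringsep <- pmin(ringsep, n - ringsep)
  min(d[ringsep >= 2])
}

#' Build the initial ring polymer
#'
#' Places `N` monomers on a closed non-self-intersecting curve of
#' circumference about `0.97 N` sigma (the equilibrium FENE+WCA bond
#' length), centred in the box, and closes the FENE bond list
#' (monomer N bonded back to monomer 1). A planar circle is used when it
#' fits; longer chains are started on a toroidal winding, which is equally
#' knot-free. The starting shape is erased by equilibration.
#'
#' @param n_monomers number of monomers (at least 3).
#' @param box_side cubic box side, in \eqn{\sigma}.
#' @param bond_length target bond length, in \eqn{\sigma}.
#' @return A `particle_config` containing only the polymer.
#' @examples
#' ring <- build_ring_polymer(50, 20)
#' nrow(ring$positions)
#' @export
build_ring_polymer <- function(n_monomers, box_side, bond_length = 0.97) {
  stopifnot(n_monomers >= 3, box_side > 0)
  pts <- ring_curve(n_monomers, box_side, bond_length)
  pts <- sweep(pts, 2, c(box_side / 2, box_side / 2, box_side / 2), "+")
  n <- n_monomers
  bonds <- data.frame(
    i = seq_len(n), j = c(seq_len(n)[-1], 1L), kind = "fene",
    stringsAsFactors = FALSE
  )
  new_particle_config(
    positions = pts, species = rep(1L, n), molecule = rep(1L, n),
    bonds = bonds, angles = matrix(integer(0), ncol = 3),
    box = box_side, n_monomers = n
  )
}

#' Build one H-NS triplex
#'
#' Returns the rest geometry of a dimer: a core sphere at `center` with
#' two patch spheres embedded `0.4` sigma from its centre along
#' `+axis`/`-axis` (so the patch-patch distance is \eqn{0.8\sigma} and the
#' internal energy is exactly zero).
#'
#' @param center numeric length-3 position of the core.
#' @param axis unit vector along the patch-patch axis.
#' @param bp a [bonded_params()] object (sets the rest distance).
#' @return A list with `positions` (3x3 matrix: core, patch A, patch B),
#'   `species` (3, 2, 2), local `bonds` and one `angle` row.
#' @export
build_hns_triplex <- function(center, axis = c(0, 0, 1),
                              bp = bonded_params()) {
  stopifnot(length(center) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  stopifnot(abs(nrm - 1) < 1e-8)
  pos <- rbind(
    center,
    center + bp$hns_r0 * axis,
    center - bp$hns_r0 * axis
  )
  rownames(pos) <- NULL
  list(
    positions = pos,
    species = c(3L, 2L, 2L),
    bonds = data.frame(
      i = c(1L, 1L), j = c(2L, 3L), kind = "hns",
      stringsAsFactors = FALSE
    ),
    angles = matrix(c(2L, 1L, 3L), ncol = 3)
  )
}

new_particle_config <- function(positions, species, molecule, bonds, angles,
                                box, n_monomers, velocities = NULL,
                                images = NULL, spec = NULL) {
  n <- nrow(positions)
  stopifnot(length(species) == n, length(molecule) == n)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(images)) images <- matrix(0L, n, 3)
  structure(
    list(
      positions = positions, species = as.integer(species),
      molecule = as.integer(molecule), bonds = bonds, angles = angles,
      box = box, n_monomers = as.integer(n_monomers),
      velocities = velocities, images = images, spec = spec
    ),
    class = "particle_config"
  )
}

#' @export
print.particle_config <- function(x, ...) {
  cnt <- table(factor(SPECIES_NAMES[x$species], levels = SPECIES_NAMES))
  cat(sprintf(
    "particle_config: %d particles in a %g-sigma periodic box\n",
    nrow(x$positions), x$box
  ))
  cat(sprintf(
    "  %s; %d bonds, %d angles\n",
    paste(sprintf("%d %s", as.integer(cnt), names(cnt)), collapse = ", "),
    nrow(x$bonds), nrow(x$angles)
  ))
  invisible(x)
}

# convert the bond/angle bookkeeping into the numeric matrices the C++
# kernels consume: columns (i, j, style, k, r0); style 1 = FENE, 2 = harmonic
topology_matrices <- function(config, bp) {
  b <- config$bonds
  if (nrow(b) == 0) {
    bm <- matrix(numeric(0), ncol = 5)
  } else {
    style <- ifelse(b$kind == "fene", 1, 2)
    k <- c(fene = bp$fene_k0, hns = bp$hns_K, anchor = bp$anchor_k)[b$kind]
    r0 <- c(fene = bp$fene_r0, hns = bp$hns_r0, anchor = bp$anchor_r0)[b$kind]
    bm <- cbind(b$i, b$j, style, k, r0)
  }
  am <- config$angles
  if (nrow(am) == 0) am <- matrix(integer(0), ncol = 3)
  storage.mode(am) <- "integer"
  list(bonds = bm, angles = am)
}

table_matrices <- function(table) {
  act <- table$active
  eps <- table$epsilon
  sig <- table$sigma
  rcut <- table$r_cut
  eps[!act] <- 0
  sig[!act] <- 0
  rcut[!act] <- 0
  list(eps = eps, sig = sig, rcut = rcut, act = act)
}

# minimum-image separation of two wrapped coordinate sets
min_image <- function(d, box) d - box * round(d / box)

# distance from each row of `pts` to each row of `ref` under periodic wrap
pbc_cross_dist2 <- function(pts, ref, box) {
  dx <- min_image(outer(pts[, 1], ref[, 1], "-"), box)
  dy <- min_image(outer(pts[, 2], ref[, 2], "-"), box)
  dz <- min_image(outer(pts[, 3], ref[, 3], "-"), box)
  dx * dx + dy * dy + dz * dz
}

#' Assemble a simulation-ready system
#'
#' Builds the full particle configuration for a [system_spec()]: the ring
#' polymer on its initial curve, H-NS triplexes and crowders inserted at
#' random positions with overlap rejection, followed (when dense packing
#' forced a relaxed insertion criterion) by a capped steepest-descent
#' push-off until no active nonbonded pair is closer than
#' `0.85` \eqn{\sigma_{ij}}. Velocities are drawn from the
#' Maxwell-Boltzmann distribution at T = 1. The result is deterministic
#' given `spec$seed`.
#'
#' @param spec a [system_spec()].
#' @param table an [interaction_table()]; its permeable flag is taken from
#'   the spec when `NULL`.
#' @param bp a [bonded_params()] object.
#' @param temperature temperature for the initial velocity draw.
#' @return A `particle_config` with positions, species, molecule ids,
#'   bonds, angles, velocities and the periodic box.
#' @examples
#' cfg <- assemble_system(system_spec(n_monomers = 50, box_side = 20, n_hns = 2))
#' @export
assemble_system <- function(spec, table = NULL, bp = bonded_params(),
                            temperature = 1.0) {
  stopifnot(inherits(spec, "system_spec"))
  if (is.null(table)) {
    table <- interaction_table(
      geometry = "N200",
      permeable_hns = spec$hns_permeable_to_crowders
    )
  }
  with_seed(spec$seed, {
    box <- spec$box_side
    cfg <- build_ring_polymer(spec$n_monomers, box)
    pos <- cfg$positions
    species <- cfg$species
    molecule <- cfg$molecule
    bonds <- cfg$bonds
    angles <- cfg$angles

    gap <- 0.85 # required r / sigma_ij after assembly
    tm <- table_matrices(table)
    # rejection-sampling insertion; the acceptance threshold is relaxed in
    # stages at high density and the final gap is restored by push-off
    insert_ok <- function(newpos, newsp, frac) {
      if (nrow(pos) == 0) {
        return(TRUE)
      }
      d2 <- pbc_cross_dist2(newpos, pos, box)
      sig <- tm$sig[newsp, species, drop = FALSE]
      sig[!tm$act[newsp, species, drop = FALSE]] <- 0
      all(d2 >= (frac * sig)^2)
    }
    relaxed <- FALSE
    n_mol <- 1L

    for (h in seq_len(spec$n_hns)) {
      placed <- FALSE
      for (frac in c(gap, 0.7, 0.55)) {
        for (try in 1:400) {
          center <- runif(3, 0, box)
          ax <- rnorm(3)
          ax <- ax / sqrt(sum(ax^2))
          tri <- build_hns_triplex(center, ax, bp)
          if (insert_ok(tri$positions, tri$species, frac)) {
            off <- nrow(pos)
            pos <- rbind(pos, tri$positions)
            species <- c(species, tri$species)
            n_mol <- n_mol + 1L
            molecule <- c(molecule, rep(n_mol, 3L))
            bonds <- rbind(bonds, data.frame(
              i = tri$bonds$i + off, j = tri$bonds$j + off,
              kind = tri$bonds$kind, stringsAsFactors = FALSE
            ))
            angles <- rbind(angles, tri$angles + off)
            placed <- TRUE
            break
          }
        }
        if (placed) {
          if (frac < gap) relaxed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "assemble_system: failed to insert H-NS %d of %d", h, spec$n_hns
        ))
      }
    }

    n_crowd <- crowder_count(spec$phi_c, box, spec$crowder_diameter)
    if (n_crowd > 0) {
      # crowders go on a jittered cubic lattice: gap-respecting by
      # construction even at dense packing, deterministic, and O(n);
      # lattice sites too close to the polymer or the H-NS cores are
      # discarded first. Equilibration erases the initial order.
      m_lat <- ceiling((1.3 * n_crowd + 50)^(1 / 3))
      spacing <- box / m_lat
      sc <- spec$crowder_diameter
      if (spacing < gap * sc) {
        stop(sprintf(
          "assemble_system: packing failed at phi_c = %g (lattice spacing %.2f below the %.2f-sigma crowder gap)",
          spec$phi_c, spacing, gap * sc
        ))
      }
      jitter <- max(0, min(0.2, (spacing - gap * sc) / (2 * sqrt(3))))
      g <- (seq_len(m_lat) - 0.5) * spacing
      sites <- as.matrix(expand.grid(x = g, y = g, z = g))
      dimnames(sites) <- NULL
      # block sites near existing particles (only species with an active
      # crowder interaction matter)
      act4 <- tm$act[4L, species]
      if (any(act4)) {
        ref <- pos[act4, , drop = FALSE]
        sigref <- tm$sig[4L, species[act4]]
        free <- rep(TRUE, nrow(sites))
        for (chunk in split(
          seq_len(nrow(sites)), ceiling(seq_len(nrow(sites)) / 2000)
        )) {
          d2 <- pbc_cross_dist2(sites[chunk, , drop = FALSE], ref, box)
          keep <- rowSums(
            d2 < rep((gap * sigref + jitter * sqrt(3))^2, each = length(chunk))
          ) == 0
          free[chunk] <- keep
        }
        sites <- sites[free, , drop = FALSE]
      }
      if (nrow(sites) < n_crowd) {
        achieved <- nrow(sites) * (pi / 6) * sc^3 / box^3
        stop(sprintf(
          "assemble_system: packing failed at phi_c = %g (room for %d of %d crowders, phi ~ %.3f)",
          spec$phi_c, nrow(sites), n_crowd, achieved
        ))
      }
      pick <- sites[sample(nrow(sites), n_crowd), , drop = FALSE]
      pick <- pick + matrix(runif(3 * n_crowd, -jitter, jitter), n_crowd, 3)
      pos <- rbind(pos, pick)
      species <- c(species, rep(4L, n_crowd))
      molecule <- c(
        molecule, seq(n_mol + 1L, length.out = n_crowd)
      )
      n_mol <- n_mol + n_crowd
    }

    cfg <- new_particle_config(
      positions = pos, species = species, molecule = molecule,
      bonds = bonds, angles = angles, box = box,
      n_monomers = spec$n_monomers, spec = spec
    )
    if (spec$n_anchored > 0) {
      cfg <- anchor_hns(cfg, spec$n_anchored, seed = spec$seed + 7L)
      relaxed <- TRUE # anchored dimers were moved; restore the gap
    }

    top <- topology_matrices(cfg, bp)
    if (relaxed) {
      res <- cpp_pushoff(
        cfg$positions, cfg$species, box, tm$eps, tm$sig, tm$rcut, tm$act,
        top$bonds, top$angles, bp$hns_kb,
        gap_frac = gap, max_iter = 5000L, max_disp = 0.04
      )
      if (!res$converged) {
        stop(sprintf(
          "assemble_system: push-off stalled at minimum gap %.3f sigma_ij (target %.2f) for phi_c = %g",
          res$min_gap_ratio, gap, spec$phi_c
        ))
      }
      cfg$positions <- res$positions
    }
    n <- nrow(cfg$positions)
    v <- matrix(rnorm(3 * n, sd = sqrt(temperature)), n, 3)
    v <- sweep(v, 2, colMeans(v)) # remove centre-of-mass drift
    cfg$velocities <- v
    cfg$positions <- cfg$positions - box * floor(cfg$positions / box)
    cfg
  })
}

#' Anchor H-NS dimers to the polymer
#'
#' Tethers `n_anchor` dimers to distinct, uniformly chosen monomers by a
#' stiff harmonic bond (rest length \eqn{0.6\sigma}) between one patch and
#' the monomer. The other patch stays free, so anchored dimers can still
#' rotate and bridge. The site choice is reproducible from `seed`, which
#' supports averaging over independent anchor draws.
#'
#' @param config a `particle_config` containing a polymer and H-NS.
#' @param n_anchor number of dimers to anchor.
#' @param seed integer seed for the site draw.
#' @return The configuration with `n_anchor` additional `"anchor"` bonds.
#' @export
anchor_hns <- function(config, n_anchor, seed = 1) {
  stopifnot(inherits(config, "particle_config"), n_anchor >= 0)
  if (n_anchor == 0) {
    return(config)
  }
  cores <- which(config$species == 3L)
  if (n_anchor > length(cores)) {
    stop(sprintf(
      "anchor_hns: requested %d anchors but only %d H-NS present",
      n_anchor, length(cores)
    ))
  }
  with_seed(seed, {
    sites <- sample(config$n_monomers, n_anchor)
    patches <- cores[seq_len(n_anchor)] + 1L # patch A of each triplex
    config$bonds <- rbind(config$bonds, data.frame(
      i = patches, j = as.integer(sites), kind = "anchor",
      stringsAsFactors = FALSE
    ))
    # pull each anchored dimer next to its site so the tether starts relaxed
    for (k in seq_len(n_anchor)) {
      core <- cores[k]
      site <- config$positions[sites[k], ]
      shift <- rnorm(3)
      shift <- shift / sqrt(sum(shift^2))
      delta <- (site + 0.6 * shift) - config$positions[core + 1L, ]
      idx <- core + 0:2
      config$positions[idx, ] <- sweep(
        config$positions[idx, , drop = FALSE], 2, -delta
      )
    }
    config$positions <- config$positions -
      config$box * floor(config$positions / config$box)
    config
  })
}
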