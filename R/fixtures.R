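#' Deterministic analysis fixtures with known observables
#'
#' Builds hand-constructed frames whose observables are known by
#' construction, so every analysis stage can be exercised without running
#' any dynamics:
#'
#' * `"clustered"` - H-NS cores laid out in prescribed connected
#'   components (compact grids with 2.5-sigma spacing, components at least
#'   14 sigma apart), far from a small reference ring; the cluster-size
#'   histogram, `theta = 0` and the ring radius are the ground truth.
#' * `"mixed_binding"` - a ring with dimers placed at prescribed sub- and
#'   super-cutoff distances: bridging dimers straddle two monomers two
#'   bonds apart, dangling dimers present one patch at 0.5 sigma with the
#'   other pointing away, free dimers sit far from everything.
#' * `"known_rg"` - monomers equally spaced on a circle, whose radius of
#'   gyration equals the circle radius exactly.
#'
#' @param kind fixture kind.
#' @param seed seed for the (inessential) random orientations.
#' @param sizes cluster sizes for `"clustered"`.
#' @param n_dangling,n_bridging,n_free dimer counts for `"mixed_binding"`.
#' @param radius,n_monomers circle geometry for `"known_rg"`.
#' @return An object of class `fixture_frame`: a list with the `config`
#'   (a `particle_config`) and `truth` (list with `rg`, `theta`,
#'   `frac_dangling`, `frac_bridging`, `cluster_sizes`).
#' @examples
#' fx <- make_fixture("mixed_binding")
#' classify_binding(fx$config)$theta == fx$truth$theta
#' @export
make_fixture <- function(kind = c("clustered", "mixed_binding", "known_rg"),
                         seed = 1, sizes = c(24, 3, 2, 1),
                         n_dangling = 3, n_bridging = 2, n_free = 5,
                         radius = 10, n_monomers = 100) {
  kind <- match.arg(kind)
  switch(kind,
    clustered = fixture_clustered(sizes, seed),
    mixed_binding = fixture_mixed_binding(n_dangling, n_bridging, n_free, seed),
    known_rg = fixture_known_rg(radius, n_monomers)
  )
}

circle_ring_config <- function(n, radius, center, box) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(
    center[1] + radius * cos(t), center[2] + radius * sin(t),
    rep(center[3], n)
  )
  list(
    positions = pos, species = rep(1L, n), molecule = rep(1L, n),
    bonds = data.frame(
      i = seq_len(n), j = c(seq_len(n)[-1], 1L), kind = "fene",
      stringsAsFactors = FALSE
    )
  )
}

append_triplex <- function(parts, center, axis, mol_id) {
  tri <- build_hns_triplex(center, axis)
  off <- nrow(parts$positions)
  parts$positions <- rbind(parts$positions, tri$positions)
  parts$species <- c(parts$species, tri$species)
  parts$molecule <- c(parts$molecule, rep(mol_id, 3L))
  parts$bonds <- rbind(parts$bonds, data.frame(
    i = tri$bonds$i + off, j = tri$bonds$j + off, kind = "hns",
    stringsAsFactors = FALSE
  ))
  parts$angles <- rbind(
    if (is.null(parts$angles)) matrix(integer(0), ncol = 3) else parts$angles,
    tri$angles + off
  )
  parts
}

finish_fixture <- function(parts, box, n_monomers, truth) {
  cfg <- new_particle_config(
    positions = parts$positions, species = parts$species,
    molecule = parts$molecule, bonds = parts$bonds,
    angles = if (is.null(parts$angles)) matrix(integer(0), ncol = 3) else parts$angles,
    box = box, n_monomers = n_monomers
  )
  structure(list(config = cfg, truth = truth), class = "fixture_frame")
}

fixture_clustered <- function(sizes, seed) {
  stopifnot(all(sizes >= 1), length(sizes) >= 1, length(sizes) <= 18)
  box <- 50
  n_ring <- 20L
  ring_radius <- n_ring * 0.97 / (2 * pi)
  parts <- circle_ring_config(n_ring, ring_radius, c(25, 25, 5), box)
  parts$angles <- matrix(integer(0), ncol = 3)
  centers <- as.matrix(expand.grid(
    x = c(10, 25, 40), y = c(10, 25, 40), z = c(20, 35)
  ))
  spacing <- 2.5 # grid spacing inside a component: < 3 connects, > core size
  mol <- 1L
  for (ci in seq_along(sizes)) {
    ctr <- centers[ci, ]
    m <- ceiling(sizes[ci]^(1 / 3))
    offs <- as.matrix(expand.grid(
      x = seq_len(m), y = seq_len(m), z = seq_len(m)
    ))[seq_len(sizes[ci]), , drop = FALSE]
    offs <- sweep(offs, 2, (m + 1) / 2) * spacing
    for (k in seq_len(sizes[ci])) {
      mol <- mol + 1L
      parts <- append_triplex(parts, ctr + offs[k, ], c(0, 0, 1), mol)
    }
  }
  truth <- list(
    rg = ring_radius, theta = 0, frac_dangling = 0, frac_bridging = 0,
    cluster_sizes = sort(sizes, decreasing = TRUE)
  )
  finish_fixture(parts, box, n_ring, truth)
}

fixture_mixed_binding <- function(n_dangling, n_bridging, n_free, seed) {
  box <- 50
  n_ring <- 40L
  n_sites <- n_dangling + n_bridging
  stopifnot(n_sites * 5 <= n_ring, n_free >= 0)
  ring_radius <- n_ring * 0.97 / (2 * pi)
  center <- c(25, 25, 25)
  parts <- circle_ring_config(n_ring, ring_radius, center, box)
  parts$angles <- matrix(integer(0), ncol = 3)
  pos <- parts$positions
  sites <- 1L + 5L * (seq_len(n_sites) - 1L) # monomer anchor sites, >= 5 apart
  mol <- 1L
  for (k in seq_len(n_bridging)) {
    i <- sites[k]
    j <- i + 2L
    mid <- (pos[i, ] + pos[j, ]) / 2
    axis <- pos[j, ] - pos[i, ]
    axis <- axis / sqrt(sum(axis^2))
    mol <- mol + 1L
    parts <- append_triplex(parts, mid, axis, mol)
  }
  for (k in seq_len(n_dangling)) {
    i <- sites[n_bridging + k]
    radial <- pos[i, ] - center
    radial <- radial / sqrt(sum(radial^2))
    mol <- mol + 1L
    # patch A ends up 0.5 sigma from monomer i; patch B points away
    parts <- append_triplex(parts, pos[i, ] + 0.9 * radial, radial, mol)
  }
  if (n_free > 0) {
    with_seed(seed, {
      for (k in seq_len(n_free)) {
        ctr <- c(5 + (k - 1) * 6, 5, 45) # > 3 sigma apart and far from ring
        ax <- rnorm(3)
        ax <- ax / sqrt(sum(ax^2))
        mol <- mol + 1L
        parts <- append_triplex(parts, ctr, ax, mol)
      }
    })
  }
  n_hns <- n_bridging + n_dangling + n_free
  truth <- list(
    rg = ring_radius,
    theta = (n_dangling + n_bridging) / n_hns,
    frac_dangling = n_dangling / n_hns,
    frac_bridging = n_bridging / n_hns,
    cluster_sizes = rep(1L, n_hns)
  )
  finish_fixture(parts, box, n_ring, truth)
}

fixture_known_rg <- function(radius, n_monomers) {
  box <- max(50, 2 * radius + 10)
  parts <- circle_ring_config(
    n_monomers, radius, rep(box / 2, 3), box
  )
  parts$angles <- matrix(integer(0), ncol = 3)
  truth <- list(
    rg = radius, theta = NA_real_, frac_dangling = NA_real_,
    frac_bridging = NA_real_, cluster_sizes = integer(0)
  )
  finish_fixture(parts, box, n_monomers, truth)
}

#' @export
print.fixture_frame <- function(x, ...) {
  cat("fixture_frame with ground truth:\n")
  str(x$truth, give.attr = FALSE)
  invisible(x)
}
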