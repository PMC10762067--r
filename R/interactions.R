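#' Pair interaction parameters
#'
#' A single entry of the species-pair interaction table: the strength
#' `epsilon` (in units of the thermal energy), range `sigma` and cutoff
#' `r_cut` (in monomer diameters) of a truncated-shifted Lennard-Jones
#' potential. Pairs that do not interact at all (patch-core and
#' patch-crowder) are represented explicitly with `active = FALSE` rather
#' than with a zero strength, so the tabulated model is auditable entry by
#' entry.
#'
#' @param epsilon interaction strength, in units of \eqn{\epsilon = k_BT}.
#' @param sigma interaction range parameter, in monomer diameters
#'   \eqn{\sigma}.
#' @param r_cut cutoff distance, in \eqn{\sigma}; the potential is shifted
#'   so it vanishes continuously there.
#' @param active logical; `FALSE` encodes a non-interacting pair, which
#'   contributes exactly zero energy and force.
#' @return An object of class `pair_params`.
#' @examples
#' wca <- pair_params(1, 1, 2^(1 / 6))
#' pair_energy(2^(1 / 6), wca) # zero at the shifted minimum
#' @export
pair_params <- function(epsilon, sigma, r_cut, active = TRUE) {
  stopifnot(is.logical(active), length(active) == 1L)
  if (active) {
    stopifnot(
      is.finite(epsilon), epsilon > 0,
      is.finite(sigma), sigma > 0,
      is.finite(r_cut), r_cut > 0
    )
  } else {
    epsilon <- NA_real_
    sigma <- NA_real_
    r_cut <- NA_real_
  }
  structure(
    list(epsilon = epsilon, sigma = sigma, r_cut = r_cut, active = active),
    class = "pair_params"
  )
}

#' @export
print.pair_params <- function(x, ...) {
  if (x$active) {
    cat(sprintf(
      "pair_params: epsilon = %g eps, sigma = %g sig, r_cut = %g sig\n",
      x$epsilon, x$sigma, x$r_cut
    ))
  } else {
    cat("pair_params: inactive (no interaction)\n")
  }
  invisible(x)
}

#' Species pair-parameter table
#'
#' Builds the symmetric 4x4 interaction table over the species
#' monomer (1), H-NS patch (2), H-NS core (3) and crowder (4). All pairs
#' are purely repulsive (cutoff at the potential minimum
#' \eqn{2^{1/6}\sigma_{ij}}, i.e. WCA) except the patch-monomer pair, whose
#' cutoff is extended to \eqn{0.685\sigma} so that it is attractive in
#' \eqn{0.6 < r < 0.685}; its strength \eqn{\epsilon_{12} = 29} is
#' calibrated so the well depth is about \eqn{-8.65\,k_BT}, close to the
#' measured H-NS-DNA binding free energy. Patch-core and patch-crowder
#' pairs do not interact.
#'
#' The `"N200"` geometry uses crowders of diameter \eqn{2\sigma}; the
#' `"N2000"` geometry uses \eqn{4\sigma} crowders (and correspondingly
#' larger monomer-crowder and core-crowder ranges).
#'
#' @param geometry `"N200"` (default) or `"N2000"` crowder geometry.
#' @param epsilon_12 patch-monomer interaction strength (\eqn{k_BT}).
#' @param permeable_hns logical; if `TRUE` the core-crowder pair is switched
#'   off (\eqn{\epsilon_{34} = 0}), making H-NS permeable to crowders; the
#'   monomer-crowder and crowder-crowder pairs are unaffected. This isolates
#'   the depletion force between H-NS dimers as a control.
#' @return An object of class `interaction_table` with 4x4 matrices
#'   `epsilon`, `sigma`, `r_cut` and logical `active`.
#' @examples
#' tbl <- interaction_table()
#' get_pair(tbl, 1, 2)
#' @export
interaction_table <- function(geometry = c("N200", "N2000"),
                              epsilon_12 = 29.0,
                              permeable_hns = FALSE) {
  geometry <- match.arg(geometry)
  rc_wca <- function(s) s * 2^(1 / 6)
  sig_c <- if (geometry == "N200") 2.0 else 4.0
  sig_14 <- if (geometry == "N200") 1.5 else 2.5
  sig_34 <- if (geometry == "N200") 1.5 else 2.5

  eps <- matrix(NA_real_, 4, 4)
  sig <- matrix(NA_real_, 4, 4)
  rcut <- matrix(NA_real_, 4, 4)
  act <- matrix(FALSE, 4, 4)
  set_pair <- function(i, j, pp) {
    eps[i, j] <<- eps[j, i] <<- pp$epsilon
    sig[i, j] <<- sig[j, i] <<- pp$sigma
    rcut[i, j] <<- rcut[j, i] <<- pp$r_cut
    act[i, j] <<- act[j, i] <<- pp$active
  }
  set_pair(1, 1, pair_params(1.0, 1.0, rc_wca(1.0)))
  # patch-monomer: sigma_12 = 0.6/2^(1/6) ~ 0.535, with the cutoff extended
  # past the minimum by 0.085 sigma so the well (depth ~ -8.65 kT at
  # r ~ 0.6) is retained. The tabulated three-decimal values are used, not
  # the analytic expressions; the well depth matches at these values.
  set_pair(1, 2, pair_params(epsilon_12, 0.535, 0.685))
  set_pair(1, 3, pair_params(1.0, 1.0, rc_wca(1.0)))
  set_pair(1, 4, pair_params(1.0, sig_14, rc_wca(sig_14)))
  set_pair(2, 2, pair_params(1.0, 0.178, 0.2))
  set_pair(2, 3, pair_params(active = FALSE))
  set_pair(2, 4, pair_params(active = FALSE))
  set_pair(3, 3, pair_params(1.0, 1.0, rc_wca(1.0)))
  if (permeable_hns) {
    set_pair(3, 4, pair_params(active = FALSE))
  } else {
    set_pair(3, 4, pair_params(1.0, sig_34, rc_wca(sig_34)))
  }
  set_pair(4, 4, pair_params(1.0, sig_c, rc_wca(sig_c)))

  dimnames(eps) <- dimnames(sig) <- dimnames(rcut) <- dimnames(act) <-
    list(SPECIES_NAMES, SPECIES_NAMES)
  structure(
    list(
      epsilon = eps, sigma = sig, r_cut = rcut, active = act,
      geometry = geometry, permeable_hns = permeable_hns
    ),
    class = "interaction_table"
  )
}

#' Extract one pair entry from an interaction table
#'
#' @param table an [interaction_table()].
#' @param i,j species indices in 1..4 (monomer, patch, core, crowder) or
#'   species names.
#' @return A [pair_params()] object.
#' @export
get_pair <- function(table, i, j) {
  stopifnot(inherits(table, "interaction_table"))
  if (is.character(i)) i <- match(i, SPECIES_NAMES)
  if (is.character(j)) j <- match(j, SPECIES_NAMES)
  stopifnot(i %in% 1:4, j %in% 1:4)
  if (!table$active[i, j]) {
    return(pair_params(active = FALSE))
  }
  pair_params(table$epsilon[i, j], table$sigma[i, j], table$r_cut[i, j])
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf(
    "interaction_table (%s geometry%s)\n", x$geometry,
    if (x$permeable_hns) ", permeable H-NS" else ""
  ))
  print(dump_table(x))
  invisible(x)
}

#' Tabulate the effective pair parameters
#'
#' Returns the full upper-triangle pair table as a data frame (one row per
#' species pair), suitable for audit or for the `--dump-table` option of
#' the command-line interface.
#'
#' @param table an [interaction_table()].
#' @return A data frame with columns `pair`, `epsilon`, `sigma`, `r_cut`,
#'   `active`.
#' @export
dump_table <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  rows <- list()
  for (i in 1:4) {
    for (j in i:4) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = sprintf("%d-%d", i, j),
        epsilon = table$epsilon[i, j],
        sigma = table$sigma[i, j],
        r_cut = table$r_cut[i, j],
        active = table$active[i, j]
      )
    }
  }
  do.call(rbind, rows)
}

#' Truncated-shifted Lennard-Jones pair energy
#'
#' \eqn{U(r) = U_{LJ}(r) - U_{LJ}(r_c)} for \eqn{r < r_c} and zero beyond,
#' with \eqn{U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}. The
#' shift makes the potential continuous at the cutoff. An inactive pair
#' returns exactly zero by contract.
#'
#' @param r center-to-center distance(s), in \eqn{\sigma}; must be positive.
#' @param pp a [pair_params()] object.
#' @return Energy in \eqn{k_BT}, vectorized over `r`.
#' @export
pair_energy <- function(r, pp) {
  stopifnot(inherits(pp, "pair_params"), is.numeric(r))
  if (any(r <= 0)) {
    stop("pair_energy: distance must be positive")
  }
  if (!pp$active) {
    return(rep(0, length(r)))
  }
  ulj <- function(r) {
    x6 <- (pp$sigma / r)^6
    4 * pp$epsilon * (x6^2 - x6)
  }
  u <- ifelse(r < pp$r_cut, ulj(r) - ulj(pp$r_cut), 0)
  as.numeric(u)
}

#' Radial pair force
#'
#' The signed radial force \eqn{F(r) = -dU/dr} of [pair_energy()]; positive
#' values are repulsive. Identically zero at and beyond the cutoff and for
#' inactive pairs.
#'
#' @inheritParams pair_energy
#' @return Force in \eqn{k_BT/\sigma}, vectorized over `r`.
#' @export
pair_force <- function(r, pp) {
  stopifnot(inherits(pp, "pair_params"), is.numeric(r))
  if (any(r <= 0)) {
    stop("pair_force: distance must be positive")
  }
  if (!pp$active) {
    return(rep(0, length(r)))
  }
  x6 <- (pp$sigma / r)^6
  f <- ifelse(r < pp$r_cut, 24 * pp$epsilon * (2 * x6^2 - x6) / r, 0)
  as.numeric(f)
}

#' Bonded interaction parameters
#'
#' Parameters of the bonded part of the Hamiltonian: the FENE springs of
#' the ring backbone, the stiff harmonic bonds and the angle term that hold
#' the two patches of an H-NS dimer at its poles, and the harmonic tether
#' used when dimers are anchored to the polymer.
#'
#' @param fene_k0 FENE spring constant \eqn{k_0} (\eqn{k_BT/\sigma^2}).
#' @param fene_r0 FENE divergence length \eqn{r_0} (\eqn{\sigma}); bonds
#'   cannot stretch past it.
#' @param hns_K radial stiffness of the patch-core bond
#'   (\eqn{k_BT/\sigma^2}); the potential is \eqn{K (r - r_0)^2}.
#' @param hns_r0 rest patch-core distance (\eqn{\sigma}).
#' @param hns_kb angle stiffness (\eqn{k_BT}); the potential
#'   \eqn{k_b(\theta - \pi)^2} keeps the two patches antipodal.
#' @param anchor_k,anchor_r0 stiffness and rest length of the harmonic
#'   anchor bond used by [anchor_hns()].
#' @return An object of class `bonded_params`.
#' @export
bonded_params <- function(fene_k0 = 30, fene_r0 = 1.5,
                          hns_K = 120, hns_r0 = 0.4, hns_kb = 50,
                          anchor_k = 120, anchor_r0 = 0.6) {
  stopifnot(
    fene_k0 > 0, fene_r0 > 0, hns_K > 0, hns_r0 > 0, hns_kb > 0,
    anchor_k > 0, anchor_r0 > 0,
    fene_r0 > 1 # must exceed the typical ~0.97 sigma bond length
  )
  structure(
    list(
      fene_k0 = fene_k0, fene_r0 = fene_r0, hns_K = hns_K,
      hns_r0 = hns_r0, hns_kb = hns_kb,
      anchor_k = anchor_k, anchor_r0 = anchor_r0
    ),
    class = "bonded_params"
  )
}

#' FENE bond energy
#'
#' \eqn{U(r) = -\tfrac{1}{2} k_0 r_0^2 \ln[1 - (r/r_0)^2]}: finitely
#' extensible nonlinear elastic spring, diverging as \eqn{r \to r_0}.
#' Together with the WCA monomer repulsion this prevents chain crossing.
#'
#' @param r bond extension(s), in \eqn{\sigma}; must satisfy
#'   \eqn{0 \le r < r_0}.
#' @param bp a [bonded_params()] object.
#' @return Energy in \eqn{k_BT}, vectorized over `r`.
#' @export
fene_energy <- function(r, bp = bonded_params()) {
  stopifnot(inherits(bp, "bonded_params"), is.numeric(r))
  if (any(r < 0)) {
    stop("fene_energy: extension must be non-negative")
  }
  if (any(r >= bp$fene_r0)) {
    stop(sprintf(
      "fene_energy: bond overstretched (r >= r0 = %g sigma)", bp$fene_r0
    ))
  }
  -0.5 * bp$fene_k0 * bp$fene_r0^2 * log(1 - (r / bp$fene_r0)^2)
}

#' Internal energy of an H-NS triplex
#'
#' The dimer is a core sphere with two patch spheres near its poles, held
#' by one radial harmonic term \eqn{K(|r_{patch} - r_{core}| - r_0)^2} per
#' patch plus one shared angle term \eqn{k_b(\theta - \pi)^2}, where
#' \eqn{\theta} is the angle between the two core-to-patch vectors. The
#' energy is zero for antipodal patches at the rest distance.
#'
#' @param core,patch_a,patch_b numeric length-3 position vectors.
#' @param bp a [bonded_params()] object.
#' @return Energy in \eqn{k_BT}.
#' @export
hns_internal_energy <- function(core, patch_a, patch_b,
                                bp = bonded_params()) {
  stopifnot(
    inherits(bp, "bonded_params"),
    length(core) == 3, length(patch_a) == 3, length(patch_b) == 3
  )
  d1 <- patch_a - core
  d2 <- patch_b - core
  r1 <- sqrt(sum(d1^2))
  r2 <- sqrt(sum(d2^2))
  if (r1 < 1e-12 || r2 < 1e-12) {
    stop("hns_internal_energy: patch coincides with core")
  }
  cth <- sum(d1 * d2) / (r1 * r2)
  cth <- min(1, max(-1, cth))
  theta <- acos(cth)
  bp$hns_K * (r1 - bp$hns_r0)^2 + bp$hns_K * (r2 - bp$hns_r0)^2 +
    bp$hns_kb * (theta - pi)^2
}

#' Locate the minimum of a pair potential
#'
#' Finds the global minimum of [pair_energy()] on \eqn{(0, r_c]}. For a
#' pair with a cutoff beyond \eqn{2^{1/6}\sigma_{ij}} the minimum sits at
#' \eqn{2^{1/6}\sigma_{ij}} with a strictly negative shifted value; for a
#' purely repulsive (WCA) pair the minimum is zero at the cutoff. Used to
#' audit the patch-monomer calibration (well depth about
#' \eqn{-8.65\,k_BT} at \eqn{r \approx 0.6\sigma}).
#'
#' @param pp an active [pair_params()] object.
#' @return A list with elements `r_min` and `u_min`.
#' @export
potential_minimum <- function(pp) {
  stopifnot(inherits(pp, "pair_params"))
  if (!pp$active) {
    stop("potential_minimum: pair is inactive")
  }
  rmin_lj <- 2^(1 / 6) * pp$sigma
  if (rmin_lj >= pp$r_cut) {
    # repulsive branch only: minimum (zero) at the cutoff
    return(list(r_min = pp$r_cut, u_min = 0))
  }
  opt <- optimize(function(r) pair_energy(r, pp),
    interval = c(0.5 * pp$sigma, pp$r_cut), tol = 1e-10
  )
  list(r_min = opt$minimum, u_min = opt$objective)
}
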