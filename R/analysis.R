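#' Radius of gyration of the ring polymer
#'
#' Unwraps the ring across periodic images by walking its bonds under the
#' minimum-image convention (starting monomer is immaterial), verifies the
#' walk closes, and returns
#' \eqn{R_g = \sqrt{\frac{1}{N}\sum_i |r_i - r_{cm}|^2}} over the N
#' monomers.
#'
#' @param frame a `particle_config` containing the ring (monomers are the
#'   particles with species 1, in ring order).
#' @return \eqn{R_g} in \eqn{\sigma}.
#' @export
radius_of_gyration <- function(frame) {
  stopifnot(inherits(frame, "particle_config"))
  mon <- which(frame$species == 1L)
  if (length(mon) < 2) {
    stop("radius_of_gyration: frame contains no ring polymer")
  }
  rg_of_ring(frame$positions[mon, , drop = FALSE], frame$box)
}

rg_of_ring <- function(pos, box) {
  n <- nrow(pos)
  d <- pos[c(seq_len(n)[-1], 1L), , drop = FALSE] - pos
  d <- d - box * round(d / box)
  if (any(rowSums(d * d) > (box / 2)^2)) {
    stop("radius_of_gyration: broken ring (a bond exceeds half the box after unwrapping)")
  }
  closure <- colSums(d)
  if (sqrt(sum(closure^2)) > 1e-6) {
    stop("radius_of_gyration: broken ring (bond walk does not close)")
  }
  u <- rbind(c(0, 0, 0), apply(d[-n, , drop = FALSE], 2, cumsum))
  u <- sweep(u, 2, colMeans(u))
  sqrt(mean(rowSums(u * u)))
}

# layout bookkeeping: each triplex was assembled as (core, patch A, patch B)
hns_layout <- function(species) {
  cores <- which(species == 3L)
  list(
    cores = cores, patch_a = cores + 1L, patch_b = cores + 2L,
    n_hns = length(cores)
  )
}

#' Classify the binding mode of every H-NS dimer
#'
#' A patch is in contact with a monomer when their minimum-image distance
#' is below `contact_cutoff`, the outer edge of the attractive
#' patch-monomer well (\eqn{0.685\sigma} by default). A dimer with no
#' patch in contact is unbound, with exactly one patch in contact dangling
#' (single-site binding), and with both patches in contact bridging
#' (cross-linking, two-site binding). The binding probability
#' \eqn{\theta} is the bound fraction, so
#' \eqn{\theta = } `frac_dangling + frac_bridging` exactly.
#'
#' @param frame a `particle_config` with monomers and H-NS.
#' @param contact_cutoff patch-monomer contact distance, in \eqn{\sigma}.
#' @return An object of class `binding_record`: a per-dimer data frame
#'   (`hns`, `mode`, `span`, `label`) plus elements `theta`,
#'   `frac_dangling`, `frac_bridging` and the per-patch contact sets.
#' @export
classify_binding <- function(frame, contact_cutoff = 0.685) {
  stopifnot(inherits(frame, "particle_config"))
  lay <- hns_layout(frame$species)
  if (lay$n_hns == 0) {
    stop("classify_binding: no H-NS present; the binding probability is undefined")
  }
  mon <- which(frame$species == 1L)
  n_mon <- length(mon)
  classify_binding_raw(
    frame$positions, frame$box, mon, lay, contact_cutoff, n_mon
  )
}

classify_binding_raw <- function(pos, box, mon, lay, contact_cutoff, n_mon) {
  pa <- pos[lay$patch_a, , drop = FALSE]
  pb <- pos[lay$patch_b, , drop = FALSE]
  mp <- pos[mon, , drop = FALSE]
  cut2 <- contact_cutoff^2
  da <- pbc_cross_dist2(pa, mp, box) < cut2
  db <- pbc_cross_dist2(pb, mp, box) < cut2
  contacts_a <- apply(da, 1, which, simplify = FALSE)
  contacts_b <- apply(db, 1, which, simplify = FALSE)
  bound_a <- rowSums(da) > 0
  bound_b <- rowSums(db) > 0
  mode <- ifelse(bound_a & bound_b, "bridging",
    ifelse(bound_a | bound_b, "dangling", "unbound")
  )
  span <- rep(NA_integer_, lay$n_hns)
  label <- rep(NA_character_, lay$n_hns)
  for (k in which(mode == "bridging")) {
    bs <- bridge_span(
      list(
        contacts_a = contacts_a[[k]], contacts_b = contacts_b[[k]],
        mode = "bridging"
      ),
      n_mon
    )
    span[k] <- bs$span
    label[k] <- bs$label
  }
  records <- data.frame(
    hns = seq_len(lay$n_hns), mode = mode, span = span, label = label,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      records = records, contacts_a = contacts_a, contacts_b = contacts_b,
      n_hns = lay$n_hns,
      theta = mean(mode != "unbound"),
      frac_dangling = mean(mode == "dangling"),
      frac_bridging = mean(mode == "bridging")
    ),
    class = "binding_record"
  )
}

#' @export
print.binding_record <- function(x, ...) {
  cat(sprintf(
    "binding_record: %d H-NS; theta = %.3f (dangling %.3f + bridging %.3f)\n",
    x$n_hns, x$theta, x$frac_dangling, x$frac_bridging
  ))
  invisible(x)
}

#' Genomic span of a bridging dimer
#'
#' The minimal separation along the ring between the closest pair of bound
#' monomers across the two patches of a bridging dimer. A bridge joining
#' sites more than two monomers apart is in trans (a genuine long-range
#' cross-link); otherwise it is in cis.
#'
#' @param record a list with integer `contacts_a`, `contacts_b` (monomer
#'   indices along the ring) and `mode`, e.g. one dimer's entry from
#'   [classify_binding()].
#' @param n_monomers ring length N.
#' @param trans_threshold spans strictly greater than this count as trans.
#' @return A list with `span` (monomers) and `label` (`"cis"`/`"trans"`).
#' @export
bridge_span <- function(record, n_monomers, trans_threshold = 2) {
  if (!identical(record$mode, "bridging")) {
    stop("bridge_span: dimer is not bridging")
  }
  a <- as.integer(record$contacts_a)
  b <- as.integer(record$contacts_b)
  stopifnot(length(a) > 0, length(b) > 0)
  dd <- abs(outer(a, b, "-"))
  dd <- pmin(dd, n_monomers - dd)
  span <- min(dd)
  list(span = as.integer(span), label = if (span > trans_threshold) "trans" else "cis")
}

#' Detect H-NS clusters
#'
#' Two dimers belong to the same cluster when their core spheres are
#' within `cluster_cutoff` (centre-to-centre, minimum image); clusters are
#' the connected components of that proximity graph, so a chain of
#' pairwise-close cores counts as one cluster regardless of its shape.
#' Every core belongs to exactly one cluster; isolated cores are clusters
#' of size 1. All dimers are counted, bound or not.
#'
#' @param frame a `particle_config` with H-NS cores.
#' @param cluster_cutoff clustering distance, in \eqn{\sigma}.
#' @return An object of class `cluster_report`: per-dimer `labels`,
#'   cluster `sizes`, a size `histogram`, `n_clusters` and `mean_size`.
#' @export
detect_clusters <- function(frame, cluster_cutoff = 3) {
  stopifnot(inherits(frame, "particle_config"))
  lay <- hns_layout(frame$species)
  cores_pos <- frame$positions[lay$cores, , drop = FALSE]
  detect_clusters_raw(cores_pos, frame$box, cluster_cutoff)
}

detect_clusters_raw <- function(cores_pos, box, cluster_cutoff) {
  n <- nrow(cores_pos)
  if (n == 0) {
    return(structure(
      list(
        labels = integer(0), sizes = integer(0),
        histogram = data.frame(size = integer(0), count = integer(0)),
        n_clusters = 0L, mean_size = NA_real_
      ),
      class = "cluster_report"
    ))
  }
  adj <- pbc_cross_dist2(cores_pos, cores_pos, box) <= cluster_cutoff^2
  diag(adj) <- FALSE
  if (any(adj)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    labels <- as.integer(comp$membership)
  } else {
    labels <- seq_len(n)
  }
  sizes <- as.integer(table(labels))
  tab <- table(sizes)
  structure(
    list(
      labels = labels, sizes = sizes,
      histogram = data.frame(
        size = as.integer(names(tab)), count = as.integer(tab)
      ),
      n_clusters = length(sizes), mean_size = mean(sizes)
    ),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "cluster_report: %d dimers in %d clusters (mean size %.2f, max %s)\n",
    length(x$labels), x$n_clusters,
    x$mean_size, if (x$n_clusters > 0) max(x$sizes) else "-"
  ))
  invisible(x)
}

# moving-block bootstrap standard error of a time-series mean
block_bootstrap_se <- function(x, n_blocks = 20, n_boot = 200) {
  n <- length(x)
  if (n < 4) {
    return(NA_real_)
  }
  n_blocks <- min(n_blocks, n %/% 2)
  bl <- n %/% n_blocks
  starts <- seq(1, n - bl + 1)
  with_seed(271828L, {
    means <- vapply(seq_len(n_boot), function(b) {
      s <- sample(starts, n_blocks, replace = TRUE)
      mean(x[as.vector(outer(0:(bl - 1), s, "+"))])
    }, numeric(1))
    sd(means)
  })
}

#' Per-frame observables and trajectory summary
#'
#' Computes, for every frame: the radius of gyration, the binding
#' probability \eqn{\theta} with its dangling/bridging decomposition, and
#' the H-NS cluster partition. Summaries are the time means with
#' block-bootstrap standard errors, the pooled cluster-size histogram, and
#' the pooled mean cluster size (total dimers clustered over total cluster
#' count, all frames). If a reference `rg0` is supplied, the compaction
#' ratio \eqn{R_g/R_{g0}} is reported as well.
#'
#' @param traj an `md_trajectory` (or one read from disk).
#' @param rg0 optional baseline radius of gyration (from a crowder-free,
#'   binder-free run) used for the compaction ratio.
#' @param contact_cutoff,cluster_cutoff analysis cutoffs, in \eqn{\sigma}.
#' @return A list of class `observable_summary` with `per_frame` (a data
#'   frame), `histogram`, and `summary`.
#' @export
aggregate_observables <- function(traj, rg0 = NULL, contact_cutoff = 0.685,
                                  cluster_cutoff = 3) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf == 0) {
    stop("aggregate_observables: trajectory has no frames")
  }
  if (!is.null(rg0)) stopifnot(rg0 > 0)
  species <- traj$species
  mon <- which(species == 1L)
  lay <- hns_layout(species)
  n <- length(species)
  has_hns <- lay$n_hns > 0

  rg <- numeric(nf)
  theta <- fd <- fb <- rep(NA_real_, nf)
  ncl <- maxcl <- rep(NA_integer_, nf)
  all_sizes <- vector("list", nf)
  for (k in seq_len(nf)) {
    pos <- matrix(traj$frames[k, , ], n, 3)
    rg[k] <- rg_of_ring(pos[mon, , drop = FALSE], traj$box)
    if (has_hns) {
      b <- classify_binding_raw(
        pos, traj$box, mon, lay, contact_cutoff, length(mon)
      )
      theta[k] <- b$theta
      fd[k] <- b$frac_dangling
      fb[k] <- b$frac_bridging
      cl <- detect_clusters_raw(
        pos[lay$cores, , drop = FALSE], traj$box, cluster_cutoff
      )
      ncl[k] <- cl$n_clusters
      maxcl[k] <- max(cl$sizes)
      all_sizes[[k]] <- cl$sizes
    }
  }
  per_frame <- data.frame(
    time = traj$times, rg = rg, theta = theta, frac_dangling = fd,
    frac_bridging = fb, n_clusters = ncl, max_cluster = maxcl
  )
  pooled <- unlist(all_sizes)
  if (length(pooled) > 0) {
    tab <- table(pooled)
    histogram <- data.frame(
      size = as.integer(names(tab)), count = as.integer(tab)
    )
    mean_cluster <- sum(pooled) / length(pooled)
  } else {
    histogram <- data.frame(size = integer(0), count = integer(0))
    mean_cluster <- NA_real_
  }
  summary <- list(
    n_frames = nf,
    mean_rg = mean(rg), se_rg = block_bootstrap_se(rg),
    mean_theta = if (has_hns) mean(theta) else NA_real_,
    se_theta = if (has_hns) block_bootstrap_se(theta) else NA_real_,
    mean_frac_dangling = if (has_hns) mean(fd) else NA_real_,
    mean_frac_bridging = if (has_hns) mean(fb) else NA_real_,
    mean_cluster_size = mean_cluster
  )
  if (!is.null(rg0)) {
    summary$rg0 <- rg0
    summary$mean_rg_ratio <- summary$mean_rg / rg0
    summary$se_rg_ratio <- summary$se_rg / rg0
  }
  structure(
    list(per_frame = per_frame, histogram = histogram, summary = summary),
    class = "observable_summary"
  )
}

#' @export
print.observable_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("observable_summary over %d frames\n", s$n_frames))
  cat(sprintf("  <Rg> = %.3f +/- %.3f sigma\n", s$mean_rg, s$se_rg))
  if (!is.null(s$mean_rg_ratio)) {
    cat(sprintf(
      "  <Rg>/Rg0 = %.3f +/- %.3f (Rg0 = %.3f)\n",
      s$mean_rg_ratio, s$se_rg_ratio, s$rg0
    ))
  }
  if (!is.na(s$mean_theta)) {
    cat(sprintf(
      "  theta = %.3f +/- %.3f (dangling %.3f + bridging %.3f)\n",
      s$mean_theta, s$se_theta, s$mean_frac_dangling, s$mean_frac_bridging
    ))
    cat(sprintf("  mean cluster size = %.2f\n", s$mean_cluster_size))
  }
  invisible(x)
}
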