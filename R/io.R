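#' Write a trajectory or configuration to a text file
#'
#' Two dialects are supported: extended XYZ (species tag column plus a
#' `Lattice=...` comment line) and a LAMMPS-dump text dialect
#' (`ITEM: TIMESTEP` / `NUMBER OF ATOMS` / `BOX BOUNDS pp pp pp` /
#' `ATOMS id type x y z`). Particle ids are 1-based in both formats;
#' positions are printed to 1e-6 sigma.
#'
#' @param x an `md_trajectory` or a single `particle_config`.
#' @param path output file.
#' @param dialect `"xyz"` or `"lammpsdump"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path, dialect = c("xyz", "lammpsdump")) {
  dialect <- match.arg(dialect)
  if (inherits(x, "particle_config")) {
    frames <- list(list(pos = x$positions, time = 0))
    species <- x$species
    box <- x$box
  } else {
    stopifnot(inherits(x, "md_trajectory"))
    nf <- n_frames(x)
    n <- length(x$species)
    frames <- lapply(seq_len(nf), function(k) {
      list(pos = matrix(x$frames[k, , ], n, 3), time = x$times[k])
    })
    species <- x$species
    box <- x$box
  }
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(species)
  for (fr in frames) {
    if (dialect == "xyz") {
      writeLines(as.character(n), con)
      writeLines(sprintf(
        'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3 Time=%g',
        box, box, box, fr$time
      ), con)
      writeLines(sprintf(
        "%s %.6f %.6f %.6f", SPECIES_TAGS[species],
        fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]
      ), con)
    } else {
      writeLines(c(
        "ITEM: TIMESTEP", as.character(fr$time),
        "ITEM: NUMBER OF ATOMS", as.character(n),
        "ITEM: BOX BOUNDS pp pp pp",
        sprintf("0 %g", box), sprintf("0 %g", box), sprintf("0 %g", box),
        "ITEM: ATOMS id type x y z"
      ), con)
      writeLines(sprintf(
        "%d %d %.6f %.6f %.6f", seq_len(n), species,
        fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]
      ), con)
    }
  }
  invisible(path)
}

#' Read a trajectory from a text file
#'
#' Parses the formats written by [write_trajectory()]. The species column
#' of an XYZ file must use the tags `M` (monomer), `P` (patch), `C` (core)
#' and `W` (crowder); LAMMPS-dump type codes are 1-4 in the same order.
#' Monomers are assumed to appear in ring order. A truncated file stops
#' with an error naming the last complete frame; an unknown species tag is
#' an error with its line number.
#'
#' @param path input file.
#' @param dialect `"xyz"` or `"lammpsdump"`.
#' @return An `md_trajectory` (without velocities or topology; bonds are
#'   reconstructed for the ring so the radius of gyration can be computed).
#' @export
read_trajectory <- function(path, dialect = c("xyz", "lammpsdump")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  frames <- list()
  times <- c()
  species <- NULL
  box <- NULL
  i <- 1L
  nframe <- 0L
  if (dialect == "xyz") {
    while (i <= length(lines)) {
      n <- suppressWarnings(as.integer(lines[i]))
      if (is.na(n)) {
        stop(sprintf(
          "read_trajectory: malformed frame header at line %d (after %d complete frames)",
          i, nframe
        ))
      }
      if (i + 1L + n > length(lines)) {
        stop(sprintf(
          "read_trajectory: truncated file; last complete frame is %d", nframe
        ))
      }
      hdr <- lines[i + 1L]
      lat <- regmatches(hdr, regexec('Lattice="([^"]+)"', hdr))[[1]][2]
      if (!is.na(lat)) {
        box <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])[1]
      }
      tm <- regmatches(hdr, regexec("Time=([0-9eE.+-]+)", hdr))[[1]][2]
      body <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
      tags <- vapply(body, `[`, character(1), 1L)
      sp <- match(tags, SPECIES_TAGS)
      if (anyNA(sp)) {
        bad <- which(is.na(sp))[1]
        stop(sprintf(
          "read_trajectory: unknown species tag '%s' at line %d",
          tags[bad], i + 1L + bad
        ))
      }
      pos <- t(vapply(
        body, function(z) as.numeric(z[2:4]), numeric(3)
      ))
      species <- as.integer(sp)
      frames[[length(frames) + 1L]] <- pos
      times <- c(times, if (is.na(tm)) nframe else as.numeric(tm))
      nframe <- nframe + 1L
      i <- i + 2L + n
    }
  } else {
    while (i <= length(lines)) {
      if (!startsWith(lines[i], "ITEM: TIMESTEP")) {
        stop(sprintf(
          "read_trajectory: expected 'ITEM: TIMESTEP' at line %d (after %d complete frames)",
          i, nframe
        ))
      }
      if (i + 8L > length(lines)) {
        stop(sprintf(
          "read_trajectory: truncated file; last complete frame is %d", nframe
        ))
      }
      tm <- as.numeric(lines[i + 1L])
      n <- as.integer(lines[i + 3L])
      bounds <- as.numeric(strsplit(trimws(lines[i + 5L]), "\\s+")[[1]])
      box <- bounds[2] - bounds[1]
      if (i + 8L + n > length(lines)) {
        stop(sprintf(
          "read_trajectory: truncated file; last complete frame is %d", nframe
        ))
      }
      body <- strsplit(trimws(lines[(i + 9L):(i + 8L + n)]), "\\s+")
      id <- vapply(body, function(z) as.integer(z[1]), integer(1))
      sp <- vapply(body, function(z) as.integer(z[2]), integer(1))
      if (any(sp < 1 | sp > 4)) {
        bad <- which(sp < 1 | sp > 4)[1]
        stop(sprintf(
          "read_trajectory: unknown species tag '%d' at line %d",
          sp[bad], i + 8L + bad
        ))
      }
      pos <- t(vapply(body, function(z) as.numeric(z[3:5]), numeric(3)))
      ord <- order(id)
      species <- sp[ord]
      frames[[length(frames) + 1L]] <- pos[ord, , drop = FALSE]
      times <- c(times, tm)
      nframe <- nframe + 1L
      i <- i + 9L + n
    }
  }
  if (nframe == 0L) {
    stop("read_trajectory: no frames found")
  }
  n <- length(species)
  arr <- array(NA_real_, c(nframe, n, 3))
  for (k in seq_len(nframe)) arr[k, , ] <- frames[[k]]
  n_mon <- sum(species == 1L)
  bonds <- if (n_mon >= 3) {
    data.frame(
      i = seq_len(n_mon), j = c(seq_len(n_mon)[-1], 1L), kind = "fene",
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(i = integer(0), j = integer(0), kind = character(0))
  }
  structure(
    list(
      frames = arr, frame_images = array(0L, c(nframe, n, 3)),
      times = times, epot = rep(NA_real_, nframe), box = box,
      species = species, molecule = rep(NA_integer_, n), bonds = bonds,
      angles = matrix(integer(0), ncol = 3), n_monomers = n_mon,
      spec = NULL, settings = NULL, schedule = NULL,
      mean_kinetic_temperature = NULL, final = NULL
    ),
    class = "md_trajectory"
  )
}

#' Save or load a simulation configuration
#'
#' The configuration file is a YAML key tree with three blocks (`system`,
#' `integrator`, `schedule`); all lengths are in sigma, energies in
#' epsilon = kT and times in tau. `read_config(write_config(...))` is a
#' lossless round trip.
#'
#' @param spec a [system_spec()].
#' @param settings an [integrator_settings()].
#' @param schedule a [run_schedule()].
#' @param path file path.
#' @param table optional [interaction_table()]; when given, the full pair
#'   table is embedded so non-default interactions travel with the config.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a list with `spec`, `settings`, `schedule` and `table` (`NULL` when
#'   the file carries none).
#' @export
write_config <- function(spec, settings, schedule, path, table = NULL) {
  stopifnot(
    inherits(spec, "system_spec"), inherits(settings, "integrator_settings"),
    inherits(schedule, "run_schedule")
  )
  cfg <- list(
    system = unclass(spec), integrator = unclass(settings),
    schedule = unclass(schedule)
  )
  if (!is.null(table)) {
    stopifnot(inherits(table, "interaction_table"))
    pairs <- dump_table(table)
    pairs[is.na(pairs)] <- 0 # inactive placeholders; ignored on read
    cfg$interactions <- list(
      geometry = table$geometry, permeable_hns = table$permeable_hns,
      pairs = pairs
    )
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  tbl <- NULL
  if (!is.null(y$interactions)) {
    tbl <- interaction_table(
      geometry = y$interactions$geometry,
      permeable_hns = isTRUE(y$interactions$permeable_hns)
    )
    p <- y$interactions$pairs
    for (k in seq_along(p$pair)) {
      ij <- as.integer(strsplit(p$pair[k], "-")[[1]])
      pp <- if (isTRUE(p$active[k])) {
        pair_params(p$epsilon[k], p$sigma[k], p$r_cut[k])
      } else {
        pair_params(active = FALSE)
      }
      tbl$epsilon[ij[1], ij[2]] <- tbl$epsilon[ij[2], ij[1]] <- pp$epsilon
      tbl$sigma[ij[1], ij[2]] <- tbl$sigma[ij[2], ij[1]] <- pp$sigma
      tbl$r_cut[ij[1], ij[2]] <- tbl$r_cut[ij[2], ij[1]] <- pp$r_cut
      tbl$active[ij[1], ij[2]] <- tbl$active[ij[2], ij[1]] <- pp$active
    }
  }
  list(
    spec = do.call(system_spec, y$system),
    settings = do.call(integrator_settings, y$integrator),
    schedule = do.call(run_schedule, y$schedule),
    table = tbl
  )
}

#' Experiment presets
#'
#' Named parameter sets for the two supported geometries. `"N200"`: a
#' 200-monomer ring in a 50-sigma box with 2-sigma crowders, the
#' production schedule (1e8 equilibration + 1e9 production steps, sampled
#' every 5e3 steps), and the sweep grid of crowder fractions crossed with
#' H-NS counts 0, 4, 8, 12, 16, 20, 30 (0 to 25.5 uM in the 125-nm box).
#' `"N2000"`: a 2000-monomer ring in a 110-sigma box with 4-sigma
#' crowders. The schedules are presets, not defaults; desk-scale work
#' should use [run_schedule_tau()] with shorter spans.
#'
#' @param name `"N200"` or `"N2000"`.
#' @param seed seed stored in the spec.
#' @return A list with `name`, `spec`, `table`, `settings`, `schedule`
#'   and the sweep `grid` (data frame of `phi_c`, `n_hns`).
#' @export
preset <- function(name = c("N200", "N2000"), seed = 1) {
  name <- match.arg(name)
  if (name == "N200") {
    spec <- system_spec(
      n_monomers = 200, box_side = 50, crowder_diameter = 2, seed = seed
    )
    tbl <- interaction_table("N200")
  } else {
    spec <- system_spec(
      n_monomers = 2000, box_side = 110, crowder_diameter = 4, seed = seed
    )
    tbl <- interaction_table("N2000")
  }
  grid <- expand.grid(
    phi_c = c(0, 0.1, 0.2, 0.32, 0.4),
    n_hns = c(0L, 4L, 8L, 12L, 16L, 20L, 30L)
  )
  list(
    name = name, spec = spec, table = tbl,
    settings = integrator_settings(dt = 0.005, temperature = 1,
      damping_time = 1, seed = seed),
    schedule = run_schedule(1e8, 1e9, 5e3),
    grid = grid
  )
}

#' Save a completed run to a directory
#'
#' Writes the trajectory (LAMMPS-dump dialect), the configuration YAML and
#' a JSON sidecar with the seed, package version and a content hash of the
#' parameters, so sweeps can be aggregated and audited later.
#'
#' @param traj an `md_trajectory` from [run_dynamics()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(traj, dir) {
  stopifnot(inherits(traj, "md_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(traj, file.path(dir, "trajectory.lammpsdump"),
    dialect = "lammpsdump"
  )
  if (!is.null(traj$spec)) {
    write_config(
      traj$spec, traj$settings, traj$schedule, file.path(dir, "config.yaml")
    )
  }
  meta <- list(
    seed = if (!is.null(traj$spec)) traj$spec$seed else NA,
    integrator_seed = if (!is.null(traj$settings)) traj$settings$seed else NA,
    package_version = as.character(packageVersion("nucleohns")),
    n_frames = n_frames(traj),
    mean_kinetic_temperature = traj$mean_kinetic_temperature,
    parameter_hash = parameter_hash(traj$spec, traj$settings, traj$schedule)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

parameter_hash <- function(spec, settings, schedule) {
  txt <- paste(
    deparse(unclass(spec)), deparse(unclass(settings)),
    deparse(unclass(schedule)),
    collapse = ";"
  )
  # small rolling hash; enough to flag mixed-parameter sweeps
  h <- 0
  for (ch in utf8ToInt(paste(txt, collapse = ""))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Load a run directory saved by [save_run()]
#' @param dir the run directory.
#' @return A list with `traj` (an `md_trajectory`, with spec/settings
#'   restored from the sidecar) and `meta`.
#' @export
load_run <- function(dir) {
  traj <- read_trajectory(file.path(dir, "trajectory.lammpsdump"),
    dialect = "lammpsdump"
  )
  cfgfile <- file.path(dir, "config.yaml")
  if (file.exists(cfgfile)) {
    cfg <- read_config(cfgfile)
    traj$spec <- cfg$spec
    traj$settings <- cfg$settings
    traj$schedule <- cfg$schedule
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  list(traj = traj, meta = meta)
}

#' Aggregate a sweep of run directories into a tidy table
#'
#' Scans `parent_dir` for run directories saved with [save_run()],
#' computes the observable summaries, and returns one row per run keyed by
#' (`phi_c`, `hns_uM`, `seed`). The compaction baseline Rg0 is taken from
#' the runs with `phi_c = 0` and no H-NS (averaged when several exist);
#' without such a run and without an explicit `rg0`, aggregation stops
#' with instructions. Runs whose parameter hash differs in anything other
#' than (`phi_c`, `n_hns`, seeds) are refused; duplicated seeds for the
#' same condition are flagged with a warning.
#'
#' @param parent_dir directory containing run subdirectories.
#' @param rg0 optional externally supplied baseline Rg.
#' @return A data frame, one row per run.
#' @export
sweep_report <- function(parent_dir, rg0 = NULL) {
  dirs <- list.dirs(parent_dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (length(dirs) == 0) {
    stop("sweep_report: no run directories with meta.json found")
  }
  runs <- lapply(dirs, load_run)
  specs <- lapply(runs, function(r) r$traj$spec)
  key_invariant <- vapply(specs, function(s) {
    paste(s$n_monomers, s$box_side, s$crowder_diameter,
      s$hns_permeable_to_crowders, s$n_anchored,
      sep = "|"
    )
  }, character(1))
  if (length(unique(key_invariant)) > 1) {
    stop("sweep_report: refusing to mix runs with incompatible system parameters")
  }
  keys <- vapply(seq_along(runs), function(k) {
    s <- specs[[k]]
    paste(s$phi_c, s$n_hns, s$seed, sep = "|")
  }, character(1))
  if (anyDuplicated(keys)) {
    warning("sweep_report: duplicated (phi_c, n_hns, seed) combinations present")
  }
  if (is.null(rg0)) {
    base <- which(vapply(
      specs, function(s) s$phi_c == 0 && s$n_hns == 0, logical(1)
    ))
    if (length(base) == 0) {
      stop(paste0(
        "sweep_report: no baseline run (phi_c = 0, n_hns = 0) found and no ",
        "rg0 given; run the same spec with phi_c = 0 and n_hns = 0 first, ",
        "save it alongside the sweep, or pass rg0 explicitly"
      ))
    }
    rg0 <- mean(vapply(base, function(k) {
      aggregate_observables(runs[[k]]$traj)$summary$mean_rg
    }, numeric(1)))
  }
  rows <- lapply(seq_along(runs), function(k) {
    s <- specs[[k]]
    agg <- aggregate_observables(runs[[k]]$traj, rg0 = rg0)
    sm <- agg$summary
    data.frame(
      run = basename(dirs[k]), phi_c = s$phi_c, n_hns = s$n_hns,
      hns_uM = molar_concentration(s$n_hns, s$box_side * sigma_nm()),
      seed = s$seed,
      rg = sm$mean_rg, se_rg = sm$se_rg,
      rg_ratio = sm$mean_rg_ratio, se_rg_ratio = sm$se_rg_ratio,
      theta = sm$mean_theta, se_theta = sm$se_theta,
      frac_dangling = sm$mean_frac_dangling,
      frac_bridging = sm$mean_frac_bridging,
      mean_cluster_size = sm$mean_cluster_size
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "rg0") <- rg0
  out
}
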