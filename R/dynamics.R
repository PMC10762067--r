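#' Integrator settings
#'
#' Velocity-Verlet integration with an impulse-style Langevin thermostat:
#' each force evaluation adds a friction term \eqn{-(m/\tau_d)\,v} and a
#' Gaussian random force of per-component variance
#' \eqn{2 m k_BT/(\tau_d\,\Delta t)}. With `thermostat = FALSE` the
#' integrator is plain (symplectic) NVE velocity-Verlet.
#'
#' @param dt time step, in \eqn{\tau}.
#' @param temperature thermostat temperature, in \eqn{\epsilon/k_B}.
#' @param damping_time Langevin damping time \eqn{\tau_d}, in \eqn{\tau}.
#' @param thermostat logical; `FALSE` gives NVE dynamics.
#' @param seed integer seed for the thermostat noise stream.
#' @return An object of class `integrator_settings`.
#' @export
integrator_settings <- function(dt = 0.005, temperature = 1.0,
                                damping_time = 1.0, thermostat = TRUE,
                                seed = 1) {
  stopifnot(dt > 0, damping_time > 0, temperature >= 0)
  structure(
    list(
      dt = dt, temperature = temperature, damping_time = damping_time,
      thermostat = isTRUE(thermostat), seed = as.integer(seed)
    ),
    class = "integrator_settings"
  )
}

#' Run schedule
#'
#' Number of equilibration steps (discarded), production steps, and the
#' sampling interval in steps; the interval must divide the production
#' length so the trajectory has a whole number of frames.
#'
#' @param equilibration_steps,production_steps,sample_interval step counts.
#' @return An object of class `run_schedule`.
#' @export
run_schedule <- function(equilibration_steps, production_steps,
                         sample_interval) {
  stopifnot(
    equilibration_steps >= 0, production_steps >= 0, sample_interval > 0,
    production_steps %% sample_interval == 0
  )
  structure(
    list(
      equilibration_steps = as.integer(equilibration_steps),
      production_steps = as.integer(production_steps),
      sample_interval = as.integer(sample_interval)
    ),
    class = "run_schedule"
  )
}

#' Run schedule specified in time units
#'
#' Convenience constructor converting durations in \eqn{\tau} to step
#' counts at the given time step. The full-scale production protocol
#' (5e5 tau equilibration, 5e6 tau production, samples every 25 tau at
#' dt = 0.005) is available as
#' `run_schedule_tau(5e5, 5e6, 25)`.
#'
#' @param equilibration_tau,production_tau,sample_tau durations in
#'   \eqn{\tau}.
#' @param dt time step, in \eqn{\tau}.
#' @return A [run_schedule()].
#' @export
run_schedule_tau <- function(equilibration_tau, production_tau,
                             sample_tau = 25, dt = 0.005) {
  si <- round(sample_tau / dt)
  prod <- round(production_tau / dt)
  prod <- (prod %/% si) * si
  run_schedule(round(equilibration_tau / dt), prod, si)
}

#' Forces and potential energy of a configuration
#'
#' Evaluates the full Hamiltonian gradient: all active nonbonded pairs
#' under the minimum-image convention, FENE ring bonds, the H-NS
#' patch-core bonds and patch-core-patch angles, and any anchor tethers.
#'
#' @param config a `particle_config`.
#' @param table an [interaction_table()].
#' @param bp a [bonded_params()] object.
#' @param method `"all"` (exact all-pairs loop), `"cell"` (cell-list
#'   search) or `"auto"`.
#' @return A list with `forces` (n x 3), total `energy` and the `pair`,
#'   `bond`, `angle` breakdown, all in reduced units.
#' @export
compute_forces <- function(config, table = interaction_table(),
                           bp = bonded_params(),
                           method = c("auto", "all", "cell")) {
  stopifnot(inherits(config, "particle_config"))
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (nrow(config$positions) > 400) "cell" else "all"
  }
  tm <- table_matrices(table)
  top <- topology_matrices(config, bp)
  cpp_compute_forces(
    config$positions, config$species, config$box,
    tm$eps, tm$sig, tm$rcut, tm$act,
    top$bonds, top$angles, bp$hns_kb, method
  )
}

#' Advance a configuration by n steps
#'
#' Low-level propagation of a `particle_config` (positions, velocities,
#' periodic images) by `n_steps` of velocity-Verlet dynamics, optionally
#' recording frames every `sample_every` steps. Used by [run_dynamics()];
#' exposed for energy-conservation and equipartition checks and custom
#' protocols.
#'
#' @param config a `particle_config` with velocities.
#' @param settings an [integrator_settings()].
#' @param n_steps number of steps.
#' @param sample_every sampling stride in steps (0 = keep no frames).
#' @param table,bp interaction and bonded parameters.
#' @param skin neighbour-list skin, in \eqn{\sigma} (default 0.7).
#' @return A list with the updated `config`, the recorded `frames`,
#'   `frame_images`, `times` and `epot` arrays (empty when
#'   `sample_every = 0`), and the run-average kinetic temperature.
#' @export
propagate <- function(config, settings, n_steps, sample_every = 0,
                      table = interaction_table(), bp = bonded_params(),
                      skin = 0.7) {
  stopifnot(inherits(config, "particle_config"),
            inherits(settings, "integrator_settings"))
  tm <- table_matrices(table)
  top <- topology_matrices(config, bp)
  res <- cpp_run_md(
    config$positions, config$velocities, config$images, config$species,
    config$box, tm$eps, tm$sig, tm$rcut, tm$act,
    top$bonds, top$angles, bp$hns_kb,
    settings$dt, settings$temperature, settings$damping_time,
    settings$thermostat, skin, as.integer(n_steps),
    as.integer(sample_every), settings$seed
  )
  config$positions <- res$positions
  config$velocities <- res$velocities
  config$images <- res$images
  list(
    config = config, frames = res$frames, frame_images = res$frame_images,
    times = res$times, epot = res$epot, ekin = res$ekin,
    mean_kinetic_temperature = res$mean_kinetic_temperature
  )
}

#' Run a full simulation
#'
#' Assembles the system (unless an assembled `particle_config` is given),
#' runs the equilibration phase, then the production phase, collecting
#' frames every `sample_interval` steps. Frames carry wrapped positions
#' plus per-particle image counters so observables can unwrap the ring
#' across periodic boundaries.
#'
#' @param spec a [system_spec()], or an already assembled
#'   `particle_config`.
#' @param settings an [integrator_settings()]; its seed (combined with the
#'   spec seed) drives the thermostat noise.
#' @param schedule a [run_schedule()].
#' @param table an [interaction_table()]; defaults to the `"N200"` table
#'   with the spec's permeability flag.
#' @param bp a [bonded_params()] object.
#' @return An object of class `md_trajectory`: frame array
#'   (`[frame, particle, xyz]`), image counters, time stamps, potential
#'   energies, topology and metadata.
#' @examples
#' \donttest{
#' traj <- run_dynamics(
#'   system_spec(n_monomers = 20, box_side = 15, n_hns = 2, seed = 4),
#'   integrator_settings(seed = 4),
#'   run_schedule(1000, 5000, 500)
#' )
#' n_frames(traj)
#' }
#' @export
run_dynamics <- function(spec, settings = integrator_settings(),
                         schedule = run_schedule_tau(100, 500, 25),
                         table = NULL, bp = bonded_params()) {
  if (inherits(spec, "system_spec")) {
    if (is.null(table)) {
      table <- interaction_table(
        permeable_hns = spec$hns_permeable_to_crowders
      )
    }
    config <- assemble_system(spec, table, bp,
      temperature = settings$temperature
    )
  } else {
    stopifnot(inherits(spec, "particle_config"))
    config <- spec
    spec <- config$spec
    if (is.null(table)) {
      table <- interaction_table(
        permeable_hns = isTRUE(spec$hns_permeable_to_crowders)
      )
    }
  }
  base_seed <- settings$seed
  eq_settings <- settings
  eq_settings$seed <- base_seed
  state <- config
  if (schedule$equilibration_steps > 0) {
    eq <- propagate(state, eq_settings, schedule$equilibration_steps,
      sample_every = 0, table = table, bp = bp
    )
    state <- eq$config
  }
  pr_settings <- settings
  pr_settings$seed <- base_seed + 1000003L
  pr <- propagate(state, pr_settings, schedule$production_steps,
    sample_every = schedule$sample_interval, table = table, bp = bp
  )
  t0 <- schedule$equilibration_steps * settings$dt
  structure(
    list(
      frames = pr$frames, frame_images = pr$frame_images,
      times = pr$times + t0, epot = pr$epot,
      box = config$box, species = config$species,
      molecule = config$molecule, bonds = config$bonds,
      angles = config$angles, n_monomers = config$n_monomers,
      spec = spec, settings = settings, schedule = schedule,
      mean_kinetic_temperature = pr$mean_kinetic_temperature,
      final = pr$config
    ),
    class = "md_trajectory"
  )
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(traj$frames) == 0) {
    return(0L)
  }
  dim(traj$frames)[1]
}

#' Extract one frame as a particle configuration
#' @param traj an `md_trajectory`.
#' @param k frame index.
#' @return A `particle_config` with that frame's positions and images.
#' @export
get_frame <- function(traj, k) {
  stopifnot(inherits(traj, "md_trajectory"), k >= 1, k <= n_frames(traj))
  n <- length(traj$species)
  pos <- matrix(traj$frames[k, , ], n, 3)
  img <- matrix(traj$frame_images[k, , ], n, 3)
  new_particle_config(
    positions = pos, species = traj$species, molecule = traj$molecule,
    bonds = traj$bonds, angles = traj$angles, box = traj$box,
    n_monomers = traj$n_monomers, images = img, spec = traj$spec
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "md_trajectory: %d frames x %d particles, box %g sigma, t = %g..%g tau\n",
    n_frames(x), length(x$species), x$box,
    if (n_frames(x) > 0) min(x$times) else NA,
    if (n_frames(x) > 0) max(x$times) else NA
  ))
  if (!is.null(x$mean_kinetic_temperature)) {
    cat(sprintf(
      "  mean kinetic temperature %.4f\n", x$mean_kinetic_temperature
    ))
  }
  invisible(x)
}
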