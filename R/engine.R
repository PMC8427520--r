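#' Run Langevin dynamics on a toy system
#'
#' Integrates the system with a BAOAB-split Langevin integrator at the
#' system's temperature and friction.  Receptor beads are held fixed unless
#' the system configures a receptor restraint.  Runs are bit-reproducible
#' for a fixed seed.
#'
#' @param system a `ToySystem`
#' @param state starting `Frame` (defaults to the system's initial frame;
#'   `NULL` velocities are treated as zero)
#' @param duration simulated time, ps; must be an integer multiple of
#'   `save_interval`
#' @param save_interval spacing of saved frames, ps; must be an integer
#'   multiple of the system timestep
#' @param seed RNG seed for the thermostat noise
#' @param hills optional data frame with columns `center`, `height`
#'   (Angstrom, kcal/mol) describing a fixed metadynamics bias on the
#'   ligand-to-site distance, with Gaussian width `hill_sigma`; used
#'   internally by [run_metadynamics()]
#' @param hill_sigma Gaussian hill width, Angstrom
#' @return a `Trajectory` with `duration/save_interval` frames (the starting
#'   state is not repeated), saved velocities, and provenance metadata.
#' @export
langevin_run <- function(system, state = initial_frame(system), duration,
                         save_interval, seed = 1,
                         hills = NULL, hill_sigma = 0.1) {
  stopifnot(inherits(system, "ToySystem"))
  check_number(duration, "duration", positive = TRUE)
  check_number(save_interval, "save_interval", positive = TRUE)
  n_save <- check_commensurate(duration, save_interval, "duration", "save_interval")
  save_every <- check_commensurate(save_interval, system$timestep,
                                   "save_interval", "timestep")
  nsteps <- n_save * save_every

  n <- nrow(system$beads)
  if (!all(dim(state$coords) == c(n, 3)))
    stop_validation("state is inconsistent with the system bead count", "state")
  vel <- state$velocities %||% matrix(0, n, 3)

  roles <- match(system$beads$role, c("ligand", "receptor", "solvent")) - 1L
  hc <- if (is.null(hills)) numeric(0) else as.numeric(hills$center)
  hh <- if (is.null(hills)) numeric(0) else as.numeric(hills$height)

  set.seed(seed)
  res <- cpp_langevin_chunk(
    coords = state$coords, vels = vel,
    mass = system$beads$mass, roles = roles,
    mobile = mobile_flags(system), pot = pot_for_engine(system),
    dt = system$timestep, temperature = system$temperature,
    friction = system$friction, nsteps = nsteps, save_every = save_every,
    hill_centers = hc, hill_heights = hh, hill_sigma = hill_sigma)

  times <- state$time + save_interval * seq_len(n_save)
  make_trajectory(
    times = times, coords = res$saved_coords, velocities = res$saved_velocities,
    window_id = rep(state$window_id, n_save),
    metadata = list(engine = "langevin_baoab", seed = seed,
                    save_interval = save_interval,
                    timestep = system$timestep))
}

# single integration call that only returns the final state (no frame
# storage); used by the metadynamics driver between hill depositions
langevin_step_raw <- function(system, coords, vel, nsteps,
                              hills = NULL, hill_sigma = 0.1) {
  roles <- match(system$beads$role, c("ligand", "receptor", "solvent")) - 1L
  hc <- if (is.null(hills)) numeric(0) else as.numeric(hills$center)
  hh <- if (is.null(hills)) numeric(0) else as.numeric(hills$height)
  cpp_langevin_chunk(
    coords = coords, vels = vel,
    mass = system$beads$mass, roles = roles,
    mobile = mobile_flags(system), pot = pot_for_engine(system),
    dt = system$timestep, temperature = system$temperature,
    friction = system$friction, nsteps = nsteps, save_every = 0L,
    hill_centers = hc, hill_heights = hh, hill_sigma = hill_sigma)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Replaces the velocities of a frame with fresh draws from the
#' Maxwell-Boltzmann distribution at the given temperature (each Cartesian
#' component is normal with variance kB*T/m).  Coordinates are untouched.
#' This is the velocity randomisation applied when a supervised window is
#' rejected and the simulation restarts from the last accepted state.
#'
#' @param state a `Frame`
#' @param temperature temperature in K (0 gives exactly zero velocities)
#' @param masses per-bead masses in amu
#' @param seed RNG seed
#' @return the frame with new velocities.
#' @export
resample_velocities <- function(state, temperature, masses, seed = 1) {
  n <- nrow(state$coords)
  if (length(masses) == 1) masses <- rep(masses, n)
  if (length(masses) != n)
    stop_validation("masses must have one entry per bead", "masses")
  if (any(masses <= 0)) stop_validation("masses must be positive", "masses")
  check_number(temperature, "temperature", nonneg = TRUE)
  set.seed(seed)
  sd <- sqrt(.kB_vel * temperature / masses)
  state$velocities <- matrix(rnorm(3 * n, sd = rep(sd, 3)), n, 3)
  state
}
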