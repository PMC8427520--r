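#' Bin trajectory frames by ligand RMSD to the start
#'
#' Path-sampling preprocessing: every frame is aligned to the first frame
#' on an alignment selection (the receptor scaffold, the analogue of the
#' protein alpha carbons), the ligand RMSD to its starting position is
#' computed, and frames are assigned to half-open bins
#' `[k*width, (k+1)*width)`.
#'
#' @param traj a `Trajectory`
#' @param system the `ToySystem` the trajectory belongs to (supplies the
#'   default selections)
#' @param bin_width RMSD bin width, Angstrom (default 1)
#' @param ligand integer indices of the ligand selection (default: all
#'   ligand beads)
#' @param align integer indices of the alignment selection (default: all
#'   receptor beads)
#' @return an object of class `RmsdBinning` with the per-frame RMSD values
#'   and a `bins` map from bin index (as character) to frame ids.
#' @export
bin_frames_by_rmsd <- function(traj, system, bin_width = 1,
                               ligand = ligand_indices(system),
                               align = receptor_indices(system)) {
  stopifnot(inherits(traj, "Trajectory"))
  check_number(bin_width, "bin_width", positive = TRUE)
  if (length(ligand) == 0) stop_validation("empty ligand selection", "ligand")
  if (length(align) == 0) stop_validation("empty alignment selection", "align")
  nf <- n_frames(traj)
  ref <- traj$coords[1, , , drop = TRUE]
  ref <- matrix(ref, ncol = 3)

  rmsd_vals <- vapply(seq_len(nf), function(i) {
    xyz <- matrix(traj$coords[i, , , drop = TRUE], ncol = 3)
    fit <- superpose(xyz[align, , drop = FALSE], ref[align, , drop = FALSE])
    moved <- apply_transform(xyz, fit)
    rmsd(moved[ligand, , drop = FALSE], ref[ligand, , drop = FALSE])
  }, numeric(1))

  idx <- floor(rmsd_vals / bin_width)
  bins <- split(seq_len(nf), idx)
  structure(list(reference = 1L, bin_width = bin_width, rmsd = rmsd_vals,
                 bins = bins),
            class = "RmsdBinning")
}

#' @export
print.RmsdBinning <- function(x, ...) {
  cat(sprintf("RmsdBinning: %d frames in %d bins of %g Angstrom\n",
              length(x$rmsd), length(x$bins), x$bin_width))
  invisible(x)
}

#' Seed unsupervised runs from RMSD bins
#'
#' Draws one frame uniformly at random from every non-empty RMSD bin and
#' launches an unsupervised run of `run_length` ps from each, with
#' velocities resampled at the system temperature.  This relaxes the
#' supervision bias of an adaptive trajectory: downstream analyses operate
#' on these unsupervised continuations only.
#'
#' @param binning an `RmsdBinning` built from `traj`
#' @param traj the binned `Trajectory`
#' @param system the `ToySystem`
#' @param run_length length of each unsupervised run, ps
#' @param save_interval frame saving interval, ps (default 50)
#' @param seed root RNG seed (frame draws and run seeds derive from it)
#' @param engine dynamics engine (default [langevin_run()])
#' @return list of `Trajectory`, one per non-empty bin, each starting at
#'   the drawn frame's coordinates (time reset to 0); the selection
#'   manifest is in `attr(, "manifest")`.
#' @export
seed_path_sampling <- function(binning, traj, system, run_length,
                               save_interval = 50, seed = 1,
                               engine = langevin_run) {
  stopifnot(inherits(binning, "RmsdBinning"), inherits(traj, "Trajectory"))
  check_number(run_length, "run_length", positive = TRUE)
  check_commensurate(run_length, save_interval, "run_length", "save_interval")
  bins <- binning$bins
  nb <- length(bins)
  set.seed(seed)
  picks <- vapply(bins, function(ids) ids[sample.int(length(ids), 1)], integer(1))
  run_seeds <- sample.int(2147483646L, nb)
  vel_seeds <- sample.int(2147483646L, nb)

  out <- vector("list", nb)
  manifest <- data.frame(bin = names(bins), source_frame = picks,
                         seed = run_seeds, row.names = NULL)
  for (b in seq_len(nb)) {
    src <- get_frame(traj, picks[b])
    state <- make_frame(time = 0, coords = src$coords)
    state <- resample_velocities(state, system$temperature,
                                 system$beads$mass, seed = vel_seeds[b])
    run <- engine(system, state, run_length, save_interval,
                  seed = run_seeds[b])
    # prepend the seeding frame so each path starts at its source coordinates
    start_piece <- make_trajectory(
      times = 0, coords = array(state$coords, c(1, nrow(state$coords), 3)),
      velocities = if (!is.null(run$velocities))
        array(state$velocities, c(1, nrow(state$coords), 3)) else NULL)
    out[[b]] <- concat_trajectories(
      list(start_piece, run),
      metadata = list(engine = "path_sampling", bin = names(bins)[b],
                      source_frame = picks[b], seed = run_seeds[b]))
  }
  attr(out, "manifest") <- manifest
  out
}
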