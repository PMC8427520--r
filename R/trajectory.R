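#' Construct a single trajectory frame
#'
#' @param time time stamp in ps (non-negative)
#' @param coords N x 3 coordinate matrix, Angstrom
#' @param velocities optional N x 3 velocity matrix, Angstrom/ps
#' @param window_id provenance tag: id of the SuMD window that produced the
#'   frame (`NA` outside supervised runs)
#' @return an object of class `Frame`.
#' @export
make_frame <- function(time, coords, velocities = NULL, window_id = NA_integer_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop_validation("coords must be an N x 3 matrix", "coords")
  if (!is.numeric(time) || length(time) != 1 || time < 0)
    stop_validation("time must be a single non-negative number", "time")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(coords)))
      stop_validation("velocities must match coords in shape", "velocities")
  }
  structure(list(time = time, coords = coords, velocities = velocities,
                 window_id = window_id), class = "Frame")
}

#' @export
print.Frame <- function(x, ...) {
  cat(sprintf("Frame: t = %g ps, %d beads%s%s\n", x$time, nrow(x$coords),
              if (is.null(x$velocities)) "" else ", with velocities",
              if (is.na(x$window_id)) "" else sprintf(", window %d", x$window_id)))
  invisible(x)
}

#' Construct a trajectory
#'
#' Frames are stored column-major as arrays (`n_frames x n_beads x 3`) for
#' fast analysis; [get_frame()] extracts individual `Frame` objects.
#'
#' @param times numeric vector of frame times, ps, strictly increasing
#' @param coords array of dimension `(n_frames, n_beads, 3)`, Angstrom
#' @param velocities optional array of the same shape, Angstrom/ps
#' @param window_id integer vector of per-frame provenance tags
#' @param metadata named list (engine name, seed, config hash, ...)
#' @return an object of class `Trajectory`.
#' @export
make_trajectory <- function(times, coords, velocities = NULL,
                            window_id = NULL, metadata = list()) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop_validation("coords must be an (n_frames, n_beads, 3) array", "coords")
  nf <- dim(coords)[1]
  if (nf == 0) stop_validation("trajectory must contain at least one frame")
  if (length(times) != nf)
    stop_validation("times length must equal the number of frames", "times")
  if (any(diff(times) <= 0))
    stop_validation("frame times must be strictly increasing", "times")
  if (any(times < 0)) stop_validation("frame times must be non-negative", "times")
  if (!is.null(velocities) && !all(dim(velocities) == dim(coords)))
    stop_validation("velocities must match coords in shape", "velocities")
  window_id <- window_id %||% rep(NA_integer_, nf)
  structure(list(times = times, coords = coords, velocities = velocities,
                 window_id = as.integer(window_id), metadata = metadata),
            class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame from a trajectory
#'
#' @param traj a `Trajectory`
#' @param i frame index (1-based)
#' @return a `Frame`.
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1 || i > nf) stop_validation(sprintf("frame index %d out of 1..%d", i, nf))
  make_frame(time = traj$times[i],
             coords = traj$coords[i, , , drop = TRUE],
             velocities = if (!is.null(traj$velocities))
               traj$velocities[i, , , drop = TRUE] else NULL,
             window_id = traj$window_id[i])
}

#' @export
print.Trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf("Trajectory: %d frames, %d beads, t = %g .. %g ps\n",
              nf, dim(x$coords)[2], x$times[1], x$times[nf]))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

# concatenate trajectories (times must keep increasing across pieces)
concat_trajectories <- function(pieces, metadata = list()) {
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) return(NULL)
  if (length(pieces) == 1) {
    out <- pieces[[1]]
    out$metadata <- utils::modifyList(out$metadata, metadata)
    return(out)
  }
  nfs <- vapply(pieces, n_frames, integer(1))
  nb <- dim(pieces[[1]]$coords)[2]
  total <- sum(nfs)
  coords <- array(0, c(total, nb, 3))
  has_vel <- all(vapply(pieces, function(p) !is.null(p$velocities), logical(1)))
  vel <- if (has_vel) array(0, c(total, nb, 3)) else NULL
  times <- numeric(total)
  wid <- integer(total)
  at <- 0L
  for (p in pieces) {
    idx <- at + seq_len(n_frames(p))
    coords[idx, , ] <- p$coords
    if (has_vel) vel[idx, , ] <- p$velocities
    times[idx] <- p$times
    wid[idx] <- p$window_id
    at <- at + n_frames(p)
  }
  make_trajectory(times, coords, vel, wid, metadata)
}

# per-frame evaluation of a metric function(frame) -> scalar
eval_metric_series <- function(traj, fn) {
  vapply(seq_len(n_frames(traj)), function(i) fn(get_frame(traj, i)), numeric(1))
}
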