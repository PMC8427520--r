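#' Write a trajectory as extended XYZ
#'
#' Each frame is an atom-count line, a comment line carrying `time=<ps>`
#' and `window=<id>` (plus any scalar metadata on the first frame), then
#' one `element x y z` line per bead.  Coordinates are written with six
#' decimals, so a round trip reproduces them to 1e-6 Angstrom.
#'
#' @param traj a `Trajectory`
#' @param path output file
#' @param elements per-bead element labels (default: taken from
#'   `traj$metadata$elements`, else `"X"`)
#' @return the path, invisibly.
#' @export
write_xyz <- function(traj, path, elements = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  nb <- dim(traj$coords)[2]
  elements <- elements %||% traj$metadata$elements %||% rep("X", nb)
  if (length(elements) != nb)
    stop_validation("elements must have one entry per bead", "elements")
  con <- file(path, "w")
  on.exit(close(con))
  meta <- traj$metadata
  scal <- meta[vapply(meta, function(m)
    is.atomic(m) && length(m) == 1 && !is.na(m), logical(1))]
  scal <- scal[setdiff(names(scal), c("elements"))]
  for (i in seq_len(n_frames(traj))) {
    wid <- traj$window_id[i]
    comment <- sprintf("time=%.6f window=%s", traj$times[i],
                       if (is.na(wid)) "NA" else as.character(wid))
    if (i == 1 && length(scal) > 0)
      comment <- paste(comment, paste(sprintf("%s=%s", names(scal),
                                              vapply(scal, format, character(1))),
                                      collapse = " "))
    xyz <- matrix(traj$coords[i, , , drop = TRUE], ncol = 3)
    writeLines(c(as.character(nb), comment,
                 sprintf("%s %.6f %.6f %.6f", elements,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_xyz()].  Malformed count or coordinate lines raise a
#' parse error naming the offending frame and line; an empty file is an
#' error, not an empty trajectory.
#'
#' @param path file to read
#' @return a `Trajectory` (no velocities); bead element labels are kept in
#'   `metadata$elements`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  # drop trailing blank lines only
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0)
    stop_validation(sprintf("no frames in '%s'", path))

  frames <- list()
  at <- 1L
  fr <- 0L
  elements <- NULL
  while (at <= length(lines)) {
    fr <- fr + 1L
    nb <- suppressWarnings(as.integer(trimws(lines[at])))
    if (is.na(nb) || nb <= 0)
      stop_validation(sprintf(
        "parse error in frame %d: expected atom count at line %d, got '%s'",
        fr, at, lines[at]))
    if (at + 1L > length(lines))
      stop_validation(sprintf("parse error: frame %d has no comment line", fr))
    comment <- lines[at + 1L]
    tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) < 2)
      stop_validation(sprintf(
        "parse error in frame %d: comment line %d lacks 'time='", fr, at + 1L))
    wd <- regmatches(comment, regexec("window=([-0-9A-Za-z]+)", comment))[[1]]
    wid <- if (length(wd) >= 2) suppressWarnings(as.integer(wd[2])) else NA_integer_

    last <- at + 1L + nb
    if (last > length(lines))
      stop_validation(sprintf(
        "parse error in frame %d: expected %d atom lines, file truncated",
        fr, nb))
    block <- strsplit(trimws(lines[(at + 2L):last]), "\\s+")
    nfield <- lengths(block)
    if (any(nfield < 4))
      stop_validation(sprintf(
        "parse error in frame %d: malformed atom line %d",
        fr, at + 1L + which(nfield < 4)[1]))
    el <- vapply(block, `[`, character(1), 1)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(block, `[`, 2:4)))), ncol = 3, byrow = TRUE)
    if (any(is.na(xyz)))
      stop_validation(sprintf(
        "parse error in frame %d: non-numeric coordinates", fr))
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop_validation(sprintf(
        "parse error in frame %d: atom count %d differs from frame 1 (%d)",
        fr, length(el), length(elements)))
    frames[[fr]] <- list(time = as.numeric(tm[2]), window = wid, xyz = xyz)
    at <- last + 1L
  }

  nf <- length(frames)
  nb <- nrow(frames[[1]]$xyz)
  coords <- array(0, c(nf, nb, 3))
  for (i in seq_len(nf)) coords[i, , ] <- frames[[i]]$xyz
  make_trajectory(
    times = vapply(frames, `[[`, numeric(1), "time"),
    coords = coords,
    window_id = vapply(frames, `[[`, integer(1), "window"),
    metadata = list(elements = elements, source = path))
}

role_to_resid <- c(ligand = "LIG", receptor = "REC", solvent = "SOL")

#' Write a toy-system topology as PDB
#'
#' Beads become HETATM records with the role as residue name (LIG/REC/SOL),
#' one residue per bead; occupancy and B-factor columns are left standard.
#'
#' @param system a `ToySystem`
#' @param path output file
#' @return the path, invisibly.
#' @export
write_pdb_topology <- function(system, path) {
  stopifnot(inherits(system, "ToySystem"))
  n <- nrow(system$beads)
  xyz <- as.vector(t(system_coords(system)))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("HETATM", n),
    resno = seq_len(n),
    resid = unname(role_to_resid[system$beads$role]),
    eleno = seq_len(n),
    elety = rep("C", n),
    chain = rep("A", n))
  invisible(path)
}

#' Read a toy topology from PDB
#'
#' @param path PDB file written by [write_pdb_topology()]
#' @return data frame with `id`, `role`, `x`, `y`, `z` per bead.
#' @export
read_pdb_topology <- function(path) {
  pdb <- bio3d::read.pdb(path)
  resid <- pdb$atom$resid
  role <- names(role_to_resid)[match(resid, role_to_resid)]
  if (any(is.na(role)))
    stop_validation(sprintf("unknown residue names in '%s': %s", path,
                            paste(unique(resid[is.na(role)]), collapse = ", ")))
  data.frame(id = as.character(seq_along(role)), role = role,
             x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z,
             stringsAsFactors = FALSE)
}

# element labels used in XYZ output, one letter per role
role_elements <- function(system) {
  c(ligand = "L", receptor = "R", solvent = "S")[system$beads$role]
}
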