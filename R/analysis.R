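#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between a
#' mobile and a reference coordinate set over a selection, by singular value
#' decomposition of the cross-covariance matrix with the usual determinant
#' correction against reflections.
#'
#' @param mobile N x 3 coordinate matrix to move
#' @param reference N x 3 coordinate matrix to match
#' @param selection optional integer indices of the rows used for the fit
#'   (default: all rows); at least 3 non-collinear points
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   such that `x %*% t(rotation) + translation` maps mobile onto
#'   reference, and `rmsd` over the selection after fitting.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  sel <- selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3)
    stop_validation("superposition needs at least 3 points", "selection")
  p <- mobile[sel, , drop = FALSE]
  q <- reference[sel, , drop = FALSE]
  if (nrow(p) != nrow(q))
    stop_validation("mobile and reference selections differ in length")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  if (qr(pc)$rank < 2 || qr(qc)$rank < 2)
    stop_validation("degenerate (collinear) selection", "selection")
  a <- crossprod(pc, qc)              # sum_i p_i q_i^T
  sv <- svd(a)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cq - rot %*% cp)
  moved <- pc %*% t(rot)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - qc)^2))))
}

#' Apply a superposition transform to coordinates
#'
#' @param coords N x 3 matrix
#' @param fit result of [superpose()]
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, -fit$translation)
}

#' Root-mean-square deviation between coordinate sets
#'
#' @param coords N x 3 matrix
#' @param reference N x 3 matrix
#' @param selection optional indices over which the deviation is computed
#' @param fit superpose before measuring? (default `FALSE`)
#' @param fit_selection selection used for the superposition when `fit` is
#'   `TRUE` (default: same as `selection`)
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords, reference, selection = NULL, fit = FALSE,
                 fit_selection = NULL) {
  coords <- as.matrix(coords); reference <- as.matrix(reference)
  if (!all(dim(coords) == dim(reference)))
    stop_validation("coords and reference differ in shape")
  sel <- selection %||% seq_len(nrow(coords))
  if (fit) {
    fs <- fit_selection %||% sel
    coords <- apply_transform(coords, superpose(coords, reference, fs))
  }
  d <- coords[sel, , drop = FALSE] - reference[sel, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Detect interatomic contacts between two groups
#'
#' A contact is productive when the distance between two atoms is strictly
#' less than the cutoff (default 3.5 Angstrom).
#'
#' @param coords N x 3 coordinate matrix (a frame)
#' @param groupA,groupB disjoint integer index vectors
#' @param cutoff contact distance, Angstrom
#' @return data frame with columns `i` (from groupA), `j` (from groupB) and
#'   `distance`; zero rows when no contact.
#' @export
detect_contacts <- function(coords, groupA, groupB, cutoff = 3.5) {
  coords <- as.matrix(coords)
  if (length(intersect(groupA, groupB)) > 0)
    stop_validation("groups must be disjoint")
  if (length(groupA) == 0 || length(groupB) == 0)
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  d <- cross_distances(coords[groupA, , drop = FALSE],
                       coords[groupB, , drop = FALSE])
  hit <- which(d < cutoff, arr.ind = TRUE)
  data.frame(i = groupA[hit[, 1]], j = groupB[hit[, 2]],
             distance = d[hit])
}

#' Geometric hydrogen-bond criteria
#'
#' @param distance donor-acceptor distance cutoff, Angstrom (default 3.5,
#'   boundary included)
#' @param angle minimum D-H...A angle at the hydrogen, degrees (default
#'   120, boundary included)
#' @return an object of class `HBondCriteria`.
#' @export
hbond_criteria <- function(distance = 3.5, angle = 120) {
  check_number(distance, "distance", positive = TRUE)
  check_number(angle, "angle", positive = TRUE)
  if (angle > 180) stop_validation("angle cutoff must be <= 180", "angle")
  structure(list(distance = distance, angle = angle), class = "HBondCriteria")
}

#' Detect hydrogen bonds by geometric criteria
#'
#' A donor-hydrogen-acceptor triple qualifies when the donor-acceptor
#' distance is within the cutoff and the D-H...A angle (measured at the
#' hydrogen) is at least the angular cutoff.
#'
#' @param coords N x 3 coordinate matrix
#' @param donor_h two-column matrix or data frame mapping each hydrogen to
#'   its covalently bound donor: columns `donor`, `hydrogen` (atom indices)
#' @param acceptors integer indices of acceptor atoms
#' @param criteria an [hbond_criteria()]
#' @return data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance` (D...A) and `angle` (degrees).
#' @export
detect_hbonds <- function(coords, donor_h, acceptors,
                          criteria = hbond_criteria()) {
  coords <- as.matrix(coords)
  donor_h <- as.data.frame(donor_h)
  if (!all(c("donor", "hydrogen") %in% names(donor_h)))
    stop_validation("donor_h must have columns 'donor' and 'hydrogen'", "donor_h")
  if (any(is.na(donor_h$donor)))
    stop_validation("hydrogen with no attached donor", "donor_h")
  n <- nrow(coords)
  if (any(donor_h$donor < 1 | donor_h$donor > n) ||
      any(donor_h$hydrogen < 1 | donor_h$hydrogen > n))
    stop_validation("donor/hydrogen index out of range", "donor_h")

  out <- list()
  for (r in seq_len(nrow(donor_h))) {
    d <- donor_h$donor[r]; h <- donor_h$hydrogen[r]
    for (a in setdiff(acceptors, d)) {
      da <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (da > criteria$distance) next
      u <- coords[d, ] - coords[h, ]
      v <- coords[a, ] - coords[h, ]
      cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= criteria$angle)
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = h, acceptor = a, distance = da, angle = ang)
    }
  }
  if (length(out) == 0)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  do.call(rbind, out)
}

#' Interaction persistency over merged replicas
#'
#' For each interaction partner, the percentage of frames -- pooled over
#' all supplied replicas -- in which at least one qualifying interaction is
#' present.
#'
#' @param trajectories a `Trajectory` or list of `Trajectory` replicas
#'   sharing a topology
#' @param extractor `function(frame)` returning the ids (bead indices,
#'   residue names, ...) interacting in that frame
#' @param ids optional vector of ids to always report (with 0% when never
#'   seen)
#' @param type label for the interaction type column (default "contact")
#' @return a `PersistencyTable` data frame: `id`, `type`, `percent`,
#'   `n_frames_total`.
#' @export
persistency <- function(trajectories, extractor, ids = NULL,
                        type = "contact") {
  if (inherits(trajectories, "Trajectory")) trajectories <- list(trajectories)
  nb <- vapply(trajectories, function(tr) dim(tr$coords)[2], integer(1))
  if (length(unique(nb)) != 1)
    stop_validation("replicas disagree on bead count (topology mismatch)")
  total <- 0L
  counts <- list()
  for (tr in trajectories) {
    for (i in seq_len(n_frames(tr))) {
      total <- total + 1L
      hit <- unique(extractor(get_frame(tr, i)))
      for (h in as.character(hit))
        counts[[h]] <- (counts[[h]] %||% 0L) + 1L
    }
  }
  all_ids <- union(as.character(ids %||% character(0)), names(counts))
  if (length(all_ids) == 0)
    return(structure(data.frame(id = character(0), type = character(0),
                                percent = numeric(0),
                                n_frames_total = integer(0)),
                     class = c("PersistencyTable", "data.frame")))
  pct <- vapply(all_ids, function(h) 100 * (counts[[h]] %||% 0L) / total,
                numeric(1))
  out <- data.frame(id = all_ids, type = type, percent = as.numeric(pct),
                    n_frames_total = total, row.names = NULL)
  out <- out[order(-out$percent, out$id), ]
  rownames(out) <- NULL
  structure(out, class = c("PersistencyTable", "data.frame"))
}

#' Voxelised solvent occupancy map
#'
#' AquaMMapS-style hydration map: the simulation region is divided into
#' cubic voxels and each voxel scores the fraction of frames (pooled over
#' replicas) in which at least one solvent bead lies inside it.  Frames can
#' optionally be aligned to the first frame on a selection first.
#'
#' @param trajectories a `Trajectory` or list of replicas
#' @param solvent integer indices of the solvent beads
#' @param lower,upper length-3 numeric bounds of the mapped region,
#'   Angstrom
#' @param spacing voxel edge, Angstrom (default 1)
#' @param align optional integer selection for pre-alignment of every frame
#'   to the first frame
#' @return an object of class `OccupancyGrid`: `origin`, `spacing`, `dim`,
#'   `occupancy` (3D array of per-voxel fractions between 0 and 1) and
#'   `n_frames`.
#' @export
water_occupancy <- function(trajectories, solvent, lower, upper, spacing = 1,
                            align = NULL) {
  if (inherits(trajectories, "Trajectory")) trajectories <- list(trajectories)
  check_number(spacing, "spacing", positive = TRUE)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3 || length(upper) != 3 || any(upper <= lower))
    stop_validation("region must have positive extent in all dimensions",
                    "region")
  dims <- pmax(ceiling((upper - lower) / spacing), 1)
  counts <- array(0L, dims)
  ref <- NULL
  total <- 0L
  for (tr in trajectories) {
    for (i in seq_len(n_frames(tr))) {
      xyz <- matrix(tr$coords[i, , , drop = TRUE], ncol = 3)
      if (!is.null(align)) {
        if (is.null(ref)) ref <- xyz
        else xyz <- apply_transform(xyz, superpose(xyz, ref, align))
      }
      total <- total + 1L
      sol <- xyz[solvent, , drop = FALSE]
      ix <- floor(sweep(sol, 2, lower) / spacing) + 1
      ok <- ix[, 1] >= 1 & ix[, 1] <= dims[1] &
            ix[, 2] >= 1 & ix[, 2] <= dims[2] &
            ix[, 3] >= 1 & ix[, 3] <= dims[3]
      ix <- unique(ix[ok, , drop = FALSE])
      if (nrow(ix) > 0) counts[ix] <- counts[ix] + 1L
    }
  }
  structure(list(origin = lower, spacing = spacing, dim = dims,
                 occupancy = counts / total, n_frames = total),
            class = "OccupancyGrid")
}

#' Hydrated spots above an occupancy threshold
#'
#' @param grid an `OccupancyGrid`
#' @param threshold minimum occupancy fraction (default 0.5)
#' @return data frame of voxel indices, voxel-centre coordinates and
#'   occupancies, ordered by decreasing occupancy.
#' @export
hydrated_spots <- function(grid, threshold = 0.5) {
  stopifnot(inherits(grid, "OccupancyGrid"))
  hit <- which(grid$occupancy >= threshold, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(ix = integer(0), iy = integer(0), iz = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      occupancy = numeric(0)))
  occ <- grid$occupancy[hit]
  out <- data.frame(
    ix = hit[, 1], iy = hit[, 2], iz = hit[, 3],
    x = grid$origin[1] + (hit[, 1] - 0.5) * grid$spacing,
    y = grid$origin[2] + (hit[, 2] - 0.5) * grid$spacing,
    z = grid$origin[3] + (hit[, 3] - 0.5) * grid$spacing,
    occupancy = occ)
  out[order(-out$occupancy), ]
}

#' Two-variable interaction-energy landscape
#'
#' Bins frames on two collective-variable series, reporting per-bin frame
#' counts, mean interaction energy, and an occupancy-derived depth
#' `-kB T log(count/total)` (the "energy landscape" rendering; the global
#' minimum of the depth is 0 when all frames share one bin).  Empty bins
#' are `NA`, not zero.
#'
#' @param cv1,cv2 numeric series of equal length (one value per frame)
#' @param energy interaction-energy series, kcal/mol, same length
#' @param bin_width length-2 numeric bin widths for (cv1, cv2)
#' @param temperature temperature for the depth scale, K
#' @return an object of class `LandscapeMap` with bin edges and `counts`,
#'   `mean_energy`, `depth` matrices.
#' @export
energy_landscape <- function(cv1, cv2, energy, bin_width = c(1, 1),
                             temperature = 300) {
  nfr <- length(cv1)
  if (length(cv2) != nfr || length(energy) != nfr)
    stop_validation("cv1, cv2 and energy must have equal length")
  if (nfr == 0) stop_validation("empty series")
  bin_width <- rep(bin_width, length.out = 2)
  o1 <- floor(min(cv1) / bin_width[1]) * bin_width[1]
  o2 <- floor(min(cv2) / bin_width[2]) * bin_width[2]
  i1 <- floor((cv1 - o1) / bin_width[1]) + 1
  i2 <- floor((cv2 - o2) / bin_width[2]) + 1
  n1 <- max(i1); n2 <- max(i2)
  counts <- matrix(0L, n1, n2)
  esum <- matrix(0, n1, n2)
  for (f in seq_len(nfr)) {
    counts[i1[f], i2[f]] <- counts[i1[f], i2[f]] + 1L
    esum[i1[f], i2[f]] <- esum[i1[f], i2[f]] + energy[f]
  }
  mean_e <- ifelse(counts > 0, esum / pmax(counts, 1L), NA_real_)
  depth <- ifelse(counts > 0, -.kB * temperature * log(counts / nfr), NA_real_)
  structure(list(
    cv1_breaks = o1 + bin_width[1] * (0:n1),
    cv2_breaks = o2 + bin_width[2] * (0:n2),
    counts = counts, mean_energy = mean_e, depth = depth,
    total = nfr, temperature = temperature),
    class = "LandscapeMap")
}

#' @export
print.LandscapeMap <- function(x, ...) {
  cat(sprintf("LandscapeMap: %d x %d bins, %d frames, %d occupied\n",
              nrow(x$counts), ncol(x$counts), x$total, sum(x$counts > 0)))
  invisible(x)
}

#' Write an occupancy grid as OpenDX text
#'
#' Regular-grid scalar field in the OpenDX format understood by most
#' molecular viewers.
#'
#' @param grid an `OccupancyGrid`
#' @param path output file
#' @return the path, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "OccupancyGrid"))
  d <- grid$dim
  n <- prod(d)
  # OpenDX wants z fastest; R arrays are x fastest
  vals <- as.vector(aperm(grid$occupancy, c(3, 2, 1)))
  rows <- split(vals, ceiling(seq_along(vals) / 3))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1] + grid$spacing / 2,
            grid$origin[2] + grid$spacing / 2, grid$origin[3] + grid$spacing / 2),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n),
    vapply(rows, function(r) paste(sprintf("%.6f", r), collapse = " "),
           character(1)),
    "attribute \"dep\" string \"positions\"",
    "object \"regular positions regular connections\" class field",
    "component \"positions\" value 1",
    "component \"connections\" value 2",
    "component \"data\" value 3"), con)
  invisible(path)
}
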