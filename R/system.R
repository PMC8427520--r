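#' Build a validated toy bead system
#'
#' A `ToySystem` is the desk-scale stand-in for a solvated receptor-ligand
#' complex: point beads with roles `"ligand"`, `"receptor"` or `"solvent"`
#' moving in a composite potential.  Available potential terms:
#'
#' * `funnel`: attractive Gaussian well of given `depth` (kcal/mol) and
#'   `width` (Angstrom) centred on `site_center`, acting on ligand beads --
#'   the binding site.
#' * `repulsion`: pairwise soft-core repulsion
#'   `V = epsilon * (1 - r/cutoff)^2` for distances below `cutoff`, between
#'   all pairs except receptor-receptor.
#' * `sphere`: confining half-harmonic sphere (`radius`, `k`, optional
#'   `center`, default the site) restraining mobile beads to a finite box.
#' * `harmonic`: isotropic harmonic well `V = k/2 r^2` on ligand beads about
#'   the site (used by calibration tests).
#' * `double_well`: quartic double well along x,
#'   `V = height * ((dx^2 - half_sep^2)/half_sep^2)^2`, with harmonic
#'   restraint `k_perp` on y and z, about `center`.
#'
#' Receptor beads are held fixed by default; set `receptor_restraint` to a
#' positive force constant (kcal/mol/A^2) to make them mobile under a
#' harmonic restraint to their initial positions.
#'
#' @param config named list with elements `beads` (data frame or list of
#'   lists with `id`, `role`, `mass` in amu and position `x`, `y`, `z` in
#'   Angstrom), `potential` (named list of the terms above), `site_center`
#'   (length-3 numeric), `temperature` (K), `friction` (1/ps), `timestep`
#'   (ps) and optional `receptor_restraint`.
#' @return An object of class `ToySystem`.
#' @export
build_toy_system <- function(config) {
  if (!is.list(config)) stop_validation("config must be a list")
  known <- c("beads", "potential", "site_center", "temperature",
             "friction", "timestep", "receptor_restraint")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0)
    stop_validation(paste0("unknown config keys: ", paste(extra, collapse = ", ")))

  beads <- config$beads
  if (is.null(beads)) stop_validation("'beads' is required", "beads")
  if (!is.data.frame(beads)) {
    beads <- do.call(rbind, lapply(beads, function(b) {
      pos <- b$position %||% c(b$x, b$y, b$z)
      data.frame(id = as.character(b$id), role = b$role, mass = b$mass,
                 x = pos[1], y = pos[2], z = pos[3],
                 stringsAsFactors = FALSE)
    }))
  }
  need <- c("id", "role", "mass", "x", "y", "z")
  if (!all(need %in% names(beads)))
    stop_validation(paste0("beads must supply columns: ",
                           paste(need, collapse = ", ")), "beads")
  beads$id <- as.character(beads$id)
  if (anyDuplicated(beads$id)) stop_validation("bead ids must be unique", "id")
  if (!all(beads$role %in% c("ligand", "receptor", "solvent")))
    stop_validation("bead role must be one of ligand/receptor/solvent", "role")
  if (!is.numeric(beads$mass) || any(!is.finite(beads$mass)) || any(beads$mass <= 0))
    stop_validation("bead masses must be positive finite numbers", "mass")
  if (any(!is.finite(c(beads$x, beads$y, beads$z))))
    stop_validation("bead positions must be finite", "position")
  if (sum(beads$role == "ligand") < 1)
    stop_validation("at least one ligand bead is required", "role")
  if (sum(beads$role == "receptor") < 1)
    stop_validation("at least one receptor bead is required", "role")

  site <- as.numeric(config$site_center %||% c(0, 0, 0))
  if (length(site) != 3 || any(!is.finite(site)))
    stop_validation("'site_center' must be a finite 3-vector", "site_center")

  temperature <- check_number(config$temperature %||% 300, "temperature", nonneg = TRUE)
  friction <- check_number(config$friction %||% 5, "friction", positive = TRUE)
  timestep <- check_number(config$timestep %||% 0.01, "timestep", positive = TRUE)
  restraint <- check_number(config$receptor_restraint %||% 0,
                            "receptor_restraint", nonneg = TRUE)

  pot <- validate_potential(config$potential %||% list(), site)

  sys <- structure(
    list(beads = beads, potential = pot, site_center = site,
         temperature = temperature, friction = friction,
         timestep = timestep, receptor_restraint = restraint),
    class = "ToySystem")

  e0 <- potential_energy(sys, initial_frame(sys))
  if (!is.finite(e0))
    stop_validation("potential energy not finite at initial positions", "beads")
  sys
}

validate_potential <- function(pot, site) {
  known <- c("funnel", "repulsion", "sphere", "harmonic", "double_well")
  extra <- setdiff(names(pot), known)
  if (length(extra) > 0)
    stop_validation(paste0("unknown potential terms: ", paste(extra, collapse = ", ")),
                    "potential")
  out <- list()
  if (!is.null(pot$funnel)) {
    out$funnel <- list(
      depth = check_number(pot$funnel$depth, "funnel.depth", positive = TRUE),
      width = check_number(pot$funnel$width, "funnel.width", positive = TRUE))
  }
  if (!is.null(pot$repulsion)) {
    out$repulsion <- list(
      epsilon = check_number(pot$repulsion$epsilon, "repulsion.epsilon", nonneg = TRUE),
      cutoff = check_number(pot$repulsion$cutoff, "repulsion.cutoff", positive = TRUE))
  }
  if (!is.null(pot$sphere)) {
    ctr <- as.numeric(pot$sphere$center %||% site)
    if (length(ctr) != 3) stop_validation("sphere.center must be a 3-vector", "sphere.center")
    out$sphere <- list(
      radius = check_number(pot$sphere$radius, "sphere.radius", positive = TRUE),
      k = check_number(pot$sphere$k, "sphere.k", positive = TRUE),
      center = ctr)
  }
  if (!is.null(pot$harmonic)) {
    out$harmonic <- list(
      k = check_number(pot$harmonic$k, "harmonic.k", positive = TRUE))
  }
  if (!is.null(pot$double_well)) {
    ctr <- as.numeric(pot$double_well$center %||% c(0, 0, 0))
    if (length(ctr) != 3)
      stop_validation("double_well.center must be a 3-vector", "double_well.center")
    out$double_well <- list(
      height = check_number(pot$double_well$height, "double_well.height", positive = TRUE),
      half_sep = check_number(pot$double_well$half_sep, "double_well.half_sep", positive = TRUE),
      k_perp = check_number(pot$double_well$k_perp %||% 0, "double_well.k_perp", nonneg = TRUE),
      center = ctr)
  }
  out
}

#' @export
print.ToySystem <- function(x, ...) {
  tab <- table(x$beads$role)
  cat("ToySystem:", nrow(x$beads), "beads (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  cat("  potential terms:",
      if (length(x$potential)) paste(names(x$potential), collapse = ", ") else "none", "\n")
  cat(sprintf("  T = %g K, friction = %g /ps, timestep = %g ps\n",
              x$temperature, x$friction, x$timestep))
  invisible(x)
}

role_indices <- function(system, role) which(system$beads$role == role)

#' Bead index helpers
#'
#' Row indices of beads with a given role.
#' @param system a `ToySystem`
#' @return integer vector of bead indices.
#' @export
ligand_indices <- function(system) role_indices(system, "ligand")

#' @rdname ligand_indices
#' @export
receptor_indices <- function(system) role_indices(system, "receptor")

#' @rdname ligand_indices
#' @export
solvent_indices <- function(system) role_indices(system, "solvent")

system_coords <- function(system) {
  m <- as.matrix(system$beads[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# TRUE for beads the integrator moves
mobile_flags <- function(system) {
  system$beads$role != "receptor" | system$receptor_restraint > 0
}

# potential description handed to the C++ integrator
pot_for_engine <- function(system) {
  c(system$potential,
    list(site = system$site_center, restraint_k = system$receptor_restraint))
}

#' Initial frame of a system
#'
#' @param system a `ToySystem`
#' @return a `Frame` at time 0 with the configured bead positions and zero
#'   velocities.
#' @export
initial_frame <- function(system) {
  n <- nrow(system$beads)
  make_frame(time = 0, coords = system_coords(system),
             velocities = matrix(0, n, 3))
}

#' Supervised ligand-to-site distance
#'
#' Distance between the ligand centroid (geometric by default, mass-weighted
#' on request) and the binding-site centre.  This is the default supervised
#' metric of the SuMD protocol.
#'
#' @param system a `ToySystem`
#' @param frame a `Frame`
#' @param mass_weighted use the ligand centre of mass instead of the
#'   geometric centre
#' @return distance in Angstrom.
#' @export
ligand_site_distance <- function(system, frame, mass_weighted = FALSE) {
  li <- ligand_indices(system)
  xyz <- frame$coords[li, , drop = FALSE]
  w <- if (mass_weighted) system$beads$mass[li] else rep(1, length(li))
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum((ctr - system$site_center)^2))
}

#' Minimum ligand-receptor interatomic distance
#'
#' @inheritParams ligand_site_distance
#' @return minimum over all ligand-receptor bead pairs, Angstrom.
#' @export
min_ligrec_distance <- function(system, frame) {
  li <- ligand_indices(system)
  ri <- receptor_indices(system)
  min(cross_distances(frame$coords[li, , drop = FALSE],
                      frame$coords[ri, , drop = FALSE]))
}

# all pairwise distances between two coordinate sets (nA x nB matrix)
cross_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Total potential energy of a frame
#'
#' Sum of all configured toy potential terms, in kcal/mol.  Useful for
#' diagnostics; the dynamics engine evaluates the same composite potential
#' internally.
#'
#' @inheritParams ligand_site_distance
#' @return energy in kcal/mol.
#' @export
potential_energy <- function(system, frame) {
  x <- frame$coords
  roles <- system$beads$role
  pot <- system$potential
  site <- system$site_center
  e <- 0
  li <- which(roles == "ligand")

  if (length(li) > 0) {
    d <- sweep(x[li, , drop = FALSE], 2, site)
    r2 <- rowSums(d^2)
    if (!is.null(pot$funnel))
      e <- e - pot$funnel$depth * sum(exp(-r2 / (2 * pot$funnel$width^2)))
    if (!is.null(pot$harmonic))
      e <- e + 0.5 * pot$harmonic$k * sum(r2)
    if (!is.null(pot$double_well)) {
      dw <- pot$double_well
      dx <- x[li, 1] - dw$center[1]
      e <- e + dw$height * sum(((dx^2 - dw$half_sep^2) / dw$half_sep^2)^2) +
        0.5 * dw$k_perp * sum((x[li, 2] - dw$center[2])^2 +
                              (x[li, 3] - dw$center[3])^2)
    }
  }

  if (!is.null(pot$repulsion)) {
    keep <- which(roles != "receptor")
    rec <- which(roles == "receptor")
    e <- e + softcore_energy(x, keep, rec, pot$repulsion)
  }

  if (!is.null(pot$sphere)) {
    mob <- which(roles != "receptor")
    if (length(mob) > 0) {
      r <- sqrt(rowSums(sweep(x[mob, , drop = FALSE], 2, pot$sphere$center)^2))
      over <- pmax(r - pot$sphere$radius, 0)
      e <- e + pot$sphere$k * sum(over^2)
    }
  }

  if (system$receptor_restraint > 0) {
    ri <- which(roles == "receptor")
    ref <- system_coords(system)[ri, , drop = FALSE]
    e <- e + 0.5 * system$receptor_restraint *
      sum((x[ri, , drop = FALSE] - ref)^2)
  }
  e
}

# soft-core repulsion over all pairs except receptor-receptor:
# mobile-mobile pairs plus mobile-receptor pairs
softcore_energy <- function(x, mob, rec, rp) {
  e <- 0
  term <- function(d) {
    d <- d[d < rp$cutoff]
    if (length(d) == 0) return(0)
    rp$epsilon * sum((1 - d / rp$cutoff)^2)
  }
  if (length(mob) > 1) {
    dm <- cross_distances(x[mob, , drop = FALSE], x[mob, , drop = FALSE])
    e <- e + term(dm[upper.tri(dm)])
  }
  if (length(mob) > 0 && length(rec) > 0) {
    e <- e + term(as.vector(cross_distances(x[mob, , drop = FALSE],
                                            x[rec, , drop = FALSE])))
  }
  e
}

#' Ligand-receptor interaction energy
#'
#' Sum of the potential terms coupling the ligand to the receptor only: the
#' binding-site funnel well (anchored on the receptor site) and
#' ligand-receptor soft-core repulsion.  Solvent-solvent and
#' receptor-internal terms are excluded.  This is the toy analogue of a
#' ligand-receptor interaction energy used to colour binding paths and
#' landscapes.
#'
#' @inheritParams ligand_site_distance
#' @return energy in kcal/mol (0 when the ligand is outside all cutoffs).
#' @export
interaction_energy <- function(system, frame) {
  x <- frame$coords
  pot <- system$potential
  li <- ligand_indices(system)
  ri <- receptor_indices(system)
  e <- 0
  if (!is.null(pot$funnel)) {
    d2 <- rowSums(sweep(x[li, , drop = FALSE], 2, system$site_center)^2)
    e <- e - pot$funnel$depth * sum(exp(-d2 / (2 * pot$funnel$width^2)))
  }
  if (!is.null(pot$harmonic)) {
    d2 <- rowSums(sweep(x[li, , drop = FALSE], 2, system$site_center)^2)
    e <- e + 0.5 * pot$harmonic$k * sum(d2)
  }
  if (!is.null(pot$repulsion) && length(ri) > 0) {
    d <- as.vector(cross_distances(x[li, , drop = FALSE], x[ri, , drop = FALSE]))
    d <- d[d < pot$repulsion$cutoff]
    if (length(d) > 0)
      e <- e + pot$repulsion$epsilon * sum((1 - d / pot$repulsion$cutoff)^2)
  }
  e
}

#' Count solvent beads bridging ligand and receptor
#'
#' Toy analogue of the number of water molecules simultaneously hydrating
#' the protein and hydrogen-bonding the ligand: solvent beads within `shell`
#' of any receptor bead and within `hbond_dist` of any ligand bead.  Used as
#' the second supervised metric during unbinding.
#'
#' @inheritParams ligand_site_distance
#' @param shell receptor hydration shell cutoff, Angstrom (default 4)
#' @param hbond_dist ligand hydrogen-bond distance cutoff, Angstrom
#'   (default 3.5)
#' @param receptor_subset optional integer vector of receptor bead indices
#'   to restrict the receptor side (the unbinding supervisor passes the
#'   current ligand-interacting partner set here)
#' @return integer count (0 when the system has no solvent beads).
#' @export
solvent_contact_count <- function(system, frame, shell = 4, hbond_dist = 3.5,
                                  receptor_subset = NULL) {
  si <- solvent_indices(system)
  if (length(si) == 0) return(0L)
  ri <- receptor_subset %||% receptor_indices(system)
  li <- ligand_indices(system)
  xs <- frame$coords[si, , drop = FALSE]
  near_rec <- apply(cross_distances(xs, frame$coords[ri, , drop = FALSE]) < shell,
                    1, any)
  near_lig <- apply(cross_distances(xs, frame$coords[li, , drop = FALSE]) < hbond_dist,
                    1, any)
  sum(near_rec & near_lig)
}
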