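fixture_names <- c("funnel_binding", "bound_complex", "solvated_complex",
                   "double_well_1d")

#' Generate a bundled toy fixture
#'
#' Deterministic toy systems that exercise each protocol at desk scale:
#'
#' * `funnel_binding`: one ligand bead started >= 30 Angstrom from the
#'   binding site (a 5 kcal/mol Gaussian funnel guarded by four fixed
#'   receptor beads), inside a 40 Angstrom confining sphere -- the binding
#'   supervision scenario, mirroring a ligand placed far from its receptor
#'   site at the start of a dynamic-docking run.
#' * `bound_complex`: the ligand at the bottom of a 3 kcal/mol site well
#'   with receptor beads in contact range -- the unbinding and
#'   metadynamics-release starting point (60 Angstrom sphere so the
#'   released ligand can travel).
#' * `solvated_complex`: `bound_complex` plus 60 inert solvent beads in a
#'   15 Angstrom droplet, so the double-metric unbinding supervisor
#'   (distance + bridging-solvent count) is exercisable.
#' * `double_well_1d`: one ligand bead in a quartic double well along x
#'   (5 kcal/mol barrier, minima 5 Angstrom apart, transverse harmonic
#'   restraint), the standard enhanced-sampling benchmark for barrier
#'   crossing.
#'
#' @param name fixture name, one of the above
#' @param seed RNG seed controlling the random placement choices (ligand
#'   start direction, solvent positions)
#' @param dir optional directory; when given, the fixture is written to
#'   disk as `<name>_config.yaml`, `<name>_topology.pdb` and
#'   `<name>_start.xyz`
#' @return list with `system` (a `ToySystem`), `start` (a `Frame`),
#'   `config` (a `RunConfig`) and `files` (paths, or `NULL`).
#' @export
generate_fixture <- function(name, seed = 1, dir = NULL) {
  if (!name %in% fixture_names)
    stop_validation(sprintf("unknown fixture '%s'; available: %s", name,
                            paste(fixture_names, collapse = ", ")), "name")
  set.seed(seed)
  fx <- switch(name,
    funnel_binding = fixture_funnel_binding(),
    bound_complex = fixture_bound_complex(),
    solvated_complex = fixture_solvated_complex(),
    double_well_1d = fixture_double_well())

  system <- build_toy_system(fx)
  start <- initial_frame(system)
  cfg <- as_run_config(list(system = system_to_config(system), seed = seed))

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      config = file.path(dir, paste0(name, "_config.yaml")),
      topology = file.path(dir, paste0(name, "_topology.pdb")),
      start = file.path(dir, paste0(name, "_start.xyz")))
    write_run_config(cfg, files$config)
    write_pdb_topology(system, files$topology)
    traj1 <- make_trajectory(
      times = 0, coords = array(start$coords, c(1, nrow(start$coords), 3)),
      metadata = list(elements = role_elements(system), fixture = name,
                      seed = seed))
    write_xyz(traj1, files$start)
  }
  list(system = system, start = start, config = cfg, files = files)
}

# four fixed receptor beads around the site in the z = 0 plane
receptor_cage <- function(r) {
  data.frame(id = paste0("rec", 1:4), role = "receptor", mass = 100,
             x = c(r, -r, 0, 0), y = c(0, 0, r, -r), z = 0,
             stringsAsFactors = FALSE)
}

fixture_funnel_binding <- function() {
  # ligand started at 32 A from the site, random direction
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  pos <- 32 * u
  beads <- rbind(
    data.frame(id = "lig", role = "ligand", mass = 20,
               x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE),
    receptor_cage(4))
  list(beads = beads,
       potential = list(funnel = list(depth = 5, width = 2.5),
                        repulsion = list(epsilon = 2, cutoff = 2.5),
                        sphere = list(radius = 40, k = 10)),
       site_center = c(0, 0, 0),
       temperature = 300, friction = 250, timestep = 0.01)
}

fixture_bound_complex <- function() {
  beads <- rbind(
    data.frame(id = "lig", role = "ligand", mass = 20, x = 0, y = 0, z = 0,
               stringsAsFactors = FALSE),
    receptor_cage(3))
  list(beads = beads,
       potential = list(funnel = list(depth = 3, width = 2),
                        repulsion = list(epsilon = 2, cutoff = 2.5),
                        sphere = list(radius = 60, k = 10)),
       site_center = c(0, 0, 0),
       temperature = 300, friction = 250, timestep = 0.01)
}

fixture_solvated_complex <- function(n_solvent = 60) {
  base <- fixture_bound_complex()
  base$potential$sphere$radius <- 15
  placed <- matrix(NA_real_, 0, 3)
  fixed <- as.matrix(base$beads[, c("x", "y", "z")])
  while (nrow(placed) < n_solvent) {
    p <- runif(3, -14, 14)
    r <- sqrt(sum(p^2))
    if (r < 4 || r > 14) next
    others <- rbind(fixed, placed)
    if (min(sqrt(rowSums(sweep(others, 2, p)^2))) < 2.2) next
    placed <- rbind(placed, p)
  }
  sol <- data.frame(id = paste0("sol", seq_len(n_solvent)), role = "solvent",
                    mass = 18, x = placed[, 1], y = placed[, 2],
                    z = placed[, 3], stringsAsFactors = FALSE)
  base$beads <- rbind(base$beads, sol)
  base
}

fixture_double_well <- function() {
  beads <- rbind(
    data.frame(id = "lig", role = "ligand", mass = 20,
               x = -2.5, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(id = "rec1", role = "receptor", mass = 100,
               x = 0, y = 20, z = 0, stringsAsFactors = FALSE))
  list(beads = beads,
       potential = list(
         double_well = list(height = 5, half_sep = 2.5, k_perp = 5,
                            center = c(0, 0, 0)),
         sphere = list(radius = 30, k = 10, center = c(0, 0, 0))),
       # the collective variable is measured from the left minimum
       site_center = c(-2.5, 0, 0),
       temperature = 300, friction = 250, timestep = 0.01)
}
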