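run_config_blocks <- c("system", "supervision", "schedule", "metadyn",
                       "analysis", "seed")

block_keys <- list(
  system = c("beads", "potential", "site_center", "temperature", "friction",
             "timestep", "receptor_restraint"),
  supervision = c("direction", "window_length", "save_interval",
                  "distance_threshold", "contact_cutoff", "metrics",
                  "mass_weighted", "max_windows", "seed"),
  schedule = c("dt0", "multipliers", "thresholds"),
  metadyn = c("height", "width", "period", "bias_factor", "temperature",
              "stop_threshold"),
  analysis = c("contact_cutoff", "hbond_distance", "hbond_angle",
               "grid_spacing", "occupancy_threshold", "bin_width"))

#' Read a run configuration file
#'
#' Run configurations are YAML files with up to five named blocks --
#' `system`, `supervision`, `schedule`, `metadyn`, `analysis` -- plus a
#' top-level `seed`.  Unknown blocks or keys are rejected so that typos do
#' not silently fall back to defaults.
#'
#' @param path YAML file
#' @return a validated named list of class `RunConfig`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a named list with the structure described above
#' @export
as_run_config <- function(cfg) {
  if (!is.list(cfg)) stop_validation("config must be a mapping")
  extra <- setdiff(names(cfg), run_config_blocks)
  if (length(extra) > 0)
    stop_validation(paste0("unknown config blocks: ",
                           paste(extra, collapse = ", ")))
  for (b in intersect(names(cfg), names(block_keys))) {
    bad <- setdiff(names(cfg[[b]]), block_keys[[b]])
    if (length(bad) > 0)
      stop_validation(sprintf("unknown keys in block '%s': %s", b,
                              paste(bad, collapse = ", ")))
  }
  structure(cfg, class = c("RunConfig", "list"))
}

#' Write a run configuration file
#'
#' @param cfg a `RunConfig` (or plain list with valid blocks)
#' @param path output YAML file
#' @return the path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- as_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Used as the provenance tag written into run manifests.
#'
#' @param cfg any R object
#' @return character hash.
#' @export
config_hash <- function(cfg) rlang::hash(cfg)

# system block of a RunConfig -> ToySystem
system_from_config <- function(cfg) {
  if (is.null(cfg$system)) stop_validation("config lacks a 'system' block")
  sys <- cfg$system
  if (!is.null(sys$beads) && !is.data.frame(sys$beads)) {
    # YAML delivers beads as a list of mappings
    sys$beads <- do.call(rbind, lapply(sys$beads, function(b) {
      pos <- unlist(b$position %||% c(b$x, b$y, b$z))
      data.frame(id = as.character(b$id), role = b$role, mass = b$mass,
                 x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
    }))
  }
  sys$site_center <- unlist(sys$site_center)
  build_toy_system(sys)
}

# ToySystem -> YAML-friendly system block
system_to_config <- function(system) {
  beads <- lapply(seq_len(nrow(system$beads)), function(i) {
    b <- system$beads[i, ]
    list(id = b$id, role = b$role, mass = b$mass,
         position = c(b$x, b$y, b$z))
  })
  list(beads = beads,
       potential = system$potential,
       site_center = system$site_center,
       temperature = system$temperature,
       friction = system$friction,
       timestep = system$timestep,
       receptor_restraint = system$receptor_restraint)
}
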