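#' Well-tempered metadynamics parameters
#'
#' Defaults are the published release-protocol settings: Gaussian hills of
#' height 0.1 kcal/mol and width 0.1 Angstrom deposited every 1 ps with
#' bias factor 20 at 300 K, until the biased distance reaches 50 Angstrom.
#'
#' @param height initial hill height w0, kcal/mol
#' @param width Gaussian hill width sigma, Angstrom
#' @param period hill deposition period, ps (must be a multiple of the
#'   engine timestep)
#' @param bias_factor well-tempering bias factor gamma (> 1); hill heights
#'   decay as `w0 * exp(-V(s)/((gamma - 1) kB T))`
#' @param temperature temperature entering the height decay, K
#' @param stop_threshold run termination: stop once the collective variable
#'   reaches this value, Angstrom
#' @return an object of class `MetadynParams`.
#' @export
metadyn_params <- function(height = 0.1, width = 0.1, period = 1,
                           bias_factor = 20, temperature = 300,
                           stop_threshold = 50) {
  check_number(height, "height", positive = TRUE)
  check_number(width, "width", positive = TRUE)
  check_number(period, "period", positive = TRUE)
  check_number(bias_factor, "bias_factor", positive = TRUE)
  if (bias_factor <= 1)
    stop_validation("bias_factor must be > 1", "bias_factor")
  check_number(temperature, "temperature", positive = TRUE)
  check_number(stop_threshold, "stop_threshold", positive = TRUE)
  structure(list(height = height, width = width, period = period,
                 bias_factor = bias_factor, temperature = temperature,
                 stop_threshold = stop_threshold),
            class = "MetadynParams")
}

#' Evaluate the metadynamics bias potential
#'
#' `V(s) = sum_k w_k exp(-(s - s_k)^2 / (2 sigma^2))` over the deposited
#' hills.
#'
#' @param s collective-variable value(s), Angstrom (vectorised)
#' @param hills hill log: data frame with columns `center` and `height`
#' @param width Gaussian width sigma, Angstrom
#' @return bias energy in kcal/mol for each element of `s`.
#' @export
evaluate_bias <- function(s, hills, width = 0.1) {
  if (is.null(hills) || nrow(hills) == 0) return(rep(0, length(s)))
  vapply(s, function(si)
    sum(hills$height * exp(-(si - hills$center)^2 / (2 * width^2))),
    numeric(1))
}

#' Derivative of the metadynamics bias
#'
#' Analytic dV/ds of [evaluate_bias()]; the engine projects `-dV/ds` on the
#' collective-variable gradient to obtain the bias force.
#'
#' @inheritParams evaluate_bias
#' @return dV/ds in kcal/mol per Angstrom.
#' @export
bias_derivative <- function(s, hills, width = 0.1) {
  if (is.null(hills) || nrow(hills) == 0) return(rep(0, length(s)))
  vapply(s, function(si) {
    ds <- si - hills$center
    sum(hills$height * (-ds / width^2) * exp(-ds^2 / (2 * width^2)))
  }, numeric(1))
}

#' Run well-tempered metadynamics on the ligand-site distance
#'
#' Langevin dynamics under the system potential plus a history-dependent
#' Gaussian bias on the scalar collective variable s = distance between the
#' ligand centroid and the binding-site centre.  Every `period` ps a hill is
#' deposited at the current s with well-tempered height
#' `w0 * exp(-V(s)/((gamma - 1) kB T))`; the run ends when s reaches the
#' stop threshold (checked at deposition resolution) or `max_time` is
#' exhausted.
#'
#' @param system a `ToySystem`
#' @param start starting `Frame` (default: the system's initial frame;
#'   missing velocities are drawn at the system temperature)
#' @param params a [metadyn_params()]
#' @param seed RNG seed
#' @param max_time safety cap on simulated time, ps
#' @return list with elements `trajectory` (one frame per deposition
#'   period), `hills` (data frame: time, center, height), `cv` (per-frame
#'   collective-variable values) and `termination`
#'   (`"threshold_reached"` or `"max_time"`).
#' @export
run_metadynamics <- function(system, start = NULL, params = metadyn_params(),
                             seed = 1, max_time = 100000) {
  stopifnot(inherits(system, "ToySystem"), inherits(params, "MetadynParams"))
  steps <- check_commensurate(params$period, system$timestep,
                              "period", "timestep")
  n_chunks <- check_commensurate(max_time, params$period, "max_time", "period")

  start <- start %||% initial_frame(system)
  s0 <- ligand_site_distance(system, start)
  if (!is.finite(s0))
    stop_validation("collective variable not finite at start", "start")

  n <- nrow(system$beads)
  set.seed(seed)
  if (is.null(start$velocities))
    start$velocities <- matrix(
      rnorm(3 * n, sd = rep(sqrt(.kB_vel * system$temperature /
                                 system$beads$mass), 3)), n, 3)

  coords <- start$coords
  vel <- start$velocities
  kbt_delta <- (params$bias_factor - 1) * .kB * params$temperature

  # preallocated hill log (one hill per deposition period)
  h_time <- numeric(n_chunks)
  h_center <- numeric(n_chunks)
  h_height <- numeric(n_chunks)

  saved <- array(0, c(n_chunks, n, 3))
  times <- numeric(n_chunks)
  cv <- numeric(n_chunks)
  termination <- "max_time"
  done <- 0L

  for (ch in seq_len(n_chunks)) {
    prev <- seq_len(ch - 1L)
    hills_now <- list(center = h_center[prev], height = h_height[prev])
    res <- langevin_step_raw(system, coords, vel, steps,
                             hills = hills_now, hill_sigma = params$width)
    coords <- res$coords
    vel <- res$velocities
    t_now <- start$time + ch * params$period
    s <- ligand_site_distance(system, make_frame(t_now, coords))

    v_here <- if (ch > 1)
      sum(h_height[prev] * exp(-(s - h_center[prev])^2 / (2 * params$width^2)))
    else 0
    h_time[ch] <- t_now
    h_center[ch] <- s
    h_height[ch] <- params$height * exp(-v_here / kbt_delta)

    saved[ch, , ] <- coords
    times[ch] <- t_now
    cv[ch] <- s
    done <- ch
    if (s >= params$stop_threshold) {
      termination <- "threshold_reached"
      break
    }
  }

  idx <- seq_len(done)
  hills <- data.frame(time = h_time[idx], center = h_center[idx],
                      height = h_height[idx])
  traj <- make_trajectory(
    times = times[idx],
    coords = saved[idx, , , drop = FALSE],
    metadata = list(engine = "metadynamics", seed = seed,
                    params = unclass(params)))
  list(trajectory = traj, hills = hills, cv = cv[idx],
       termination = termination)
}

#' Write a hill log as a HILLS-style table
#'
#' Three whitespace-separated columns: deposition time (ps), hill centre
#' (Angstrom), hill height (kcal/mol), with a provenance comment header.
#'
#' @param hills hill log data frame from [run_metadynamics()]
#' @param path output file
#' @param header optional named list written as `#! key value` lines
#' @return the path, invisibly.
#' @export
write_hills <- function(hills, path, header = list()) {
  lines <- c(sprintf("#! FIELDS time center height"),
             vapply(names(header), function(k)
               sprintf("#! %s %s", k, format(header[[k]])), character(1)),
             sprintf("%.6f %.6f %.8f", hills$time, hills$center, hills$height))
  writeLines(lines, path)
  invisible(path)
}

#' Read a HILLS-style table
#'
#' @param path file written by [write_hills()]
#' @return data frame with columns time, center, height.
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(time = numeric(0), center = numeric(0),
                      height = numeric(0)))
  parts <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  data.frame(time = as.numeric(parts[, 1]), center = as.numeric(parts[, 2]),
             height = as.numeric(parts[, 3]))
}
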