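#' Supervision settings for a SuMD run
#'
#' Binding defaults follow the standard protocol: 500 ps windows sampled
#' every 50 ps, terminating when the supervised ligand-to-site distance
#' drops below 4 Angstrom.  Unbinding windows are scheduled adaptively by an
#' [unbinding_schedule()] and terminate when no ligand-receptor contact
#' remains at the 3.5 Angstrom cutoff.
#'
#' @param direction `"binding"` or `"unbinding"`
#' @param window_length window length in ps (binding only; unbinding window
#'   lengths come from the schedule). Must be a multiple of `save_interval`
#'   with at least two samples per window (the slope fit needs two points).
#' @param save_interval metric sampling / frame saving interval, ps
#' @param distance_threshold binding termination distance, Angstrom
#' @param contact_cutoff contact distance defining "bound" for the
#'   unbinding termination rule, Angstrom
#' @param metrics optional character vector naming supervised metrics among
#'   `"site_distance"` and `"solvent_bridges"`.  Defaults: binding
#'   supervises the site distance; unbinding additionally supervises the
#'   bridging-solvent count when the system contains solvent beads.
#' @param mass_weighted use centre of mass rather than geometric centre for
#'   the supervised distance
#' @param max_windows safety cap on the number of windows (accepted or not)
#' @param seed root RNG seed; per-window child seeds are derived from it so
#'   restarts are reproducible
#' @return an object of class `SupervisionConfig`.
#' @export
supervision_config <- function(direction = c("binding", "unbinding"),
                               window_length = NULL, save_interval = 50,
                               distance_threshold = 4, contact_cutoff = 3.5,
                               metrics = NULL, mass_weighted = FALSE,
                               max_windows = 10000, seed = 1) {
  direction <- match.arg(direction)
  check_number(save_interval, "save_interval", positive = TRUE)
  check_number(distance_threshold, "distance_threshold", positive = TRUE)
  check_number(contact_cutoff, "contact_cutoff", positive = TRUE)
  check_number(max_windows, "max_windows", positive = TRUE)
  if (max_windows < 1) stop_validation("max_windows must be >= 1", "max_windows")
  if (is.null(window_length) && direction == "binding") window_length <- 500
  if (!is.null(window_length)) {
    ns <- check_commensurate(window_length, save_interval,
                             "window_length", "save_interval")
    if (ns < 2)
      stop_validation("window_length must allow >= 2 samples per window",
                      "window_length")
  }
  if (!is.null(metrics) &&
      !all(metrics %in% c("site_distance", "solvent_bridges")))
    stop_validation("metrics must be among site_distance, solvent_bridges",
                    "metrics")
  structure(list(direction = direction, window_length = window_length,
                 save_interval = save_interval,
                 distance_threshold = distance_threshold,
                 contact_cutoff = contact_cutoff, metrics = metrics,
                 mass_weighted = mass_weighted,
                 max_windows = as.integer(max_windows), seed = seed),
            class = "SupervisionConfig")
}

#' Adaptive window-length schedule for unbinding
#'
#' Along an unbinding pathway the window length grows with the
#' ligand-protein distance r_L observed at the end of the previous
#' productive window: `dt = dt0 * Nt_i`, where the multiplier is selected
#' by comparing r_L with three increasing distance thresholds,
#'
#' * `r_L <= D1` -> 1
#' * `D1 < r_L <= D2` -> Nt1
#' * `D2 < r_L <= D3` -> Nt2
#' * `D3 < r_L` -> Nt3
#'
#' Defaults are the published protocol values: dt0 = 300 ps, multipliers
#' 3, 6, 10 and thresholds 5, 8, 10 Angstrom.
#'
#' @param dt0 initial window length, ps
#' @param multipliers integer vector (Nt1, Nt2, Nt3), non-decreasing
#' @param thresholds numeric vector (D1, D2, D3) in Angstrom, strictly
#'   increasing
#' @return an object of class `UnbindingSchedule`.
#' @export
unbinding_schedule <- function(dt0 = 300, multipliers = c(3, 6, 10),
                               thresholds = c(5, 8, 10)) {
  check_number(dt0, "dt0", positive = TRUE)
  if (length(multipliers) != 3 || any(multipliers <= 0))
    stop_validation("multipliers must be three positive values", "multipliers")
  if (any(diff(multipliers) < 0))
    stop_validation("multipliers must be non-decreasing (Nt1 <= Nt2 <= Nt3)",
                    "multipliers")
  if (length(thresholds) != 3 || any(thresholds <= 0))
    stop_validation("thresholds must be three positive distances", "thresholds")
  if (any(diff(thresholds) <= 0))
    stop_validation("thresholds must be strictly increasing (D1 < D2 < D3)",
                    "thresholds")
  structure(list(dt0 = dt0, multipliers = multipliers, thresholds = thresholds),
            class = "UnbindingSchedule")
}

#' Window length for a given ligand-protein distance
#'
#' @param r_L ligand-protein distance(s) at the end of the previous
#'   productive window, Angstrom (vectorised)
#' @param schedule an [unbinding_schedule()]
#' @return window length(s) in ps.
#' @export
schedule_window_length <- function(r_L, schedule = unbinding_schedule()) {
  if (!inherits(schedule, "UnbindingSchedule"))
    stop_validation("schedule must be an UnbindingSchedule", "schedule")
  if (any(!is.finite(r_L)) || any(r_L < 0))
    stop_validation("r_L must be finite and >= 0", "r_L")
  D <- schedule$thresholds
  Nt <- schedule$multipliers
  mult <- ifelse(r_L <= D[1], 1,
          ifelse(r_L <= D[2], Nt[1],
          ifelse(r_L <= D[3], Nt[2], Nt[3])))
  schedule$dt0 * mult
}

#' Least-squares slope of a metric series
#'
#' Ordinary least-squares slope of `values` against `times`, the quantity
#' the supervisor inspects after each window.
#'
#' @param times sampling times, ps (at least two, not all equal)
#' @param values metric values at those times
#' @return slope in metric units per ps.
#' @export
fit_slope <- function(times, values) {
  if (length(times) < 2 || length(values) != length(times))
    stop_validation("need >= 2 paired (time, value) samples")
  tc <- times - mean(times)
  den <- sum(tc^2)
  if (den == 0) stop_validation("times are degenerate (zero variance)", "times")
  sum(tc * (values - mean(values))) / den
}

#' Accept or reject a supervised window
#'
#' Binding windows are productive when every supervised slope is negative
#' (the metric trends inward); unbinding windows when every slope is
#' positive.  A slope of exactly zero is non-productive in both directions:
#' zero slope means no progress.
#'
#' @param slopes numeric vector of per-metric fitted slopes
#' @param direction `"binding"` or `"unbinding"`
#' @return logical: is the window accepted (productive)?
#' @export
classify_window <- function(slopes, direction = c("binding", "unbinding")) {
  direction <- match.arg(direction)
  if (length(slopes) < 1 || any(!is.finite(slopes)))
    stop_validation("at least one finite slope is required", "slopes")
  if (direction == "binding") all(slopes < 0) else all(slopes > 0)
}

# resolve metric names into functions(frame) -> value, honouring the
# current unbinding partner set stored in `partners_env`
resolve_metrics <- function(system, config, partners_env = NULL) {
  names <- config$metrics
  if (is.null(names)) {
    names <- "site_distance"
    if (config$direction == "unbinding" && length(solvent_indices(system)) > 0)
      names <- c("site_distance", "solvent_bridges")
  }
  fns <- lapply(names, function(nm) {
    switch(nm,
      site_distance = function(frame)
        ligand_site_distance(system, frame, config$mass_weighted),
      solvent_bridges = function(frame)
        solvent_contact_count(system, frame,
                              receptor_subset = if (!is.null(partners_env))
                                partners_env$ids else NULL))
  })
  stats::setNames(fns, names)
}

# receptor beads currently interacting with the ligand (toy analogue of the
# protein atoms hydrogen-bonding / contacting the ligand); empty detection
# retains the previous set
update_partner_set <- function(system, frame, cutoff, previous) {
  ri <- receptor_indices(system)
  li <- ligand_indices(system)
  d <- cross_distances(frame$coords[ri, , drop = FALSE],
                       frame$coords[li, , drop = FALSE])
  hit <- ri[apply(d < cutoff, 1, any)]
  if (length(hit) == 0) previous else hit
}

sumd_seeds <- function(seed, max_windows) {
  set.seed(seed)
  list(sim = sample.int(2147483646L, max_windows + 1L),
       vel = sample.int(2147483646L, max_windows + 1L))
}

#' Run a supervised MD binding simulation
#'
#' Iterates fixed-length unbiased windows from `start`.  After each window
#' the supervised metric samples are fitted to a straight line; a negative
#' slope makes the window productive and the next window continues from the
#' last coordinates and velocities produced, otherwise the window is
#' discarded and the run restarts from the last accepted frame with
#' randomly reassigned Maxwell-Boltzmann velocities (tabu-like rule).  The
#' run terminates when the end-of-window supervised distance drops below
#' the configured threshold, or at `max_windows`.
#'
#' @param system a `ToySystem`
#' @param start starting `Frame` (default: the system's initial frame;
#'   missing velocities are drawn at the system temperature)
#' @param config a [supervision_config()] with direction `"binding"`
#' @param engine dynamics engine, any
#'   `function(system, state, duration, save_interval, seed)` returning a
#'   `Trajectory`; defaults to [langevin_run()]
#' @return an object of class `SuMDResult`: the accepted trajectory, the
#'   full per-window log, the restart count and the termination reason.
#' @export
run_sumd_binding <- function(system, start = NULL,
                             config = supervision_config("binding"),
                             engine = langevin_run) {
  if (config$direction != "binding")
    stop_validation("config direction must be 'binding'", "direction")
  run_sumd(system, start, config, engine, schedule = NULL)
}

#' Run a supervised MD unbinding simulation
#'
#' Double-metric adaptive unbinding: each window's length is scheduled from
#' the supervised distance at the end of the previous productive window
#' (the first window uses dt0), a window is productive only when all
#' supervised slopes are positive, and after each productive window the set
#' of receptor beads interacting with the ligand is re-detected (falling
#' back to the previous set when empty) so the bridging-solvent metric
#' tracks the current interface.  The run terminates when the final frame
#' has no ligand-receptor pair within the contact cutoff.
#'
#' @inheritParams run_sumd_binding
#' @param config a [supervision_config()] with direction `"unbinding"`
#' @param schedule an [unbinding_schedule()]
#' @return an object of class `SuMDResult`.
#' @export
run_sumd_unbinding <- function(system, start = NULL,
                               config = supervision_config("unbinding"),
                               schedule = unbinding_schedule(),
                               engine = langevin_run) {
  if (config$direction != "unbinding")
    stop_validation("config direction must be 'unbinding'", "direction")
  if (!inherits(schedule, "UnbindingSchedule"))
    stop_validation("schedule must be an UnbindingSchedule", "schedule")
  start <- start %||% initial_frame(system)
  if (min_ligrec_distance(system, start) >= config$contact_cutoff)
    stop_validation(sprintf(
      "start is not bound: no ligand-receptor contact within %g Angstrom",
      config$contact_cutoff), "start")
  run_sumd(system, start, config, engine, schedule = schedule)
}

# shared supervision loop for both directions
run_sumd <- function(system, start, config, engine, schedule) {
  start <- start %||% initial_frame(system)
  binding <- config$direction == "binding"
  seeds <- sumd_seeds(config$seed, config$max_windows)

  if (is.null(start$velocities))
    start <- resample_velocities(start, system$temperature,
                                 system$beads$mass,
                                 seed = seeds$vel[config$max_windows + 1L])

  partners_env <- new.env(parent = emptyenv())
  partners_env$ids <- update_partner_set(system, start, config$contact_cutoff,
                                         receptor_indices(system))
  metrics <- resolve_metrics(system, config, partners_env)

  current <- start
  last_accepted <- start
  windows <- vector("list", config$max_windows)
  accepted_pieces <- list()
  restart_count <- 0L
  steps_total <- 0
  termination <- "max_windows"
  r_sched <- if (!binding) ligand_site_distance(system, start, config$mass_weighted)

  for (w in seq_len(config$max_windows)) {
    dt_w <- if (binding) config$window_length
            else schedule_window_length(r_sched, schedule)
    traj_w <- engine(system, current, dt_w, config$save_interval,
                     seed = seeds$sim[w])
    traj_w$window_id <- rep(w, n_frames(traj_w))
    steps_total <- steps_total + round(dt_w / system$timestep)

    samples <- data.frame(time = traj_w$times)
    for (nm in names(metrics))
      samples[[nm]] <- eval_metric_series(traj_w, metrics[[nm]])
    slopes <- vapply(names(metrics),
                     function(nm) fit_slope(samples$time, samples[[nm]]),
                     numeric(1))
    accepted <- classify_window(slopes, config$direction)

    end_frame <- get_frame(traj_w, n_frames(traj_w))
    r_end <- ligand_site_distance(system, end_frame, config$mass_weighted)
    windows[[w]] <- structure(
      list(window_id = w, dt = dt_w, start_time = current$time,
           start_coords = current$coords, seed = seeds$sim[w],
           r_scheduled_from = if (!binding) r_sched else NA_real_,
           samples = samples, slopes = slopes, accepted = accepted,
           r_end = r_end),
      class = "WindowRecord")

    if (accepted) {
      accepted_pieces[[length(accepted_pieces) + 1L]] <- traj_w
      current <- end_frame
      last_accepted <- end_frame
      if (binding) {
        if (r_end < config$distance_threshold) {
          termination <- "criterion_met"
          windows <- windows[seq_len(w)]
          break
        }
      } else {
        r_sched <- r_end
        partners_env$ids <- update_partner_set(system, end_frame,
                                               config$contact_cutoff,
                                               partners_env$ids)
        if (min_ligrec_distance(system, end_frame) >= config$contact_cutoff) {
          termination <- "criterion_met"
          windows <- windows[seq_len(w)]
          break
        }
      }
    } else {
      restart_count <- restart_count + 1L
      current <- resample_velocities(last_accepted, system$temperature,
                                     system$beads$mass, seed = seeds$vel[w])
    }
    if (w == config$max_windows) windows <- windows[seq_len(w)]
  }

  trajectory <- concat_trajectories(
    accepted_pieces,
    metadata = list(engine = "sumd", direction = config$direction,
                    seed = config$seed))
  structure(
    list(trajectory = trajectory, windows = windows,
         restart_count = restart_count, termination = termination,
         steps_total = steps_total, final_frame = last_accepted,
         direction = config$direction, config = config,
         schedule = schedule),
    class = "SuMDResult")
}

#' @export
print.SuMDResult <- function(x, ...) {
  nacc <- sum(vapply(x$windows, function(w) w$accepted, logical(1)))
  cat(sprintf("SuMD %s run: %d windows (%d accepted, %d restarts), %s\n",
              x$direction, length(x$windows), nacc, x$restart_count,
              x$termination))
  cat(sprintf("  total integration steps: %d\n", as.integer(x$steps_total)))
  if (!is.null(x$trajectory))
    cat(sprintf("  accepted trajectory: %d frames, t up to %g ps\n",
                n_frames(x$trajectory), max(x$trajectory$times)))
  invisible(x)
}

#' Tabulate the window log of a SuMD run
#'
#' @param result a `SuMDResult`
#' @return data frame with one row per window: id, length, slopes,
#'   acceptance and end-of-window supervised distance.
#' @export
window_log <- function(result) {
  stopifnot(inherits(result, "SuMDResult"))
  rows <- lapply(result$windows, function(w) {
    df <- data.frame(window_id = w$window_id, dt = w$dt,
                     start_time = w$start_time, accepted = w$accepted,
                     r_end = w$r_end,
                     r_scheduled_from = w$r_scheduled_from)
    for (nm in names(w$slopes)) df[[paste0("slope_", nm)]] <- w$slopes[[nm]]
    df
  })
  do.call(rbind, rows)
}
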