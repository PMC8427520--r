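test_that("the supervised slope is an ordinary least-squares fit", {
  expect_identical(fit_slope(c(0, 50, 100), c(7, 7, 7)), 0)
  expect_equal(fit_slope(c(0, 50, 100), c(10, 9, 8)), -0.02)

  set.seed(1)
  for (rep in 1:20) {
    t <- sort(runif(20, 0, 500))
    y <- runif(20, 0, 40)
    expect_equal(fit_slope(t, y), slope_normal_equations(t, y),
                 tolerance = 1e-10)
  }

  expect_error(fit_slope(1, 2), class = "sumdr_validation_error")
  expect_error(fit_slope(c(5, 5, 5), c(1, 2, 3)),
               class = "sumdr_validation_error")
})

test_that("window lengths follow the four distance branches of the schedule", {
  sch <- unbinding_schedule()  # dt0 = 300, Nt = 3/6/10, D = 5/8/10
  expect_equal(schedule_window_length(4, sch), 300)
  expect_equal(schedule_window_length(5, sch), 300)    # boundary: <= D1
  expect_equal(schedule_window_length(6, sch), 900)
  expect_equal(schedule_window_length(8, sch), 900)    # boundary: <= D2
  expect_equal(schedule_window_length(9, sch), 1800)
  expect_equal(schedule_window_length(10, sch), 1800)  # boundary: <= D3
  expect_equal(schedule_window_length(12, sch), 3000)

  expect_error(unbinding_schedule(multipliers = c(6, 3, 10)),
               class = "sumdr_validation_error")
  expect_error(unbinding_schedule(thresholds = c(8, 5, 10)),
               class = "sumdr_validation_error")
  expect_error(schedule_window_length(-1, sch),
               class = "sumdr_validation_error")
})

test_that("window classification follows the slope-sign rules with zero rejected", {
  expect_true(classify_window(-0.02, "binding"))
  expect_false(classify_window(0.02, "binding"))
  expect_true(classify_window(c(0.01, 0.3), "unbinding"))
  expect_false(classify_window(c(0.01, -0.3), "unbinding"))
  expect_false(classify_window(0, "binding"))
  expect_false(classify_window(0, "unbinding"))
  expect_error(classify_window(numeric(0), "binding"),
               class = "sumdr_validation_error")
})

test_that("a deterministic inward drift is accepted every window", {
  sys <- build_toy_system(minimal_binding_config(lig_pos = c(30, 0, 0)))
  res <- run_sumd_binding(sys, config = supervision_config("binding", seed = 1),
                          engine = drift_engine(rate = 0.02))
  expect_equal(res$termination, "criterion_met")
  expect_equal(res$restart_count, 0L)
  lg <- window_log(res)
  expect_true(all(lg$accepted))
  expect_true(all(diff(lg$r_end) < 0))
  expect_lt(lg$r_end[nrow(lg)], 4)
  # accepted trajectory: strictly increasing times, each window once
  expect_true(all(diff(res$trajectory$times) > 0))
  expect_equal(unique(res$trajectory$window_id), lg$window_id)
})

test_that("a purely repulsive system exhausts max_windows without acceptance", {
  sys <- build_toy_system(list(
    beads = data.frame(id = c("l", "r"), role = c("ligand", "receptor"),
                       mass = c(20, 100), x = c(2, 0), y = 0, z = 0,
                       stringsAsFactors = FALSE),
    potential = list(repulsion = list(epsilon = 5, cutoff = 6),
                     sphere = list(radius = 30, k = 10)),
    site_center = c(0, 0, 0), temperature = 300, friction = 250,
    timestep = 0.01))
  res <- run_sumd_binding(
    sys, config = supervision_config("binding", window_length = 200,
                                     save_interval = 50, max_windows = 4,
                                     seed = 2))
  expect_equal(res$termination, "max_windows")
  expect_equal(length(res$windows), 4)
})

test_that("binding supervision terminates below the distance threshold", {
  fx <- generate_fixture("funnel_binding", seed = 8)
  res <- run_sumd_binding(fx$system,
                          config = supervision_config("binding", seed = 8))
  expect_equal(res$termination, "criterion_met")
  expect_lt(ligand_site_distance(fx$system, res$final_frame), 4)
  lg <- window_log(res)
  expect_equal(sum(lg$accepted) + res$restart_count, nrow(lg))
})

test_that("rejected windows restart exactly from the last accepted coordinates", {
  fx <- generate_fixture("funnel_binding", seed = 8)
  res <- run_sumd_binding(fx$system,
                          config = supervision_config("binding", seed = 8))
  last_accepted_coords <- fx$start$coords
  for (w in res$windows) {
    expect_identical(w$start_coords, last_accepted_coords)
    if (w$accepted) {
      nf <- nrow(w$samples)
      # end of this window becomes the new tabu anchor
      idx <- which(res$trajectory$window_id == w$window_id)
      last_accepted_coords <-
        matrix(res$trajectory$coords[max(idx), , , drop = TRUE], ncol = 3)
    }
  }
})

test_that("unbinding terminates contact-free with a schedule-consistent log", {
  fx <- generate_fixture("bound_complex", seed = 4)
  sch <- unbinding_schedule()
  res <- run_sumd_unbinding(fx$system,
                            config = supervision_config("unbinding", seed = 4),
                            schedule = sch)
  expect_equal(res$termination, "criterion_met")
  expect_gte(min_ligrec_distance(fx$system, res$final_frame), 3.5)
  lg <- window_log(res)
  expect_equal(lg$dt, schedule_window_length(lg$r_scheduled_from, sch))
  # first window always uses dt0
  expect_equal(lg$dt[1], sch$dt0)
})

test_that("a degenerate schedule keeps every window at dt0", {
  fx <- generate_fixture("bound_complex", seed = 6)
  sch <- unbinding_schedule(multipliers = c(1, 1, 1))
  res <- run_sumd_unbinding(fx$system,
                            config = supervision_config("unbinding", seed = 6,
                                                        max_windows = 20),
                            schedule = sch)
  expect_true(all(window_log(res)$dt == 300))
})

test_that("an unbound start violates the unbinding precondition", {
  fx <- generate_fixture("funnel_binding", seed = 1)  # ligand 32 A away
  expect_error(
    run_sumd_unbinding(fx$system,
                       config = supervision_config("unbinding", seed = 1)),
    "not bound", class = "sumdr_validation_error")
})

test_that("double supervision runs both metrics on a solvated complex", {
  fx <- generate_fixture("solvated_complex", seed = 2)
  res <- run_sumd_unbinding(
    fx$system,
    config = supervision_config("unbinding", seed = 2, max_windows = 3))
  for (w in res$windows) {
    expect_named(w$slopes, c("site_distance", "solvent_bridges"))
    expect_identical(w$accepted,
                     classify_window(w$slopes, "unbinding"))
    # stored slopes reproduce from stored samples
    expect_equal(w$slopes[["site_distance"]],
                 fit_slope(w$samples$time, w$samples$site_distance))
    expect_equal(w$slopes[["solvent_bridges"]],
                 fit_slope(w$samples$time, w$samples$solvent_bridges))
  }
})
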