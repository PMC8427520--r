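test_that("toy systems build deterministically and validate their fields", {
  cfg <- minimal_binding_config()
  sys <- build_toy_system(cfg)
  expect_s3_class(sys, "ToySystem")
  expect_equal(nrow(sys$beads), 5)
  expect_identical(sys, build_toy_system(cfg))

  bad <- cfg
  bad$beads$mass[1] <- 0
  expect_error(build_toy_system(bad), "mass", class = "sumdr_validation_error")

  bad <- cfg
  bad$beads$role[2] <- "membrane"
  expect_error(build_toy_system(bad), "role", class = "sumdr_validation_error")

  bad <- cfg
  bad$timestep <- -1
  expect_error(build_toy_system(bad), "timestep",
               class = "sumdr_validation_error")

  norec <- cfg
  norec$beads <- norec$beads[norec$beads$role == "ligand", ]
  expect_error(build_toy_system(norec), "receptor",
               class = "sumdr_validation_error")
})

test_that("a ligand at the potential minimum stays put at zero temperature", {
  cfg <- minimal_binding_config(lig_pos = c(0, 0, 0))
  cfg$temperature <- 0
  sys <- build_toy_system(cfg)
  tr <- langevin_run(sys, duration = 100, save_interval = 10, seed = 1)
  expect_equal(max(abs(tr$coords[, 1, ])), 0)
})

test_that("runs are bit-reproducible for a fixed seed and differ across seeds", {
  sys <- build_toy_system(minimal_binding_config())
  a <- langevin_run(sys, duration = 50, save_interval = 10, seed = 11)
  b <- langevin_run(sys, duration = 50, save_interval = 10, seed = 11)
  c <- langevin_run(sys, duration = 50, save_interval = 10, seed = 12)
  expect_identical(a$coords, b$coords)
  expect_identical(a$velocities, b$velocities)
  expect_false(identical(a$coords, c$coords))
})

test_that("fixed receptor beads never move and frame times are arithmetic", {
  sys <- build_toy_system(minimal_binding_config())
  tr <- langevin_run(sys, duration = 200, save_interval = 20, seed = 3)
  ri <- receptor_indices(sys)
  start <- system_coords <- initial_frame(sys)$coords
  for (i in seq_len(n_frames(tr)))
    expect_equal(tr$coords[i, ri, ], start[ri, ])
  expect_equal(diff(tr$times), rep(20, n_frames(tr) - 1))
})

test_that("non-commensurate durations are rejected", {
  sys <- build_toy_system(minimal_binding_config())
  expect_error(langevin_run(sys, duration = 55, save_interval = 10, seed = 1),
               class = "sumdr_validation_error")
  expect_error(langevin_run(sys, duration = 50, save_interval = 0.013, seed = 1),
               class = "sumdr_validation_error")
})

test_that("velocity resampling is Maxwell-Boltzmann and leaves coordinates alone", {
  fr <- random_frame(2000)
  out <- resample_velocities(fr, 300, masses = rep(20, 2000), seed = 5)
  expect_identical(out$coords, fr$coords)
  expect_equal(var(as.vector(out$velocities)), kB_vel * 300 / 20,
               tolerance = 0.05)

  zero <- resample_velocities(fr, 0, masses = rep(20, 2000), seed = 5)
  expect_true(all(zero$velocities == 0))

  again <- resample_velocities(fr, 300, masses = rep(20, 2000), seed = 5)
  expect_identical(out$velocities, again$velocities)
})

test_that("interaction energy follows its definition", {
  sys <- build_toy_system(minimal_binding_config())

  far <- initial_frame(sys)
  far$coords[1, ] <- c(0, 0, 1000)
  expect_equal(interaction_energy(sys, far), 0, tolerance = 1e-12)

  bound <- initial_frame(sys)
  bound$coords[1, ] <- sys$site_center
  expect_equal(interaction_energy(sys, bound), -5)

  set.seed(42)
  for (rep in 1:20) {
    fr <- initial_frame(sys)
    fr$coords[1, ] <- runif(3, -6, 6)
    expect_equal(interaction_energy(sys, fr),
                 interaction_energy_oracle(sys, fr), tolerance = 1e-12)
  }
})

test_that("interaction energy is invariant under rigid motion of the complex", {
  cfg <- minimal_binding_config(lig_pos = c(2, 1, -1))
  sys <- build_toy_system(cfg)
  fr <- initial_frame(sys)
  e0 <- interaction_energy(sys, fr)
  set.seed(7)
  for (rep in 1:5) {
    rot <- random_rotation()
    shift <- runif(3, -20, 20)
    cfg2 <- cfg
    moved <- t(rot %*% t(as.matrix(cfg$beads[, c("x", "y", "z")]))) +
      matrix(shift, nrow(cfg$beads), 3, byrow = TRUE)
    cfg2$beads$x <- moved[, 1]; cfg2$beads$y <- moved[, 2]
    cfg2$beads$z <- moved[, 3]
    cfg2$site_center <- as.numeric(rot %*% cfg$site_center + shift)
    sys2 <- build_toy_system(cfg2)
    expect_equal(interaction_energy(sys2, initial_frame(sys2)), e0,
                 tolerance = 1e-10)
  }
})

test_that("bridging-solvent counting matches constructed geometry and brute force", {
  cfg <- minimal_binding_config(lig_pos = c(0, 0, 0))
  sys_dry <- build_toy_system(cfg)
  expect_identical(solvent_contact_count(sys_dry, initial_frame(sys_dry)), 0L)

  # one solvent bead 3 A from both the ligand and a receptor bead
  cfg$beads <- rbind(cfg$beads,
    data.frame(id = "sol1", role = "solvent", mass = 18,
               x = 2, y = 2.23607, z = 0, stringsAsFactors = FALSE))
  sys1 <- build_toy_system(cfg)
  fr <- initial_frame(sys1)
  expect_lt(sqrt(sum((fr$coords[6, ] - fr$coords[1, ])^2)), 3.5)
  expect_equal(solvent_contact_count(sys1, fr), 1L)

  set.seed(99)
  cfg$beads <- rbind(
    cfg$beads[cfg$beads$role != "solvent", ],
    data.frame(id = paste0("s", 1:50), role = "solvent", mass = 18,
               x = runif(50, -8, 8), y = runif(50, -8, 8),
               z = runif(50, -8, 8), stringsAsFactors = FALSE))
  sysN <- build_toy_system(cfg)
  fr <- initial_frame(sysN)
  si <- solvent_indices(sysN); ri <- receptor_indices(sysN)
  li <- ligand_indices(sysN)
  manual <- 0L
  for (s in si) {
    near_rec <- any(vapply(ri, function(r)
      sqrt(sum((fr$coords[s, ] - fr$coords[r, ])^2)) < 4, logical(1)))
    near_lig <- any(vapply(li, function(l)
      sqrt(sum((fr$coords[s, ] - fr$coords[l, ])^2)) < 3.5, logical(1)))
    if (near_rec && near_lig) manual <- manual + 1L
  }
  expect_equal(solvent_contact_count(sysN, fr), manual)
})
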