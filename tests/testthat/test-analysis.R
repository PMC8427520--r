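test_that("superposition recovers identity and known rigid transforms", {
  set.seed(11)
  ref <- matrix(runif(30, -10, 10), 10, 3)

  ident <- superpose(ref, ref)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ident$rmsd, 0, tolerance = 1e-12)

  for (rep in 1:5) {
    rot <- random_rotation()
    shift <- runif(3, -15, 15)
    mobile <- t(rot %*% t(ref)) + matrix(shift, 10, 3, byrow = TRUE)
    fit <- superpose(mobile, ref)
    expect_equal(fit$rmsd, 0, tolerance = 1e-10)
    expect_equal(apply_transform(mobile, fit), ref, tolerance = 1e-9)
    # recovered rotation inverts the applied one
    expect_equal(fit$rotation %*% rot, diag(3), tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  }

  expect_error(superpose(ref[1:2, ], ref[1:2, ]),
               class = "sumdr_validation_error")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line + 1), class = "sumdr_validation_error")
})

test_that("superposition agrees with an independent quaternion oracle", {
  set.seed(12)
  for (rep in 1:20) {
    a <- matrix(rnorm(30, sd = 5), 10, 3)
    b <- matrix(rnorm(30, sd = 5), 10, 3)
    fit <- superpose(a, b)
    oracle <- quaternion_superpose(a, b)
    expect_equal(fit$rmsd, oracle$rmsd, tolerance = 1e-9)
    expect_equal(fit$rotation, oracle$rotation, tolerance = 1e-6)
  }
})

test_that("rmsd matches its definition and is symmetric under fitting", {
  a <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(rmsd(a, a), 0)

  b <- a
  b[1, ] <- c(2, 0, 0)  # one of two particles displaced by 2
  expect_equal(rmsd(b, a, selection = 1), 2)
  expect_equal(rmsd(b, a), sqrt((4 + 0) / 2))

  set.seed(13)
  p <- matrix(rnorm(30), 10, 3)
  q <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(p, q, fit = TRUE), rmsd(q, p, fit = TRUE),
               tolerance = 1e-9)
  expect_error(rmsd(p, q[1:5, ]), class = "sumdr_validation_error")
})

test_that("contact detection is strict at the cutoff and matches brute force", {
  coords <- matrix(c(0, 0, 0,  3.49, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(detect_contacts(coords, 1, 2)), 1)
  coords[2, 1] <- 3.50
  expect_equal(nrow(detect_contacts(coords, 1, 2)), 0)
  expect_equal(nrow(detect_contacts(coords, integer(0), 2)), 0)
  expect_error(detect_contacts(coords, 1:2, 2), class = "sumdr_validation_error")

  set.seed(14)
  for (rep in 1:10) {
    x <- matrix(runif(300, 0, 12), 100, 3)
    a <- 1:50; b <- 51:100
    got <- detect_contacts(x, a, b, 3.5)
    expect_equal(nrow(got), contacts_oracle(x, a, b, 3.5))
    expect_true(all(got$distance < 3.5))
  }
})

test_that("hydrogen bonds require both the distance and the angle criterion", {
  # D at origin, H on the D-A axis, A at 2.9: ideal collinear bond
  coords <- matrix(c(0, 0, 0,  1, 0, 0,  2.9, 0, 0), 3, 3, byrow = TRUE)
  dh <- data.frame(donor = 1, hydrogen = 2)
  expect_equal(nrow(detect_hbonds(coords, dh, acceptors = 3)), 1)

  far <- coords; far[3, 1] <- 3.6
  expect_equal(nrow(detect_hbonds(far, dh, acceptors = 3)), 0)

  # close D...A but a D-H...A angle of only 100 degrees
  bent <- coords
  theta <- 80 * pi / 180  # places A so that the angle at H is 100 degrees
  bent[3, ] <- bent[2, ] + 2.2 * c(cos(theta), sin(theta), 0)
  expect_lt(sqrt(sum((bent[3, ] - bent[1, ])^2)), 3.5)
  expect_equal(nrow(detect_hbonds(bent, dh, acceptors = 3)), 0)

  expect_error(detect_hbonds(coords, data.frame(donor = NA, hydrogen = 2), 3),
               class = "sumdr_validation_error")

  set.seed(15)
  for (rep in 1:10) {
    x <- matrix(runif(90, 0, 8), 30, 3)
    dh <- data.frame(donor = 1:10, hydrogen = 11:20)
    acc <- 21:30
    got <- detect_hbonds(x, dh, acc)
    expect_equal(nrow(got), hbonds_oracle(x, dh, acc, 3.5, 120))
  }
})

test_that("persistency pools frames over replicas and matches a recount", {
  sys <- build_toy_system(minimal_binding_config(lig_pos = c(0, 0, 0)))
  li <- ligand_indices(sys); ri <- receptor_indices(sys)
  ext <- function(frame) unique(detect_contacts(frame$coords, ri, li, 4.5)$i)

  base <- initial_frame(sys)$coords
  mk <- function(offsets) {
    coords <- array(0, c(length(offsets), nrow(base), 3))
    for (i in seq_along(offsets)) {
      x <- base; x[1, 1] <- x[1, 1] + offsets[i]
      coords[i, , ] <- x
    }
    make_trajectory(50 * seq_along(offsets), coords)
  }
  # ligand within 4.5 A of rec1 (at x = 4) only in the first frame of rep 1
  rep1 <- mk(c(0, 30))
  rep2 <- mk(c(30, 30))
  tab <- persistency(list(rep1, rep2), ext, ids = ri)
  expect_equal(tab$n_frames_total, rep(4L, nrow(tab)))
  # the interaction exists in 1 of the 4 merged frames
  expect_equal(max(tab$percent), 25)

  always <- persistency(mk(c(0, 0, 0)), ext)
  expect_true(all(always$percent == 100))

  # invariant to replica order and to merging
  t_a <- persistency(list(rep1, rep2), ext, ids = ri)
  t_b <- persistency(list(rep2, rep1), ext, ids = ri)
  expect_equal(t_a[order(t_a$id), c("id", "percent")],
               t_b[order(t_b$id), c("id", "percent")],
               ignore_attr = TRUE)

  set.seed(16)
  for (rep in 1:5) {
    offs <- runif(6, 0, 35)
    reps <- list(mk(offs[1:3]), mk(offs[4:6]))
    tab <- persistency(reps, ext, ids = ri)
    manual <- sapply(as.character(ri), function(id) {
      hits <- 0
      for (tr in reps) for (i in seq_len(n_frames(tr)))
        if (id %in% as.character(ext(get_frame(tr, i)))) hits <- hits + 1
      100 * hits / 6
    })
    expect_equal(tab$percent[match(names(manual), tab$id)],
                 unname(manual))
  }
})

test_that("water occupancy maps fractions of frames per voxel", {
  nb <- 3
  mk_traj <- function(sol_positions) {
    nf <- length(sol_positions)
    coords <- array(0, c(nf, nb, 3))
    for (i in seq_len(nf)) {
      coords[i, 1, ] <- c(-5, -5, -5)   # ligand parked outside the grid
      coords[i, 2, ] <- c(-6, -6, -6)
      coords[i, 3, ] <- sol_positions[[i]]
    }
    make_trajectory(seq_len(nf), coords)
  }
  fixed <- mk_traj(rep(list(c(0.5, 0.5, 0.5)), 4))
  g <- water_occupancy(fixed, solvent = 3, lower = c(0, 0, 0),
                       upper = c(3, 3, 3), spacing = 1)
  expect_equal(g$occupancy[1, 1, 1], 1)
  expect_equal(sum(g$occupancy), 1)

  half <- mk_traj(list(c(0.5, 0.5, 0.5), c(10, 10, 10),
                       c(0.5, 0.5, 0.5), c(10, 10, 10)))
  gh <- water_occupancy(half, solvent = 3, lower = c(0, 0, 0),
                        upper = c(3, 3, 3), spacing = 1)
  expect_equal(gh$occupancy[1, 1, 1], 0.5)

  spots <- hydrated_spots(gh, threshold = 0.5)
  expect_equal(nrow(spots), 1)
  expect_equal(unlist(spots[1, c("x", "y", "z")]), c(x = 0.5, y = 0.5, z = 0.5))

  set.seed(17)
  sols <- replicate(20, list(runif(3, -1, 4)))
  tr <- mk_traj(sols)
  g2 <- water_occupancy(tr, solvent = 3, lower = c(0, 0, 0),
                        upper = c(3, 3, 3), spacing = 1)
  expect_equal(g2$occupancy,
               occupancy_oracle(list(tr), 3, c(0, 0, 0), c(3, 3, 3), 1))
})

test_that("energy landscapes bin counts, mean energies and depths correctly", {
  # all frames in one bin: depth 0
  lm1 <- energy_landscape(rep(1.2, 10), rep(3.4, 10), rnorm(10))
  expect_equal(sum(lm1$counts), 10)
  expect_equal(lm1$depth[lm1$counts > 0], 0)

  # two equally populated bins sit kB*T*ln(2) above the single-bin case
  lm2 <- energy_landscape(c(rep(0.5, 5), rep(1.5, 5)), rep(0.5, 10),
                          rep(0, 10), temperature = 300)
  d <- lm2$depth[lm2$counts > 0]
  expect_equal(d[1], d[2])
  expect_equal(d[1], kB * 300 * log(2))

  # per-bin mean energy is the arithmetic mean of member energies
  e <- c(1, 2, 3, 10, 20)
  lm3 <- energy_landscape(c(0.1, 0.2, 0.3, 1.5, 1.6), rep(0.5, 5), e)
  expect_equal(lm3$mean_energy[lm3$counts > 0], c(2, 15))
  expect_true(all(is.na(lm3$mean_energy[lm3$counts == 0])))

  expect_error(energy_landscape(1:3, 1:2, 1:3),
               class = "sumdr_validation_error")
})
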