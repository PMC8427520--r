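# Independent oracles and small reusable systems for the test suite.

kB <- 0.0019872041
kB_vel <- kB * 418.4

# --- small systems -------------------------------------------------------

minimal_binding_config <- function(lig_pos = c(30, 0, 0), depth = 5) {
  list(
    beads = rbind(
      data.frame(id = "lig", role = "ligand", mass = 20,
                 x = lig_pos[1], y = lig_pos[2], z = lig_pos[3],
                 stringsAsFactors = FALSE),
      data.frame(id = paste0("rec", 1:4), role = "receptor", mass = 100,
                 x = c(4, -4, 0, 0), y = c(0, 0, 4, -4), z = 0,
                 stringsAsFactors = FALSE)),
    potential = list(funnel = list(depth = depth, width = 2.5),
                     repulsion = list(epsilon = 2, cutoff = 2.5),
                     sphere = list(radius = 40, k = 10)),
    site_center = c(0, 0, 0),
    temperature = 300, friction = 250, timestep = 0.01)
}

harmonic_system <- function(k = 2, mass = 20, temperature = 300,
                            friction = 5) {
  build_toy_system(list(
    beads = data.frame(id = c("l", "r"), role = c("ligand", "receptor"),
                       mass = c(mass, 100), x = c(0, 50), y = 0, z = 0,
                       stringsAsFactors = FALSE),
    potential = list(harmonic = list(k = k)),
    site_center = c(0, 0, 0),
    temperature = temperature, friction = friction, timestep = 0.01))
}

# deterministic engine: ligand drifts toward the site at constant speed,
# everything else frozen; used to test the supervision loop in isolation
drift_engine <- function(rate = 0.02) {
  function(system, state, duration, save_interval, seed) {
    n_save <- round(duration / save_interval)
    li <- ligand_indices(system)
    site <- system$site_center
    nb <- nrow(state$coords)
    coords <- array(0, c(n_save, nb, 3))
    x <- state$coords
    for (i in seq_len(n_save)) {
      d <- site - colMeans(x[li, , drop = FALSE])
      dn <- sqrt(sum(d^2))
      step <- if (dn > 1e-9) d / dn * min(rate * save_interval, dn) else c(0, 0, 0)
      x[li, ] <- sweep(x[li, , drop = FALSE], 2, -step)
      coords[i, , ] <- x
    }
    make_trajectory(times = state$time + save_interval * seq_len(n_save),
                    coords = coords,
                    velocities = array(0, c(n_save, nb, 3)))
  }
}

# --- closed-form / brute-force oracles -----------------------------------

slope_normal_equations <- function(t, y) {
  n <- length(t)
  (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
}

schedule_oracle <- function(r, dt0, nt, d) {
  if (r <= d[1]) return(dt0)
  if (r <= d[2]) return(dt0 * nt[1])
  if (r <= d[3]) return(dt0 * nt[2])
  dt0 * nt[3]
}

contacts_oracle <- function(coords, groupA, groupB, cutoff) {
  hits <- 0L
  for (i in groupA) for (j in groupB) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff) hits <- hits + 1L
  }
  hits
}

hbonds_oracle <- function(coords, donor_h, acceptors, dist_cut, ang_cut) {
  out <- 0L
  for (r in seq_len(nrow(donor_h))) {
    d <- donor_h$donor[r]; h <- donor_h$hydrogen[r]
    for (a in acceptors) {
      if (a == d) next
      da <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (da > dist_cut) next
      u <- coords[d, ] - coords[h, ]
      v <- coords[a, ] - coords[h, ]
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang >= ang_cut) out <- out + 1L
    }
  }
  out
}

occupancy_oracle <- function(traj_list, solvent, lower, dims, spacing) {
  counts <- array(0L, dims)
  total <- 0L
  for (tr in traj_list) for (f in seq_len(n_frames(tr))) {
    total <- total + 1L
    seen <- character(0)
    for (s in solvent) {
      p <- tr$coords[f, s, ]
      ix <- floor((p - lower) / spacing) + 1
      if (any(ix < 1) || any(ix > dims)) next
      key <- paste(ix, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      counts[ix[1], ix[2], ix[3]] <- counts[ix[1], ix[2], ix[3]] + 1L
    }
  }
  counts / total
}

# Horn's quaternion absolute-orientation method: an independent check on
# the SVD-based Kabsch fit
quaternion_superpose <- function(mobile, reference) {
  cp <- colMeans(mobile); cq <- colMeans(reference)
  p <- sweep(mobile, 2, cp); q <- sweep(reference, 2, cq)
  s <- crossprod(p, q)
  n4 <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],       s[3,1]-s[1,3],       s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],       s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],       -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],       s[2,3]+s[3,2],       -s[1,1]-s[2,2]+s[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(n4, symmetric = TRUE)
  qv <- ev$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  moved <- p %*% t(rot)
  list(rotation = rot,
       rmsd = sqrt(mean(rowSums((moved - q)^2))))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

# interaction-energy recomputation, term by term, straight from definitions
interaction_energy_oracle <- function(system, frame) {
  e <- 0
  li <- ligand_indices(system)
  ri <- receptor_indices(system)
  pot <- system$potential
  for (i in li) {
    r2 <- sum((frame$coords[i, ] - system$site_center)^2)
    if (!is.null(pot$funnel))
      e <- e - pot$funnel$depth * exp(-r2 / (2 * pot$funnel$width^2))
    if (!is.null(pot$harmonic))
      e <- e + 0.5 * pot$harmonic$k * r2
    for (j in ri) {
      if (is.null(pot$repulsion)) next
      r <- sqrt(sum((frame$coords[i, ] - frame$coords[j, ])^2))
      if (r < pot$repulsion$cutoff)
        e <- e + pot$repulsion$epsilon * (1 - r / pot$repulsion$cutoff)^2
    }
  }
  e
}

random_frame <- function(n, spread = 10) {
  make_frame(0, matrix(runif(3 * n, -spread, spread), n, 3))
}
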