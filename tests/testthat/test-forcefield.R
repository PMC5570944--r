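# Energies, forces, Langevin propagation, mask locality.

test_that("LJ pair energy matches the closed form and the mask zeroes it", {
  # minimum of eps((r0/r)^12 - 2 (r0/r)^6) is -eps at r = r0
  expect_equal(lj_pair_energy(4.0), -0.25)
  expect_identical(lj_pair_energy(3.0, masked = TRUE), 0)
  # hand evaluation at r = 2, r0 = 4: 0.25 * (2^12 - 2 * 2^6) = 992
  expect_equal(lj_pair_energy(2.0), 0.25 * (4096 - 128))
  expect_identical(lj_pair_energy(11.0), 0) # beyond the 10.5 A cutoff
  expect_error(lj_pair_energy(0), "non-positive")
  expect_error(lj_pair_energy(-1), "non-positive")
})

test_that("restraint energy reproduces hand-computed harmonic values", {
  x <- rbind(c(0, 0, 0), c(2.038, 0, 0))
  rs <- distance_restraint(c(1, 2))
  expect_equal(restraint_energy(x, rs, alpha = 1), 0)
  x2 <- rbind(c(0, 0, 0), c(3.038, 0, 0)) # unit deviation
  expect_equal(restraint_energy(x2, rs, alpha = 1), 166)
  expect_equal(restraint_energy(x2, rs, alpha = 1 / 200), 0.83)
  expect_error(restraint_energy(x2, distance_restraint(c(1, 5))),
               "out of range")
  # angle restraint at target is zero; 10 degrees off costs k * (10 pi/180)^2
  xa <- rbind(c(1.8, 0, 0), c(0, 0, 0), c(1.8 * cos(pi * 113.7 / 180),
                                          1.8 * sin(pi * 113.7 / 180), 0))
  ra <- angle_restraint(c(1, 2, 3), target = 103.7, k = 68)
  expect_equal(restraint_energy(xa, ra, 1), 68 * (10 * pi / 180)^2,
               tolerance = 1e-8)
  # dihedral deviation is taken on the shortest arc
  fb <- four_bead_css_c(2.1, angle = 103.7, dihedral = -170)
  rd <- dihedral_restraint(1:4, target = 170, k = 2)
  expect_equal(restraint_energy(fb$frame$positions, rd, 1),
               2 * (20 * pi / 180)^2, tolerance = 1e-6)
})

test_that("forces equal minus the finite-difference energy gradient for every term type", {
  sys <- random_chain(guanylin_spec(seed = 7))
  top <- set_lj_mask(sys$topology, TRUE)
  pair <- sort(top$reactive_sites[1:2])
  terms <- disulfide_terms(top, pair)
  rs <- disulfide_restraints(top, pair, terms)
  x <- sys$frame$positions
  f <- compute_forces(x, top, rs, alpha = 0.7)
  h <- 1e-5
  set.seed(1)
  for (i in sample(nrow(x), 5)) {
    for (c in 1:3) {
      xp <- x; xp[i, c] <- xp[i, c] + h
      xm <- x; xm[i, c] <- xm[i, c] - h
      fd <- -(energy_breakdown(xp, top, rs, 0.7)$total -
                energy_breakdown(xm, top, rs, 0.7)$total) / (2 * h)
      expect_equal(f[i, c], fd, tolerance = 1e-4)
    }
  }
  # dihedral gradient specifically, on the four-bead fixture
  fb <- four_bead_css_c(2.2, angle = 100, dihedral = 35)
  rd <- merge_restraints(dihedral_restraint(c(1, 2, 3, 4), target = 90,
                                            k = 3.5),
                         angle_restraint(c(1, 2, 3)))
  xb <- fb$frame$positions
  fbmat <- compute_forces(xb, fb$topology, rd, alpha = 1)
  for (i in 1:4) {
    for (c in 1:3) {
      xp <- xb; xp[i, c] <- xp[i, c] + h
      xm <- xb; xm[i, c] <- xm[i, c] - h
      fd <- -(energy_breakdown(xp, fb$topology, rd, 1)$total -
                energy_breakdown(xm, fb$topology, rd, 1)$total) / (2 * h)
      expect_equal(fbmat[i, c], fd, tolerance = 1e-4)
    }
  }
})

test_that("an isolated unmasked pair at r0 feels no LJ force", {
  top <- cg_topology(particles = data.frame(name = c("SG", "SG"),
                                            resid = 1:2,
                                            mass = c(32.06, 32.06)),
                     bonds = NULL, residue_labels = c("ALA", "ALA"))
  x <- rbind(c(0, 0, 0), c(4, 0, 0))
  f <- compute_forces(x, top)
  expect_equal(max(abs(f)), 0)
  # masked pair: no LJ force at any distance
  tb <- two_bead_system(3.0)
  expect_equal(max(abs(compute_forces(tb$frame, tb$topology))), 0)
})

test_that("overlapping particles raise an invalid-geometry error", {
  top <- free_sulfur_topology(2, integer())
  x <- rbind(c(0, 0, 0), c(1e-8, 0, 0))
  expect_error(energy_breakdown(x, top), "overlap")
})

test_that("gamma = 0 reduces to velocity Verlet and conserves energy", {
  p <- data.frame(name = c("CA", "CA"), resid = 1:2, mass = c(32, 32))
  b <- data.frame(i = 1, j = 2, k = 1, r0 = 3)
  top <- cg_topology(p, b, c("ALA", "ALA"))
  fr <- new_frame(0, rbind(c(-1.75, 0, 0), c(1.75, 0, 0)),
                  rng_state = seed_rng(1))
  seg <- run_segment(fr, top, length_ps = 20, frame_interval = 0.02,
                     dt = 0.002, gamma = 0) # 1e4 steps
  E <- vapply(seg$frames, function(f) {
    0.5 * sum(32 * f$velocities^2) / 418.4 + energy_breakdown(f, top)$total
  }, numeric(1))
  expect_lt((max(E) - min(E)) / abs(E[1]), 1e-4)
})

test_that("the thermostat recovers the target kinetic temperature", {
  sys <- random_chain(guanylin_spec(seed = 4))
  top <- set_lj_mask(sys$topology, TRUE)
  seg <- run_segment(sys$frame, top, length_ps = 400, frame_interval = 1,
                     gamma = 2, temperature = 293)
  Tk <- vapply(seg$frames[101:400], kinetic_temperature,
               masses = top$particles$mass, numeric(1))
  se <- sd(Tk) / sqrt(length(Tk))
  expect_lt(abs(mean(Tk) - 293), 3 * se)
})

test_that("identical frame and RNG state yield a bitwise identical successor", {
  sys <- random_chain(guanylin_spec(seed = 9))
  top <- set_lj_mask(sys$topology, TRUE)
  a <- langevin_step(sys$frame, top)
  b <- langevin_step(sys$frame, top)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  expect_identical(a$rng_state, b$rng_state)
  # and the state advances (successive steps differ)
  c2 <- langevin_step(a, top)
  expect_false(identical(a$positions, c2$positions))
})

test_that("the mask changes no interaction outside the reactive set", {
  sys <- random_chain(guanylin_spec(seed = 11))
  top_on <- set_lj_mask(sys$topology, TRUE)
  top_off <- set_lj_mask(sys$topology, FALSE)
  x <- sys$frame$positions
  e_on <- energy_breakdown(x, top_on)
  e_off <- energy_breakdown(x, top_off)
  # bonded terms untouched
  expect_identical(e_on$bond, e_off$bond)
  expect_identical(e_on$angle, e_off$angle)
  # the LJ difference is exactly the masked pairs' pairwise energy
  masked_sum <- sum(apply(top_on$lj_mask, 1, function(p)
    lj_pair_energy(sqrt(sum((x[p[1], ] - x[p[2], ])^2)), top_on$lj)))
  expect_equal(e_off$lj - e_on$lj, masked_sum, tolerance = 1e-10)
})

test_that("shrunk_r0 mode matches masked mode for all non-reactive pairs", {
  spec <- guanylin_spec(seed = 12)
  sys <- random_chain(spec)
  x <- sys$frame$positions
  top_m <- set_lj_mask(sys$topology, TRUE)
  top_s <- sys$topology
  top_s$lj_mode <- "shrunk_r0"
  top_s <- set_lj_mask(top_s, TRUE)
  e_m <- energy_breakdown(x, top_m)
  e_s <- energy_breakdown(x, top_s)
  shrunk <- lj_params(r0 = 2, cutoff = 10.5)
  rp <- reactive_pairs(top_m)
  shrunk_sum <- sum(apply(rp, 1, function(p)
    lj_pair_energy(sqrt(sum((x[p[1], ] - x[p[2], ])^2)), shrunk)))
  # shrunk total = masked total + contracted reactive-pair terms
  expect_equal(e_s$lj - e_m$lj, shrunk_sum, tolerance = 1e-10)
})

test_that("escaping particles are reflected back into the confining sphere", {
  top <- free_sulfur_topology(1, integer())
  top$sphere_radius <- 10
  fr <- new_frame(0, matrix(c(9.9, 0, 0), 1, 3),
                  velocities = matrix(c(50, 0, 0), 1, 3),
                  rng_state = seed_rng(1))
  seg <- run_segment(fr, top, length_ps = 2, frame_interval = 0.1,
                     gamma = 0)
  r <- vapply(seg$frames, function(f) sqrt(sum(f$positions^2)), numeric(1))
  expect_true(all(r <= 10 + 1e-9))
})
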