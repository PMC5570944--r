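# Isomer bookkeeping, kinetic footprints, Rg, ensemble RMSD, NOE scoring.

test_that("radius of gyration matches closed forms and is rigid-motion invariant", {
  x <- matrix(1.5, 4, 3) # all particles at one point
  expect_equal(radius_of_gyration(x), 0)
  x2 <- rbind(c(0, 0, 0), c(2, 0, 0)) # two unit masses 2 A apart
  expect_equal(radius_of_gyration(x2), 1)
  # mass weighting pulls Rg toward the heavy particle
  expect_equal(radius_of_gyration(x2, masses = c(3, 1)),
               sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4))
  set.seed(2)
  x3 <- matrix(rnorm(30), 10, 3)
  R <- random_rotation()
  x3r <- sweep(x3 %*% t(R), 2, c(5, -3, 2), "+")
  expect_equal(radius_of_gyration(x3), radius_of_gyration(x3r),
               tolerance = 1e-10)
  expect_error(radius_of_gyration(x3, integer()), "empty")
})

test_that("pairing enumeration counts perfect matchings (double factorial)", {
  expect_length(enumerate_pairings(c(4, 7, 12, 15)), 3)
  expect_length(enumerate_pairings(c(1, 2)), 1)
  expect_length(enumerate_pairings(1:6), 15)
  # brute-force oracle: all permutations of 6 positions, deduplicated
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  canon <- unique(lapply(perms(1:6), function(p) {
    prs <- lapply(seq(1, 5, 2), function(i) sort(p[c(i, i + 1)]))
    prs[order(vapply(prs, `[`, 1, 1))]
  }))
  expect_length(canon, 15)
  expect_error(enumerate_pairings(1:3), "odd")
  # each position used exactly once in every pairing
  for (p in enumerate_pairings(c(4, 7, 12, 15)))
    expect_setequal(unlist(p), c(4, 7, 12, 15))
})

test_that("isomer classification maps the three pairings and partial commitments", {
  expect_equal(classify_isomer(list(c(4, 7), c(12, 15)))$label, "isomer1")
  expect_equal(classify_isomer(list(c(4, 12), c(7, 15)))$label, "isomer2")
  expect_equal(classify_isomer(list(c(15, 4), c(12, 7)))$label, "isomer3")
  p <- classify_isomer(list(c(7, 12)))
  expect_equal(p$label, "partial")
  expect_equal(p$committed_to, "isomer3")
  expect_equal(classify_isomer(list(c(12, 15)))$committed_to, "isomer1")
  expect_equal(classify_isomer(list())$label, "none")
  expect_error(classify_isomer(list(c(4, 7), c(7, 12))), "invalid pairing")
  expect_error(classify_isomer(list(c(4, 5))), "invalid pairing")
  # classification covers each isomer exactly once over all pairings
  labs <- vapply(enumerate_pairings(c(4, 7, 12, 15)),
                 function(p) classify_isomer(p)$label, "")
  expect_setequal(labs, c("isomer1", "isomer2", "isomer3"))
})

test_that("kinetic footprints extract bond times and isomer fractions", {
  ev <- function(times, pairs) {
    do.call(rbind, lapply(seq_along(times), function(i)
      data.frame(time = times[i], frame = NA_integer_,
                 particle_i = 0L, particle_j = 0L,
                 res_i = pairs[[i]][1], res_j = pairs[[i]][2],
                 distance = 2.4, gate_draws = 0L, kind = "formed")))
  }
  logs <- list(ev(c(5000, 203000), list(c(4, 12), c(7, 15))),
               ev(3000, list(c(12, 15))),
               ev(c(1000, 9000), list(c(4, 7), c(12, 15))))
  fp <- kinetic_footprint(logs)
  expect_equal(fp$t_first, c(5000, 3000, 1000))
  expect_equal(fp$t_second, c(203000, NA, 9000))
  expect_equal(fp$isomer, c("isomer2", "partial", "isomer1"))
  s <- attr(fp, "summary")
  expect_equal(s$mean_t_second, mean(c(203000, 9000)))
  expect_equal(sum(s$isomer_fractions), 1)
  # an all-partial ensemble
  fp2 <- kinetic_footprint(list(ev(10, list(c(4, 7)))))
  expect_true(all(fp2$isomer == "partial"))
  expect_true(is.na(fp2$t_second))
})

test_that("ensemble RMSD agrees with the quaternion superposition oracle", {
  set.seed(10)
  for (rep in 1:8) {
    n <- sample(5:20, 1)
    A <- matrix(rnorm(3 * n, sd = 3), n, 3)
    B <- A + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    Brot <- sweep(B %*% t(random_rotation()), 2, rnorm(3, sd = 10), "+")
    expect_equal(superpose(Brot, A)$rmsd, quat_rmsd(Brot, A),
                 tolerance = 1e-8)
  }
  # identical conformers: zero everywhere
  A <- matrix(rnorm(30), 10, 3)
  ens <- ensemble_rmsd(list(A, A, A))
  expect_equal(ens$ensemble_rmsd, 0, tolerance = 1e-10)
  # a pure rotation is removed by superposition
  ens2 <- ensemble_rmsd(list(A, A %*% t(random_rotation())))
  expect_lt(max(ens2$pairwise), 1e-8)
  expect_error(ensemble_rmsd(list(A, matrix(0, 4, 3))), "mismatch")
  expect_error(ensemble_rmsd(list(A)), "at least 2")
})

test_that("NOE deviations follow the bounds and r^-6 ambiguity rules", {
  coords <- rbind("1:HA" = c(0, 0, 0), "2:HA" = c(3, 0, 0),
                  "3:HB1" = c(7, 0, 0), "3:HB2" = c(7, 4, 3))
  # within range
  expect_equal(noe_violation(coords, noe_restraint("1:HA", "2:HA", 2, 4))$mean,
               0)
  # above the upper bound by 1 A
  coords2 <- rbind("1:HA" = c(0, 0, 0), "2:HA" = c(5, 0, 0))
  expect_equal(noe_violation(coords2,
                             noe_restraint("1:HA", "2:HA", 2, 4))$mean, 1)
  # below the lower bound
  coords3 <- rbind("1:HA" = c(0, 0, 0), "2:HA" = c(1, 0, 0))
  expect_equal(noe_violation(coords3,
                             noe_restraint("1:HA", "2:HA", 2, 4))$mean, 1)
  # two equivalent protons each 4 A away: r_eff = (2 * 4^-6)^(-1/6)
  amb <- rbind("1:HA" = c(0, 0, 0), "3:HB1" = c(4, 0, 0),
               "3:HB2" = c(-4, 0, 0))
  v <- noe_violation(amb, noe_restraint("1:HA", "3:HB*", 1, 3))
  r_eff <- (2 * 4^-6)^(-1 / 6)
  expect_equal(r_eff, 3.5636, tolerance = 1e-4)
  expect_equal(v$mean, r_eff - 3, tolerance = 1e-10)
  # deviations combine linearly, normalized per restraint
  rs <- list(noe_restraint("1:HA", "2:HA", 2, 4),
             noe_restraint("1:HA", "3:HB*", 1, 3))
  both <- noe_violation(rbind(coords2, amb[-1, ]), rs)
  expect_equal(both$mean, (1 + (r_eff - 3)) / 2, tolerance = 1e-10)
  expect_error(noe_violation(coords, noe_restraint("9:XX", "1:HA", 1, 2)),
               "unresolvable")
  expect_error(noe_restraint("a", "b", 3, 2), "bounds")
})

test_that("NOE scoring is rigid-motion invariant and monotone in the bounds", {
  set.seed(4)
  coords <- matrix(rnorm(15, sd = 3), 5, 3)
  rownames(coords) <- paste0(1:5, ":HA")
  rs <- list(noe_restraint("1:HA", "3:HA", 2, 3),
             noe_restraint("2:HA", "5:HA", 2, 3.5))
  v1 <- noe_violation(coords, rs)$mean
  moved <- sweep(coords %*% t(random_rotation()), 2, c(8, -2, 1), "+")
  rownames(moved) <- rownames(coords)
  expect_equal(noe_violation(moved, rs)$mean, v1, tolerance = 1e-10)
  expect_gte(v1, 0)
  # tightening any bound never decreases the mean violation
  tighter <- list(noe_restraint("1:HA", "3:HA", 2, 2.5),
                  noe_restraint("2:HA", "5:HA", 2.4, 3.0))
  expect_gte(noe_violation(coords, tighter)$mean, v1)
})

test_that("S-S distance series are symmetric and track every stored frame", {
  sys <- two_bead_system(3.0, seed = 2)
  seg <- run_segment(sys$frame, sys$topology, length_ps = 25,
                     frame_interval = 1)
  d <- ss_distance_series(seg$frames, sys$topology)
  expect_equal(nrow(d), 25)
  expect_equal(ncol(d), 1)
  d12 <- ss_distance_series(seg$frames, sys$topology, pairs = rbind(c(1, 2)))
  d21 <- ss_distance_series(seg$frames, sys$topology, pairs = rbind(c(2, 1)))
  expect_identical(d12[, 1], d21[, 1])
})

test_that("a completed ramp holds the mean S-S distance at the bond length", {
  cfg <- controller_config(ramp = ramp_schedule(40, 5))
  tb <- two_bead_system(2.5, seed = 8)
  ramp <- run_ramp(tb$frame, tb$topology, c(1, 2), schedule = cfg$ramp,
                   config = cfg)
  d <- ss_distance_series(tail(ramp$frames, 20), tb$topology)
  expect_equal(mean(d), 2.038, tolerance = 0.1)
})

test_that("the truncated-octahedron diameter is l sqrt(6)", {
  expect_equal(truncated_octahedron_diameter(1), sqrt(6))
  expect_equal(truncated_octahedron_diameter(56 / sqrt(6)), 56)
  expect_error(truncated_octahedron_diameter(0), "positive")
  l <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(truncated_octahedron_diameter(l)) > 0))
})
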