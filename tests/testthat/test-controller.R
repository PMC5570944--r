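# Capture detection, gating, rewind, ramping, topology mutation, the
# three-stage protocol.

test_that("capture detection returns the earliest crossing with deterministic tie-breaks", {
  top <- free_sulfur_topology(16, c(4, 7, 12, 15))
  # never below the radius -> no capture
  seg <- as_segment(spread_frames(top, 5, list(
    list(frame = 3, pair = c(4, 12), distance = 2.6))))
  expect_null(detect_capture(seg, top, r_c = 2.5))
  # earliest frame wins over a closer later approach
  seg <- as_segment(spread_frames(top, 60, list(
    list(frame = 37, pair = c(4, 12), distance = 2.4),
    list(frame = 52, pair = c(7, 15), distance = 2.3))))
  hit <- detect_capture(seg, top, r_c = 2.5)
  expect_equal(hit$frame_index, 37)
  expect_equal(unname(hit$pair), c(4, 12))
  expect_equal(hit$distance, 2.4)
  # within one frame: smallest distance wins
  seg <- as_segment(spread_frames(top, 12, list(
    list(frame = 10, pair = c(4, 7), distance = 2.45),
    list(frame = 10, pair = c(12, 15), distance = 2.30))))
  hit <- detect_capture(seg, top, r_c = 2.5)
  expect_equal(hit$frame_index, 10)
  expect_equal(unname(hit$pair), c(12, 15))
  # exact distance tie: lexicographically smallest pair
  seg <- as_segment(spread_frames(top, 12, list(
    list(frame = 10, pair = c(4, 7), distance = 2.3),
    list(frame = 10, pair = c(12, 15), distance = 2.3))))
  expect_equal(unname(detect_capture(seg, top, 2.5)$pair), c(4, 7))
  # empty reactive set -> none
  top0 <- free_sulfur_topology(4, integer())
  expect_null(detect_capture(as_segment(spread_frames(top0, 3)), top0))
})

test_that("the reactivity gate is Bernoulli with the configured probability", {
  expect_error(gate_decision(0), "accept_prob")
  expect_error(gate_decision(1.2), "accept_prob")
  set.seed(1)
  expect_true(all(gate_decision(1.0, 1000))) # original protocol
  set.seed(1)
  frac <- mean(gate_decision(0.1, 2e4))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 2e4))
})

test_that("contact frames until acceptance follow the geometric law", {
  set.seed(1)
  draws <- gate_decision(0.02, 1.5e5)
  idx <- which(draws)
  waits <- diff(c(0L, idx)) - 1L # rejected decisions before each success
  expect_equal(mean(waits), (1 - 0.02) / 0.02, tolerance = 0.1)
  brk <- c(seq(0, 200, by = 25), Inf)
  obs <- as.vector(table(cut(waits, brk, right = FALSE)))
  pr <- diff(c(0, pgeom(brk[-1] - 1, 0.02)))
  expect_gt(chisq.test(obs, p = pr)$p.value, 0.01)
})

test_that("lowering the gate probability never accelerates acceptance (coupled draws)", {
  set.seed(3)
  for (rep in 1:50) {
    u <- runif(500)
    first_hi <- which(u < 0.5)[1]
    first_lo <- which(u < 0.05)[1]
    if (!is.na(first_lo)) expect_gte(first_lo, first_hi)
  }
})

test_that("rewind reproduces the crossing frame bitwise and detects divergence", {
  sys <- two_bead_system(3.2, seed = 21)
  seg <- run_segment(sys$frame, sys$topology, length_ps = 50,
                     frame_interval = 1)
  # last frame replays exactly
  got <- rewind_to_crossing(seg, length(seg$frames), sys$topology)
  expect_identical(got$positions, seg$frames[[50]]$positions)
  expect_identical(got$rng_state, seg$frames[[50]]$rng_state)
  # intermediate frame too
  got <- rewind_to_crossing(seg, 17, sys$topology)
  expect_identical(got$positions, seg$frames[[17]]$positions)
  # a perturbed restart state is a fatal reproducibility error
  bad <- seg
  bad$start_frame$rng_state <- seed_rng(999)
  expect_error(rewind_to_crossing(bad, 17, sys$topology),
               "reproducibility")
})

test_that("rewinding to a detected crossing lands within the capture radius", {
  sys <- two_bead_system(3.5, seed = 5)
  sys$topology$sphere_radius <- 8 # confine so an encounter is certain
  seg <- run_segment(sys$frame, sys$topology, length_ps = 500,
                     frame_interval = 1)
  hit <- detect_capture(seg, sys$topology, 2.5)
  expect_false(is.null(hit))
  state <- rewind_to_crossing(seg, hit$frame_index, sys$topology)
  expect_lte(pair_dist(state, hit$pair), 2.5)
})

test_that("a short ramp reaches full scale and records the alpha series", {
  cfg <- controller_config(ramp = ramp_schedule(10, 1))
  tb <- two_bead_system(2.4, seed = 2)
  ramp <- run_ramp(tb$frame, tb$topology, c(1, 2), schedule = cfg$ramp,
                   config = cfg)
  expect_equal(ramp$alphas, (1:10) / 10)
  expect_equal(ramp$alphas[length(ramp$alphas)], 1.0)
  expect_equal(ramp$alphas[1], 1 / 10)
  # the pair is pulled toward the bond length even in a short ramp
  expect_lt(abs(ramp$window_distance[10] - 2.038), 0.5)
  # entering a ramp outside the capture radius is an error
  tb2 <- two_bead_system(3.1)
  expect_error(run_ramp(tb2$frame, tb2$topology, c(1, 2),
                        schedule = cfg$ramp, config = cfg),
               "capture radius")
})

test_that("ramped restraints equal the generic bond exactly at full strength", {
  # two reactive cysteines: before/after energies agree to 1e-6
  sys <- random_chain(chain_spec(6, c(2, 5), seed = 31))
  top <- set_lj_mask(sys$topology, TRUE)
  pair <- sort(top$reactive_sites)
  terms <- disulfide_terms(top, pair)
  rs <- disulfide_restraints(top, pair, terms)
  x <- sys$frame$positions
  e_before <- energy_breakdown(
    x, top, rs, alpha = 1,
    extra_mask = redoxfold:::.prospective_exclusions(top, pair))$total
  top2 <- form_disulfide(top, pair, terms)
  e_after <- energy_breakdown(x, top2)$total
  expect_equal(e_before, e_after, tolerance = 1e-6)

  # four cysteines: the only difference is the re-enabled standard LJ
  # between the newly bonded sulfurs and the remaining reactive ones
  sys4 <- random_chain(guanylin_spec(seed = 32))
  top4 <- set_lj_mask(sys4$topology, TRUE)
  p4 <- sort(top4$reactive_sites[c(1, 3)])
  t4 <- disulfide_terms(top4, p4)
  x4 <- sys4$frame$positions
  e_b <- energy_breakdown(
    x4, top4, disulfide_restraints(top4, p4, t4), alpha = 1,
    extra_mask = redoxfold:::.prospective_exclusions(top4, p4))$total
  top4b <- form_disulfide(top4, p4, t4)
  e_a <- energy_breakdown(x4, top4b)$total
  unmasked <- expand.grid(p4, setdiff(top4$reactive_sites, p4))
  lj_new <- sum(apply(unmasked, 1, function(p)
    lj_pair_energy(sqrt(sum((x4[p[1], ] - x4[p[2], ])^2)), top4$lj)))
  expect_equal(e_a - e_b, lj_new, tolerance = 1e-6)
})

test_that("bonding one pair removes exactly its mask entries", {
  sys <- random_chain(guanylin_spec(seed = 33))
  top <- set_lj_mask(sys$topology, TRUE)
  sites <- top$reactive_sites # SG of residues 4, 7, 12, 15
  pair <- sites[c(1, 3)]      # the 4-12 bridge
  top2 <- form_disulfide(top, pair)
  keys <- apply(top2$lj_mask, 1, paste, collapse = "-")
  gone <- c(paste(sort(c(sites[1], sites[2])), collapse = "-"),
            paste(sort(c(sites[1], sites[4])), collapse = "-"),
            paste(sort(c(sites[3], sites[2])), collapse = "-"),
            paste(sort(c(sites[3], sites[4])), collapse = "-"),
            paste(sort(pair), collapse = "-"))
  expect_false(any(gone %in% keys))
  expect_equal(keys, paste(sort(sites[c(2, 4)]), collapse = "-"))
})

test_that("reduction is probabilistic, reversible, and favors the bonded state when slow", {
  fb <- four_bead_css_c(2.1)
  top <- fb$topology
  top <- form_disulfide(top, c(2, 3))
  # base_prob = 0: never reduced
  set.seed(1)
  r0 <- maybe_reduce(top, fb$frame, reduction_config(TRUE, 0))
  expect_equal(nrow(r0$topology$disulfides), 1)
  expect_equal(nrow(r0$events), 0)
  # base_prob = 1, constant exposure: reduced at the first decision
  r1 <- maybe_reduce(top, fb$frame, reduction_config(TRUE, 1))
  expect_equal(nrow(r1$topology$disulfides), 0)
  expect_equal(r1$events$kind, "reduced")
  expect_equal(r1$topology$reactive_sites, c(2, 3))
  # two-state occupancy: slow reduction vs fast formation favors bonded
  set.seed(7)
  p_form <- 0.5; bonded_time <- 0
  state <- top
  for (step in 1:400) {
    if (nrow(state$disulfides) == 0) {
      if (gate_decision(p_form)) state <- form_disulfide(state, c(2, 3))
    } else {
      state <- maybe_reduce(state, fb$frame,
                            reduction_config(TRUE, 0.05))$topology
    }
    bonded_time <- bonded_time + (nrow(state$disulfides) > 0)
  }
  # Markov occupancy p_form/(p_form + p_r) ~ 0.91 >> 0.5
  expect_gt(bonded_time / 400, 0.5)
})

test_that("a run with no reactive sites equals a conventional simulation", {
  spec <- chain_spec(6, integer(), seed = 41)
  sys <- random_chain(spec)
  cfg <- controller_config(seed = 41,
                           stage_lengths = c(equilibration = 20,
                                             folding = 50, extension = 30),
                           segment_length = 50)
  run <- run_oxidative_folding(sys, cfg)
  expect_equal(run$status, "completed")
  expect_equal(nrow(run$events), 0)
  plain <- run_segment(sys$frame, sys$topology, length_ps = 50,
                       frame_interval = 1)
  expect_identical(run$final_frame$positions,
                   plain$frames[[50]]$positions)
})

test_that("the folding loop forms bonds in order and within the capture radius", {
  sys <- random_chain(guanylin_spec(seed = 55))
  cfg <- controller_config(seed = 55,
                           stage_lengths = c(equilibration = 100,
                                             folding = 3000,
                                             extension = 100),
                           segment_length = 500,
                           ramp = ramp_schedule(20, 5))
  run <- run_oxidative_folding(sys, cfg, store_frames = FALSE)
  formed <- run$events[run$events$kind == "formed", ]
  expect_gt(nrow(formed), 0)
  expect_true(all(formed$distance <= 2.5))
  expect_true(all(diff(formed$time) > 0))
  if (run$status == "completed") {
    expect_equal(length(run$topology$reactive_sites), 0)
    expect_equal(nrow(run$topology$disulfides), 2)
  }
})

test_that("a folding budget too short to bond reports unbonded-remaining", {
  sys <- random_chain(guanylin_spec(seed = 56))
  cfg <- controller_config(seed = 56,
                           stage_lengths = c(equilibration = 10,
                                             folding = 20, extension = 10),
                           segment_length = 20)
  run <- run_oxidative_folding(sys, cfg, store_frames = FALSE)
  if (nrow(run$events) == 0) {
    expect_equal(run$status, "unbonded-remaining")
    expect_equal(length(run$topology$reactive_sites), 4)
  } else succeed()
})

test_that("the controller machinery leaves the pre-capture trajectory bitwise untouched", {
  sys <- random_chain(guanylin_spec(seed = 60))
  cfg <- controller_config(seed = 60,
                           stage_lengths = c(equilibration = 100,
                                             folding = 2000, extension = 0),
                           segment_length = 100)
  run <- run_oxidative_folding(sys, cfg, store_frames = TRUE)
  formed <- run$events[run$events$kind == "formed", ]
  expect_gt(nrow(formed), 0) # the comparison below needs a capture
  times <- vapply(run$frames, function(f) f$time, numeric(1))
  k_bond <- which(times == formed$time[1])[1]

  # control: plain propagation of the same seeds, no controller attached
  frame <- sys$frame
  frame$rng_state <- seed_rng(cfg$seed)
  top <- set_lj_mask(sys$topology, FALSE)
  ctrl <- run_segment(frame, top, length_ps = 100, frame_interval = 1)
  frames <- ctrl$frames
  frame <- frames[[length(frames)]]
  top <- set_lj_mask(sys$topology, TRUE)
  while (length(frames) < k_bond) {
    seg <- run_segment(frame, top, length_ps = 100, frame_interval = 1)
    frames <- c(frames, seg$frames)
    frame <- seg$frames[[length(seg$frames)]]
  }
  for (f in seq_len(k_bond))
    expect_identical(run$frames[[f]]$positions, frames[[f]]$positions)
})
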