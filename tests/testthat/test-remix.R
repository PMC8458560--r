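test_that("step pool: qualifying steps counted, straight tracks rejected", {
  # straight 5-position track: every joint collinear, no plane angle
  expect_error(build_step_pool(straight_track(12, n_pos = 5)), "empty")

  # generic 5-position track: exactly 2 triplets (steps 3 and 4)
  set.seed(21)
  g <- generate_cohort(cohort_spec(n_tracks = 1, duration = 80))
  pool <- build_step_pool(g)
  expect_equal(nrow(pool), 2)
  expect_equal(pool$step, c(3, 4))
})

test_that("pool size equals a brute-force per-step count", {
  set.seed(22)
  cohort <- generate_cohort(cohort_preset("WT", n_tracks = 25))
  pool <- build_step_pool(cohort)
  # independent counting oracle: walk every track, count steps s >= 3 whose
  # entry joint has a defined turning AND plane angle
  count <- 0L
  for (m in tcellscan:::track_matrices(cohort)) {
    tu <- tcellscan:::.turning_angles_mat(m, 20)
    pl <- tcellscan:::.plane_angles_mat(m, 20)
    for (s in 3:(nrow(m) - 1))
      if (!is.na(tu[s - 1]) && !is.na(pl[s - 2])) count <- count + 1L
  }
  expect_equal(nrow(pool), count)
  # triplet components agree with direct recomputation at their provenance
  i <- c(1L, nrow(pool))
  for (k in i) {
    m <- tcellscan:::track_matrices(cohort)[[pool$track_id[k]]]
    s <- pool$step[k]
    expect_equal(pool$speed[k], tcellscan:::.step_speeds_mat(m, 20)[s])
    expect_equal(pool$turn[k], tcellscan:::.turning_angles_mat(m, 20)[s - 1])
    expect_equal(pool$plane[k], tcellscan:::.plane_angles_mat(m, 20)[s - 2])
  }
})

test_that("measured roughness matches hand values and a brute-force loop", {
  # helix: constant speed and constant turning angle -> roughness (0, 0)
  hx <- helix_track(n_pos = 12)
  r <- measured_roughness(hx)
  expect_equal(r$speed_roughness, 0, tolerance = 1e-12)
  expect_equal(r$turn_roughness, 0, tolerance = 1e-12)

  # speeds 6, 12, 6 um/min in a straight line: mean((6)^2, (-6)^2) = 36
  m <- cbind(cumsum(c(0, 2, 4, 2)), 0, 0)
  r2 <- measured_roughness(make_track(m))
  expect_equal(r2$speed_roughness, 36)

  # oracle equivalence on a synthetic cohort
  set.seed(23)
  cohort <- generate_cohort(cohort_preset("WT", n_tracks = 10))
  got <- measured_roughness(cohort)
  ds <- dtu <- numeric(0)
  for (mm in tcellscan:::track_matrices(cohort)) {
    sp <- tcellscan:::.step_speeds_mat(mm, 20)
    for (i in seq_len(length(sp) - 1)) ds <- c(ds, (sp[i + 1] - sp[i])^2)
    tu <- tcellscan:::.turning_angles_mat(mm, 20)
    for (i in seq_len(length(tu) - 1))
      if (!is.na(tu[i]) && !is.na(tu[i + 1]))
        dtu <- c(dtu, (tu[i + 1] - tu[i])^2)
  }
  expect_equal(got$speed_roughness, mean(ds))
  expect_equal(got$turn_roughness, mean(dtu))
})

test_that("exchange returns an already-smooth sequence unchanged", {
  smooth <- data.frame(speed = c(10, 10.1, 10.2, 10.3), turn = c(30, 31, 32, 33),
                       plane = c(0, 5, -5, 0))
  out <- remix_exchange(smooth, list(speed_roughness = 1, turn_roughness = 10))
  expect_equal(out$speed, smooth$speed)
  expect_equal(attr(out, "n_accepted"), 0)
  expect_equal(attr(out, "n_proposals"), 0)
})

test_that("exchange reaches the enumerated optimum for a 4-step sequence", {
  # speeds 1,10,1,10: brute-force enumeration of all orders gives minimum
  # roughness mean((delta speed)^2) = 27, attained by sorted-like orders
  perms <- unique(t(apply(expand.grid(1:4, 1:4, 1:4, 1:4), 1, function(p)
    if (length(unique(p)) == 4) p else rep(NA, 4))))
  perms <- perms[stats::complete.cases(perms), , drop = FALSE]
  sp <- c(1, 10, 1, 10)
  rough <- apply(perms, 1, function(p) mean(diff(sp[p])^2))
  expect_equal(min(rough), 27)

  df <- data.frame(speed = sp, turn = c(20, 20, 20, 20), plane = 0)
  set.seed(24)
  out <- remix_exchange(df, list(speed_roughness = 27, turn_roughness = 1e6))
  expect_lte(attr(out, "speed_roughness"), 27)
  expect_equal(attr(out, "speed_roughness"), mean(diff(out$speed)^2))
})

test_that("exchange converges on resampled pools and conserves the multiset", {
  set.seed(25)
  cohort <- generate_cohort(cohort_preset("WT", n_tracks = 20))
  pool <- build_step_pool(cohort)
  targets <- measured_roughness(cohort)
  for (run in 1:20) {
    sampled <- pool[sample.int(nrow(pool), 50, replace = TRUE), ]
    out <- remix_exchange(sampled, targets)
    # stopping rule satisfied
    expect_lte(attr(out, "speed_roughness"), targets$speed_roughness)
    expect_lte(attr(out, "turn_roughness"), targets$turn_roughness)
    # exchange is a permutation: multisets conserved
    expect_equal(sort(out$speed), sort(sampled$speed))
    expect_equal(sort(out$turn), sort(sampled$turn))
    expect_equal(sort(out$plane), sort(sampled$plane))
    # objective strictly decreases over accepted swaps
    tr <- attr(out, "objective_trace")
    if (length(tr) > 1) expect_true(all(diff(tr) < 0))
    # local-delta bookkeeping agrees with full recomputation
    rr <- tcellscan:::sequence_roughness(out)
    expect_equal(attr(out, "speed_roughness"), rr$speed_roughness,
                 tolerance = 1e-9)
    expect_equal(attr(out, "turn_roughness"), rr$turn_roughness,
                 tolerance = 1e-9)
  }
})

test_that("exchange errors when targets are unreachable in the budget", {
  df <- data.frame(speed = c(1, 30, 1, 30, 1, 30), turn = 20, plane = 0)
  expect_error(remix_exchange(df, list(speed_roughness = 1e-6,
                                       turn_roughness = 1e-6),
                              max_proposals = 100),
               "did not reach")
})

test_that("reconstruction: straight line, closed square, and round trip", {
  set.seed(26)
  n <- 12
  straight <- data.frame(speed = 9, turn = 0, plane = 0)[rep(1, n), ]
  tt <- reconstruct_track(straight)
  m <- tcellscan:::track_matrices(tt)[[1]]
  expect_equal(sqrt(sum((m[n + 1, ] - m[1, ])^2)), 9 / 60 * 20 * n,
               tolerance = 1e-9)

  square <- data.frame(speed = 15, turn = 90, plane = 0)[rep(1, 4), ]
  sq <- tcellscan:::track_matrices(reconstruct_track(square))[[1]]
  expect_equal(sq[5, ], sq[1, ], tolerance = 1e-9, ignore_attr = TRUE)

  # round trip: extracting (speed, turn, plane) from the reconstructed
  # positions reproduces the triplets (the initial random frame consumes
  # the first turn and the first two plane angles)
  trip <- data.frame(speed = stats::runif(60, 5, 25),
                     turn = stats::runif(60, 5, 170),
                     plane = stats::runif(60, -175, 175))
  mm <- tcellscan:::track_matrices(reconstruct_track(trip))[[1]]
  expect_equal(tcellscan:::.step_speeds_mat(mm, 20), trip$speed,
               tolerance = 1e-6)
  expect_equal(tcellscan:::.turning_angles_mat(mm, 20), trip$turn[-1],
               tolerance = 1e-6)
  expect_equal(tcellscan:::.plane_angles_mat(mm, 20), trip$plane[-(1:2)],
               tolerance = 1e-6)
})

test_that("synthesize_tracks: sizes, determinism, preserved marginals", {
  set.seed(27)
  cohort <- generate_cohort(cohort_preset("WT", n_tracks = 20))
  one <- synthesize_tracks(cohort, n_tracks = 1, duration = 60, seed = 1)
  expect_equal(nrow(one), 4)

  a <- synthesize_tracks(cohort, n_tracks = 3, duration = 1200, seed = 5)
  b <- synthesize_tracks(cohort, n_tracks = 3, duration = 1200, seed = 5)
  expect_identical(a, b)

  # resampling preserves the speed marginal of the pool
  pool <- build_step_pool(cohort)
  syn <- synthesize_tracks(cohort, n_tracks = 20, duration = 2 * 3600,
                           seed = 6)
  expect_equal(mean(unlist(step_speeds(syn))), mean(pool$speed),
               tolerance = 0.05)
})

test_that("synthesized cohorts keep the measured motility coefficient", {
  set.seed(28)
  cohort <- generate_cohort(cohort_preset("WT"))
  mc_meas <- motility(cohort)$motility_coefficient
  syn <- synthesize_tracks(cohort, n_tracks = 100, duration = 8 * 3600,
                           seed = 29)
  mc_syn <- motility(syn, max_lag = 600)$motility_coefficient
  expect_equal(mc_syn, mc_meas, tolerance = 0.15)
})
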