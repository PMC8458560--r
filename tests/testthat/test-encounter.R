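test_that("DC placement is uniform in the ball", {
  set.seed(31)
  R <- 500
  dc <- place_dcs(1e5, R)
  r <- sqrt(rowSums(dc^2))
  expect_true(all(r <= R))
  # mean radius of the uniform ball is 3R/4
  expect_equal(mean(r), 3 * R / 4, tolerance = 0.005)
  # radius CDF is (r/R)^3, i.e. (r/R)^3 is standard uniform
  # runif's 2^-32 grid produces occasional ties at this n; harmless here
  ks <- suppressWarnings(stats::ks.test((r / R)^3, "punif"))
  expect_gt(ks$p.value, 0.01)
  # the rejection sampler draws from the same distribution
  rej <- place_dcs(2e4, R, method = "rejection")
  ks2 <- stats::ks.test(sqrt(rowSums(rej^2)) / R, function(q) q^3)
  expect_gt(ks2$p.value, 0.01)
  expect_equal(nrow(place_dcs(0, R)), 0)
})

test_that("T cell placement: start distribution, rigid preservation", {
  set.seed(32)
  tr <- generate_cohort(cohort_spec(n_tracks = 6, duration = 400))
  mats <- tcellscan:::track_matrices(tr)

  # start_sd -> 0: all starts at the centre
  tight <- place_tcells(mats, 6, start_sd = 1e-9)
  for (m in tight) expect_equal(m[1, ], c(0, 0, 0), tolerance = 1e-6,
                                ignore_attr = TRUE)

  # fraction of starts inside the zone ~ chi^2_3 CDF at (R/sd)^2
  starts <- replicate(4000, place_tcells(mats, 1, start_sd = 150)[[1]][1, ])
  inside <- mean(colSums(starts^2) <= 500^2)
  expect_equal(inside, stats::pchisq((500 / 150)^2, df = 3),
               tolerance = 0.01)

  # placement is rigid: speeds and turning angles preserved
  placed <- place_tcells(mats, 6, start_sd = 150)
  got <- sort(unlist(lapply(placed, function(m)
    tcellscan:::.turning_angles_mat(m, 20))))
  want <- sort(unlist(lapply(mats, function(m)
    tcellscan:::.turning_angles_mat(m, 20))))
  expect_equal(got, want, tolerance = 1e-8)
  sp <- sort(unlist(lapply(placed, function(m)
    tcellscan:::.step_speeds_mat(m, 20))))
  expect_equal(sp, sort(unlist(lapply(mats, function(m)
    tcellscan:::.step_speeds_mat(m, 20)))), tolerance = 1e-8)
})

test_that("contact logic: immediate contact, out-of-range, freezing", {
  cfg <- arena_config(n_dc = 1, n_tcells = 1, duration = 100, n_reps = 1)

  # cell and DC both at the centre: contact at step 0
  still <- matrix(0, 6, 3)
  out <- run_replicate(list(still), matrix(0, 1, 3), cfg)
  expect_equal(out$contact_fraction, 100)
  expect_equal(out$first_contact_time, 0)

  # stationary cell 20 um from the only DC with 15-um radius: never
  far <- matrix(rep(c(20, 0, 0), each = 6), 6, 3)
  out2 <- run_replicate(list(far), matrix(0, 1, 3), cfg)
  expect_equal(out2$contact_fraction, 0)
  expect_true(is.na(out2$first_contact_time))

  # a moving cell freezes at its first contact position
  mover <- cbind(seq(-50, 50, by = 4), 0, 0)  # passes through the DC
  out3 <- run_replicate(list(mover), matrix(0, 1, 3), cfg,
                        keep_positions = TRUE)
  hit <- which(abs(mover[, 1]) <= 15)[1]
  pos <- out3$positions[[1]]
  expect_equal(out3$first_contact_time, (hit - 1) * cfg$dt / 60)
  for (i in hit:nrow(pos))
    expect_equal(pos[i, ], mover[hit, ], ignore_attr = TRUE)
})

test_that("with contact radius covering the zone every in-zone cell contacts at once", {
  set.seed(33)
  cfg <- arena_config(n_dc = 1, n_tcells = 5, duration = 100, n_reps = 1)
  cfg$contact_radius <- 2 * cfg$zone_diameter  # covers the whole zone
  mats <- replicate(5, matrix(rep(stats::rnorm(3, 0, 150), each = 6), 6, 3),
                    simplify = FALSE)
  dc <- place_dcs(1, cfg$zone_diameter / 2)
  out <- run_replicate(mats, dc, cfg)
  inz <- vapply(mats, function(m) sum(m[1, ]^2) <= (cfg$zone_diameter / 2)^2,
                TRUE)
  expect_true(all(out$first_contact_time[inz] == 0))
})

test_that("initial contact probability matches the Poisson approximation", {
  # for n DCs uniform in the ball, an interior cell is within r_c of >= 1 DC
  # with probability ~ 1 - exp(-n (r_c/R)^3)
  set.seed(34)
  n_dc <- 1e4; R <- 500; rc <- 15
  cfg <- arena_config(n_dc = n_dc, n_tcells = 1, duration = 40, n_reps = 1)
  cells <- place_dcs(800, R * 0.9)  # interior points, away from the edge
  dcs <- place_dcs(n_dc, R)
  grid <- tcellscan:::dc_grid(dcs, rc)
  hit0 <- vapply(seq_len(nrow(cells)), function(i)
    !is.na(tcellscan:::first_contact_grid(cells[i, , drop = FALSE], grid)),
    TRUE)
  expect_equal(mean(hit0), 1 - exp(-n_dc * (rc / R)^3), tolerance = 0.15)
})

test_that("grid-hashed contact detection equals brute force", {
  set.seed(35)
  cfg <- arena_config(n_dc = 300, n_tcells = 20, duration = 600, n_reps = 1)
  tr <- generate_cohort(cohort_spec(n_tracks = 20, duration = 600))
  placed <- place_tcells(tcellscan:::track_matrices(tr), 20, 150)
  dcs <- place_dcs(300, 500)
  bf <- run_replicate(placed, dcs, cfg, method = "bruteforce")
  gr <- run_replicate(placed, dcs, cfg, method = "grid")
  expect_equal(gr, bf)
})

test_that("contact fraction is monotone in DC count and contact radius", {
  set.seed(36)
  tr <- generate_cohort(cohort_spec(n_tracks = 40, duration = 1200))
  placed <- place_tcells(tcellscan:::track_matrices(tr), 40, 150)
  dcs <- place_dcs(600, 500)
  cfg <- arena_config(n_dc = 600, n_tcells = 40, duration = 1200, n_reps = 1)
  # common random numbers: nested DC sets, identical placed tracks
  f_dc <- vapply(c(60, 240, 600), function(n)
    run_replicate(placed, dcs[seq_len(n), , drop = FALSE], cfg)$contact_fraction,
    0)
  expect_true(all(diff(f_dc) >= 0))
  f_rc <- vapply(c(8, 15, 30), function(r) {
    cfg$contact_radius <- r
    run_replicate(placed, dcs[1:60, ], cfg)$contact_fraction
  }, 0)
  expect_true(all(diff(f_rc) >= 0))
})

test_that("experiments: no DCs means no contacts, fixed seed reproduces", {
  set.seed(37)
  tr <- generate_cohort(cohort_spec(n_tracks = 12, duration = 400))
  cfg <- arena_config(n_dc = 0, n_tcells = 10, duration = 400, n_reps = 3)
  e0 <- run_experiment(tr, cfg, seed = 41)
  expect_true(all(e0$per_rep_contact_fraction == 0))

  cfg$n_dc <- 200
  e1 <- run_experiment(tr, cfg, seed = 42)
  e2 <- run_experiment(tr, cfg, seed = 42)
  expect_identical(e1, e2)
  expect_true(all(e1$per_rep_contact_fraction >= 0 &
                    e1$per_rep_contact_fraction <= 100))
  expect_true(all(unlist(e1$first_contact_times) <=
                    cfg$duration / 60, na.rm = TRUE))
  expect_true(all(unlist(e1$residency_steps) <= cfg$duration / cfg$dt + 1))
})

test_that("residence half-life: no decay, exact synthetic decay", {
  # nobody leaves: infinite half-life
  expect_equal(residence_half_life(rep(1, 50), time_h = seq(0, 8, length.out = 50)),
               Inf)
  # exact exponential: recovered half-life equals the constructed one
  th <- seq(0, 8, by = 0.1)
  curve <- 0.95 * exp(-log(2) / 10 * th)  # half-life 10 h
  expect_equal(residence_half_life(curve, time_h = th), 10, tolerance = 1e-9)
})
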