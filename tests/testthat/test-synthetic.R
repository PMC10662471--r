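test_that("subject sampling is seeded and respects the template", {
  s1 <- sample_subject(seed = 10)
  s2 <- sample_subject(seed = 10)
  expect_identical(s1, s2)
  # zero-variance ranges reproduce the template exactly
  s0 <- sample_subject(seed = 1, mass_range = c(70, 70),
                       stature_range = c(1, 1), frac_jitter = 0)
  tmpl <- sescom:::full_segments()
  expect_equal(s0$segments$frac, tmpl$frac, tolerance = 1e-12)
  expect_equal(s0$total_mass, 70)
  expect_error(sample_subject(seed = 1, mass_range = c(90, 80)),
               "degenerate")
  # mass fractions stay a unit simplex over many draws
  for (seed in 1:25) {
    s <- sample_subject(seed = seed)
    expect_equal(sum(s$segments$frac), 1, tolerance = 1e-10)
    expect_true(all(s$segments$frac > 0))
  }
})

test_that("posture sampling stays within range and is reproducible", {
  m <- build_preset("d")
  P <- sample_postures(m, 200, seed = 20)
  expect_identical(P, sample_postures(m, 200, seed = 20))
  rng <- default_ranges()
  for (dn in colnames(P)) {
    r <- sescom:::range_for(rng, dn) * pi / 180
    expect_true(all(P[, dn] >= r[1] & P[, dn] <= r[2]))
  }
  # collapsed ranges give identical neutral postures
  zero <- lapply(rng, function(r) c(0, 0))
  expect_equal(sample_postures(m, 5, ranges = zero, seed = 1),
               neutral_posture(m, 5))
  # stratified draws excite every DoF across >= 25% of its range
  Ps <- sample_postures(m, 40, seed = 21, stratify = TRUE)
  for (dn in colnames(Ps)) {
    r <- sescom:::range_for(rng, dn) * pi / 180
    expect_gt(diff(range(Ps[, dn])), 0.25 * diff(r))
  }
})

test_that("observation noise has the configured statistics", {
  subj <- sample_subject(seed = 30)
  m <- build_preset("b", subj)
  P <- sample_postures(m, 2000, seed = 31)
  obs <- generate_observations(subj, m, P,
                               noise = noise_spec(3, 0.75, seed = 32))
  err_mm <- (obs$cop - obs$com[, 1:2]) * 1000
  expect_equal(sd(err_mm), 3, tolerance = 0.05)
  expect_equal(mean(err_mm), 0, tolerance = 0.2)
  ang_err_deg <- (obs$postures - attr(obs, "true_postures")) * 180 / pi
  expect_equal(sd(ang_err_deg), 0.75, tolerance = 0.05)
  # zero noise: CoP equals the true horizontal CoM exactly
  obs0 <- generate_observations(subj, m, P[1:5, ],
                                noise = noise_spec(0, 0))
  expect_identical(obs0$cop, obs0$com[, 1:2])
})

test_that("scheduled time series round-trip through static detection", {
  subj <- sample_subject(seed = 40)
  m <- build_preset("d", subj)
  sched <- sample_postures(m, 3, seed = 41)
  ts <- generate_timeseries(subj, m, sched, hold_s = 6,
                            noise = noise_spec(3, 0.75, seed = 42))
  merged <- unify_frames(ts$angles,
                         resample_series(lowpass_filter(ts$cop), 60))
  det <- detect_static(merged)
  sch <- attr(ts, "schedule")
  expect_identical(nrow(det$postures), 3L)
  expect_lt(max(abs(det$postures[, colnames(sched)] - sch$angles_deg)), 0.5)
  expect_lt(max(abs(det$postures[, c("cop.x", "cop.y")] - sch$cop_mm)), 2)
  # noise at 150% of the criteria: no posture passes
  ts_bad <- generate_timeseries(subj, m, sched, hold_s = 6,
                                noise = noise_spec(9, 2.25, seed = 43))
  merged_bad <- unify_frames(ts_bad$angles,
                             resample_series(lowpass_filter(ts_bad$cop), 60))
  expect_identical(nrow(detect_static(merged_bad)$postures), 0L)
  expect_error(generate_timeseries(subj, m, sched, hold_s = 0.5), "1 s")
})

test_that("zero-noise full cycle: simulate, detect, identify, predict", {
  subj <- sample_subject(seed = 50)
  m <- build_preset("d", subj)
  sched <- sample_postures(m, 16, seed = 51)  # >= minimum 14 postures
  ts <- generate_timeseries(subj, m, sched, hold_s = 6,
                            noise = noise_spec(0, 0))
  merged <- unify_frames(ts$angles,
                         resample_series(lowpass_filter(ts$cop), 60))
  det <- detect_static(merged)
  expect_identical(nrow(det$postures), 16L)
  obs <- observations_from_static(det$postures, m)
  fit <- suppressWarnings(sesc_fit(obs, m))
  held <- sample_postures(m, 10, seed = 52)
  err <- abs(predict(fit, held) - com_weighted_sum(m, subj, held))
  expect_lt(max(err), 1e-4)  # limited only by trajectory interpolation
})

test_that("cohort simulation is deterministic in the master seed", {
  c1 <- simulate_cohort(n_subjects = 2, postures_per_subject = 20, seed = 9)
  c2 <- simulate_cohort(n_subjects = 2, postures_per_subject = 20, seed = 9)
  expect_identical(c1$subjects[[1]]$observations$cop,
                   c2$subjects[[1]]$observations$cop)
  expect_identical(length(c1$subjects), 2L)
})
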