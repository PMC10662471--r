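test_that("design blocks are the chained joint rotations", {
  toy <- toy_chain()
  # all angles zero: n stacked identity blocks
  B0 <- sesc_design_block(toy$model, neutral_posture(toy$model))
  expect_equal(B0, cbind(diag(3), diag(3)), ignore_attr = TRUE)
  # two-joint Y chain: blocks Ry(a1), Ry(a1)Ry(a2)
  p <- neutral_posture(toy$model)
  p[1, ] <- c(0.4, -0.7)
  B <- sesc_design_block(toy$model, p)
  expect_equal(B[, 1:3], rotation_about_axis("y", 0.4), ignore_attr = TRUE)
  expect_equal(B[, 4:6],
               rotation_about_axis("y", 0.4) %*%
                 rotation_about_axis("y", -0.7), ignore_attr = TRUE)
})

test_that("model (a)'s mediolateral design row is posture-invariant", {
  ma <- build_preset("a")
  set.seed(13)
  for (i in 1:10) {
    P <- sample_postures(ma, 1, seed = 100 + i)
    B <- sesc_design_block(ma, P)
    expect_equal(B[2, ], rep(c(0, 1, 0), nrow(ma$joints)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("closed-form SESC vector matches the hand-derived toy", {
  toy <- toy_chain()
  V <- sesc_true_vector(toy$model, toy$subject)
  expect_equal(unname(V), c(0, 0, -0.375, 0, 0, -0.125), tolerance = 1e-12)
  # a zero-mass distal segment contributes a zero subvector
  subj0 <- sesc_subject(1, segments = data.frame(
    joint = c("j1", "j2"), frac = c(1, 0), cx = 0, cy = 0, cz = -0.25),
    geometry = toy$subject$geometry)
  V0 <- sesc_true_vector(toy$model, subj0)
  expect_equal(unname(V0[4:6]), c(0, 0, 0))
})

test_that("weighted-sum CoM equals d1 + B V_true for every preset", {
  # the module's central oracle, at 1e-10 m over random subjects/postures
  for (mid in c("a", "b", "c", "d")) {
    for (s in 1:3) {
      subj <- sample_subject(seed = 50 + s)
      m <- build_preset(mid, subj)
      P <- sample_postures(m, 30, seed = 60 + s)
      d1 <- matrix(rnorm(3 * 30, 0, 0.05), 30, 3)
      expect_lt(max(abs(com_weighted_sum(m, subj, P, d1 = d1) -
                          estimate_com(m, sesc_true_vector(m, subj), P,
                                       d1 = d1))), 1e-10)
    }
  }
})

test_that("minimum posture counts follow ceiling(3n/2)", {
  expect_identical(sesc_min_postures(build_preset("b")), 14L)
  expect_identical(sesc_min_postures(build_preset("d")), 14L)
  expect_identical(sesc_min_postures(build_preset("a")), 11L)
  expect_identical(sesc_min_postures(build_preset("c")), 11L)
  expect_identical(sesc_min_postures(toy_chain()$model), 3L)
})

test_that("full-3D identification recovers a known vector and flags defects", {
  toy <- spherical_chain()
  V_true <- sesc_true_vector(toy$model, toy$subject)
  P <- random_angles(toy$model, 15, seed = 70)
  com <- estimate_com(toy$model, V_true, P)
  obs <- sesc_observations(P, com = com, model = toy$model)
  fit <- sesc_fit(obs, toy$model, observe = "com")
  expect_lt(max(abs(coef(fit) - V_true)), 1e-9)
  expect_identical(fit$rank, fit$n_col)
  # duplicate postures only: rank-deficiency error
  Pd <- P[rep(1, 15), , drop = FALSE]
  obs_d <- sesc_observations(Pd, com = com[rep(1, 15), ],
                             model = toy$model)
  expect_error(sesc_fit(obs_d, toy$model, observe = "com"),
               class = "sesc_rank_error")
  # too few postures: shortage error
  obs_s <- sesc_observations(P[1, , drop = FALSE],
                             com = com[1, , drop = FALSE],
                             model = toy$model)
  expect_error(sesc_fit(obs_s, toy$model, observe = "com"),
               class = "sesc_shortage_error")
})

test_that("least-squares residual RMS approaches the noise SD", {
  toy <- spherical_chain()
  V_true <- sesc_true_vector(toy$model, toy$subject)
  P <- random_angles(toy$model, 3400, seed = 71)  # ~10^4 rows
  com <- estimate_com(toy$model, V_true, P)
  set.seed(72)
  sigma <- 0.004
  obs <- sesc_observations(P, com = com + matrix(rnorm(length(com), 0, sigma),
                                                 nrow(com), 3),
                           model = toy$model)
  fit <- sesc_fit(obs, toy$model, observe = "com")
  expect_equal(fit$residual_rms, sigma, tolerance = 0.05)
})

test_that("2D CoP identification predicts held-out 3D CoM", {
  subj <- sample_subject(seed = 80)
  m <- build_preset("d", subj)
  P <- sample_postures(m, 40, seed = 81)
  obs <- generate_observations(subj, m, P, noise = noise_spec(0, 0, seed = 82))
  fit <- suppressWarnings(sesc_fit(obs, m))
  held <- sample_postures(m, 25, seed = 83)
  est <- predict(fit, held)
  expect_lt(max(abs(est - com_weighted_sum(m, subj, held))), 1e-8)
  # shortage: k = 2 postures for n = 9 joints
  obs2 <- subset_obs_for_test(obs, 1:2)
  expect_error(sesc_fit(obs2, m), class = "sesc_shortage_error")
})

test_that("leg chains of Y-only joints share mediolateral columns", {
  # structural degeneracy: Ry fixes the y axis, so a knee/ankle distal to a
  # hip has the same mediolateral B column as the hip; the minimum-norm
  # solution still reproduces every prediction
  subj <- sample_subject(seed = 84)
  m <- build_preset("d", subj)
  P <- sample_postures(m, 40, seed = 85)
  obs <- generate_observations(subj, m, P, noise = noise_spec(0, 0, seed = 86))
  expect_warning(fit <- sesc_fit(obs, m), class = "sesc_rank_warning")
  expect_identical(fit$rank, 23L)
  expect_identical(fit$n_col, 27L)
  expect_true(all(fit$deficient[c("hip_l.y", "knee_l.y", "ankle_l.y")]))
})

test_that("model (a) fitted to a 3-DoF subject has constant ML output", {
  subj <- sample_subject(seed = 90)
  md <- build_preset("d", subj)
  ma <- build_preset("a")
  P <- sample_postures(md, 40, seed = 91)
  obs <- generate_observations(subj, md, P, noise = noise_spec(0, 0, seed = 92))
  proj <- project_posture(obs$postures, md, ma)
  pobs <- sesc_observations(proj, cop = obs$cop, d1 = obs$d1, model = ma)
  expect_warning(fit <- sesc_fit(pobs, ma), class = "sesc_rank_warning")
  expect_true(any(fit$deficient))
  est <- predict(fit, proj)
  expect_lt(diff(range(est[, 2])), 1e-12)
})

test_that("identification is unbiased under zero-mean CoP noise", {
  subj <- sample_subject(seed = 95)
  m <- build_preset("c", subj)  # full-rank preset (all spherical + knees)
  V_true <- sesc_true_vector(m, subj)
  P <- sample_postures(m, 60, seed = 96)
  com <- com_weighted_sum(m, subj, P)
  n_rep <- 60
  V_acc <- 0
  set.seed(97)
  for (r in seq_len(n_rep)) {
    cop <- com[, 1:2] + matrix(rnorm(2 * nrow(P), 0, 0.003), nrow(P), 2)
    obs <- sesc_observations(P, cop = cop, model = m)
    fit <- suppressWarnings(sesc_fit(obs, m))
    V_acc <- V_acc + coef(fit)
  }
  V_bar <- V_acc / n_rep
  # identifiable components average toward truth
  ok <- !suppressWarnings(sesc_fit(
    sesc_observations(P, cop = com[, 1:2], model = m), m))$deficient
  expect_lt(max(abs(V_bar[ok] - V_true[ok])), 0.004)
})

test_that("estimation is affine in V and validates lengths", {
  toy <- toy_chain()
  P <- random_angles(toy$model, 4, seed = 99)
  V1 <- c(0, 0, -0.3, 0, 0, -0.1)
  V2 <- c(0.1, 0, 0.2, 0, 0.05, 0)
  d1 <- c(0.3, -0.1, 0.2)
  e12 <- estimate_com(toy$model, V1 + V2, P, d1 = d1)
  e1 <- estimate_com(toy$model, V1, P, d1 = d1)
  e2 <- estimate_com(toy$model, V2, P, d1 = d1)
  expect_equal(e12, e1 + e2 - matrix(d1, nrow(P), 3, byrow = TRUE),
               tolerance = 1e-12)
  # zero angles: d1 + sum of subvectors
  e0 <- estimate_com(toy$model, V1, neutral_posture(toy$model), d1 = d1)
  expect_equal(drop(e0), d1 + c(0, 0, -0.4), ignore_attr = TRUE)
  expect_error(estimate_com(toy$model, V1[1:5], P), "length")
})
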