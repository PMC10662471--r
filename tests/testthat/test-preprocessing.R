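make_series <- function(f, rate = 1000, dur = 5, name = "cop.x",
                        inclusive = TRUE) {
  # inclusive endpoint puts integer-Hz tones at zero crossings on both ends,
  # where the steady-state (analytic) filter response is the right oracle
  t_end <- if (inclusive) dur else dur - 1 / rate
  t <- seq(0, t_end, by = 1 / rate)
  sesc_timeseries(matrix(f(t), ncol = 1, dimnames = list(NULL, name)), rate)
}

test_that("zero-phase low-pass has unit DC gain and the analytic roll-off", {
  const <- make_series(function(t) rep(2.5, length(t)))
  expect_lt(max(abs(lowpass_filter(const)$data - 2.5)), 1e-9)
  # 50 Hz tone at 5x cutoff: 4th-order magnitude (1 + (f/fc)^8)^-1/2,
  # squared by the forward-backward pass -> ~1.6e-6; assert < 0.01
  tone50 <- make_series(function(t) sin(2 * pi * 50 * t))
  expect_lt(max(abs(lowpass_filter(tone50)$data)), 0.01)
  # 1 Hz tone passes within 1%
  tone1 <- make_series(function(t) sin(2 * pi * 1 * t))
  ref <- make_series(function(t) sin(2 * pi * 1 * t))$data
  expect_lt(max(abs(lowpass_filter(tone1)$data - ref)), 0.01)
  expect_error(lowpass_filter(make_series(sin, rate = 15)), "Nyquist")
})

test_that("resampling preserves duration and band-limited content", {
  s <- make_series(function(t) rep(1.2, length(t)), inclusive = FALSE)
  r <- resample_series(s, 60)
  expect_identical(nrow(r$data), 300L)  # 5 s at 60 Hz
  expect_lt(max(abs(r$data - 1.2)), 1e-9)
  tone2 <- make_series(function(t) sin(2 * pi * 2 * t))
  r2 <- resample_series(tone2, 60)
  expect_lt(max(abs(r2$data - sin(2 * pi * 2 * r2$time))), 0.01)
  expect_error(resample_series(r2, 1000), "upsampling")
})

test_that("filter + resample pipeline is linear", {
  pipeline <- function(s) resample_series(lowpass_filter(s), 60)$data
  set.seed(123)
  t <- seq(0, 3, by = 1 / 1000)
  x <- sin(2 * pi * 3 * t) + 0.5 * rnorm(length(t))
  y <- cos(2 * pi * 7 * t)
  mk <- function(v) sesc_timeseries(
    matrix(v, ncol = 1, dimnames = list(NULL, "cop.x")), 1000)
  lhs <- pipeline(mk(2 * x - 3 * y))
  rhs <- 2 * pipeline(mk(x)) - 3 * pipeline(mk(y))
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("frame unification subtracts the root position from the CoP", {
  t60 <- seq(0, 4, by = 1 / 60)
  ang <- sesc_timeseries(
    matrix(10, length(t60), 1, dimnames = list(NULL, "l5s1.y")), 60)
  coppos <- cbind(`cop.x` = 5 + 3 * t60, `cop.y` = rep(-2, length(t60)))
  cop <- sesc_timeseries(coppos, 60)
  # CoP identical to the L5 horizontal position: unified CoP is zero
  l5 <- sesc_timeseries(cbind(`l5.x` = coppos[, 1], `l5.y` = coppos[, 2],
                              `l5.z` = rep(0, length(t60))), 60)
  u <- unify_frames(ang, cop, l5)
  expect_lt(max(abs(u$data[, c("cop.x", "cop.y")])), 1e-9)
  # constant frame offset shifts the unified CoP by its negative
  l5o <- sesc_timeseries(cbind(`l5.x` = rep(7, length(t60)),
                               `l5.y` = rep(-1, length(t60)),
                               `l5.z` = rep(0, length(t60))), 60)
  u2 <- unify_frames(ang, cop, l5o)
  expect_equal(u2$data[, "cop.x"], coppos[, 1] - 7, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(u2$data[, "cop.y"], coppos[, 2] + 1, tolerance = 1e-9,
               ignore_attr = TRUE)
  disjoint <- sesc_timeseries(coppos, 60, start = 100)
  expect_error(unify_frames(ang, disjoint), "overlap")
})

test_that("static detection finds scheduled holds and applies the criteria", {
  rate <- 60
  hold_vals <- c(10, -20, 35)
  seg <- function(v, s) matrix(v, round(s * rate), 1)
  ramp <- function(a, b, s) matrix(seq(a, b, length.out = round(s * rate)),
                                   ncol = 1)
  ang <- rbind(seg(hold_vals[1], 6), ramp(hold_vals[1], hold_vals[2], 2),
               seg(hold_vals[2], 6), ramp(hold_vals[2], hold_vals[3], 2),
               seg(hold_vals[3], 6))
  dat <- cbind(ang, ang * 0.5, ang * 0)
  colnames(dat) <- c("l5s1.y", "cop.x", "cop.y")
  s <- sesc_timeseries(dat, rate)
  det <- detect_static(s)
  expect_identical(nrow(det$postures), 3L)
  expect_equal(unname(det$postures[, "l5s1.y"]), hold_vals,
               tolerance = 1e-9)
  expect_equal(unname(det$postures[, "cop.x"]), hold_vals * 0.5,
               tolerance = 1e-9)
  # angle noise above the 1.5 deg criterion suppresses every posture
  set.seed(5)
  noisy <- dat
  noisy[, 1] <- noisy[, 1] + rnorm(nrow(dat), 0, 2)
  expect_identical(nrow(detect_static(sesc_timeseries(noisy, rate))$postures),
                   0L)
  # a 4 s hold below the 5 s minimum is discarded
  short <- rbind(seg(0, 4), ramp(0, 40, 3), seg(40, 4))
  dshort <- cbind(short, short * 0, short * 0)
  colnames(dshort) <- c("l5s1.y", "cop.x", "cop.y")
  expect_identical(nrow(detect_static(sesc_timeseries(dshort, rate))$postures),
                   0L)
})

test_that("posture splitting is a seed-reproducible partition", {
  s1 <- split_postures(98, seed = 7)
  expect_identical(length(s1$train), 74L)  # round(0.75 * 98)
  expect_identical(length(s1$test), 24L)
  expect_identical(sort(c(s1$train, s1$test)), 1:98)
  expect_identical(split_postures(98, seed = 7), s1)
  expect_false(identical(split_postures(98, seed = 8), s1))
  s2 <- split_postures(4)
  expect_identical(length(s2$train), 3L)
  expect_identical(split_postures(10, chronological = TRUE)$train, 1:8)
  expect_warning(split_postures(6, seed = 1, model = build_preset("d")),
                 "minimum")
  expect_error(split_postures(1), "at least 2")
})
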