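# Synthetic ground-truth generation: subjects with known inertial
# parameters, random static postures, CoP observations (true horizontal CoM
# plus noise), and raw time series with scheduled holds, so every pipeline
# stage is testable against a known answer.
#
# Study conditions emulated by the defaults: 18 subjects, 98 static
# postures each, truth body of model (d) topology, observation noise at
# half the static-detection criteria (CoP SD 3 mm, angle SD 0.75 deg),
# 75/25 identification/testing split.

#' Noise specification for synthetic observations
#'
#' @param cop_noise_sd_mm CoP noise SD per horizontal axis (mm).
#' @param angle_noise_sd_deg Joint-angle noise SD per DoF (deg).
#' @param seed Optional seed applied when the spec is used.
#' @return List of class `sesc_noise`.
#' @export
noise_spec <- function(cop_noise_sd_mm = 3, angle_noise_sd_deg = 0.75,
                       seed = NULL) {
  if (cop_noise_sd_mm < 0 || angle_noise_sd_deg < 0)
    stop("noise SDs must be >= 0")
  structure(list(cop_noise_sd_mm = cop_noise_sd_mm,
                 angle_noise_sd_deg = angle_noise_sd_deg, seed = seed),
            class = "sesc_noise")
}

#' Default joint-angle sampling ranges
#'
#' Conservative healthy range-of-motion subsets, degrees, per joint kind
#' and axis. Flexion/extension (`y`) carries the widest excursions;
#' ab/adduction (`x`) and axial rotation (`z`) are narrower.
#'
#' @return Named list `kind.axis` -> `c(lo, hi)` in degrees.
#' @export
default_ranges <- function() {
  list(
    l5s1.y = c(-20, 60), l5s1.x = c(-15, 15), l5s1.z = c(-20, 20),
    shoulder.y = c(-50, 120), shoulder.x = c(-30, 60),
    shoulder.z = c(-30, 30),
    hip.y = c(-20, 80), hip.x = c(-20, 30), hip.z = c(-20, 20),
    knee.y = c(0, 90),
    ankle.y = c(-20, 20)
  )
}

range_for <- function(ranges, dof_name) {
  kind_axis <- sub("^([a-z0-9]+)(_[lr])?\\.", "\\1.", dof_name)
  r <- ranges[[kind_axis]]
  if (is.null(r)) r <- ranges[[dof_name]]
  if (is.null(r)) stop("no sampling range for DoF '", dof_name, "'")
  if (r[2L] < r[1L]) stop("empty range for DoF '", dof_name, "'")
  r
}

#' Draw a synthetic subject
#'
#' Samples total mass, a global stature scale, and multiplicative jitter of
#' the template segment mass fractions (renormalized to sum to 1) and
#' geometry. Deterministic for a given seed; zero jitter reproduces the
#' neutral template exactly.
#'
#' @param seed Seed for the draw (caller RNG untouched).
#' @param mass_range Total-mass range (kg).
#' @param stature_range Multiplicative range on all template offsets.
#' @param frac_jitter Half-width of the multiplicative jitter on mass
#'   fractions (0 = template).
#' @return A [sesc_subject()].
#' @export
sample_subject <- function(seed = NULL, mass_range = c(55, 95),
                           stature_range = c(0.92, 1.08),
                           frac_jitter = 0.1) {
  if (mass_range[2L] < mass_range[1L] || stature_range[2L] < stature_range[1L]
      || frac_jitter < 0 || frac_jitter >= 1)
    stop("degenerate sampling ranges")
  with_seed(seed, {
    M <- stats::runif(1L, mass_range[1L], mass_range[2L])
    scale <- stats::runif(1L, stature_range[1L], stature_range[2L])
    segs <- full_segments()
    mult <- stats::runif(nrow(segs), 1 - frac_jitter, 1 + frac_jitter)
    segs$frac <- segs$frac * mult / sum(segs$frac * mult)
    segs[, c("cx", "cy", "cz")] <- segs[, c("cx", "cy", "cz")] * scale *
      matrix(stats::runif(nrow(segs) * 3L, 0.97, 1.03), nrow(segs), 3L)
    geom <- full_skeleton()
    geom[, c("ox", "oy", "oz")] <- geom[, c("ox", "oy", "oz")] * scale
    sesc_subject(M, segments = segs, geometry = geom)
  })
}

#' Draw random static postures
#'
#' Independent uniform draws per DoF within per-joint ranges. With
#' `stratify = TRUE` each DoF is sampled on a randomly permuted stratified
#' grid (one draw per equal-probability bin), guaranteeing that every DoF
#' is excited across its range.
#'
#' @param model A `sesc_model`.
#' @param k Number of postures (>= 1).
#' @param ranges Ranges as from [default_ranges()], degrees.
#' @param seed Seed (caller RNG untouched).
#' @param stratify Use per-DoF stratified (Latin-hypercube style) sampling.
#' @return `k x DoF` posture matrix (radians).
#' @export
sample_postures <- function(model, k, ranges = default_ranges(),
                            seed = NULL, stratify = FALSE) {
  if (k < 1L) stop("'k' must be >= 1")
  dn <- dof_names(model)
  with_seed(seed, {
    out <- vapply(dn, function(d) {
      r <- range_for(ranges, d) * pi / 180
      if (stratify) {
        u <- (sample.int(k) - stats::runif(k)) / k
        r[1L] + u * (r[2L] - r[1L])
      } else {
        stats::runif(k, r[1L], r[2L])
      }
    }, numeric(k))
    matrix(out, nrow = k, dimnames = list(NULL, dn))
  })
}

#' Generate CoP/CoM observations for postures
#'
#' The physical ground truth: in a static posture the CoP is the horizontal
#' projection of the CoM. The true 3D CoM is computed by the
#' weighted-segment formula; the observed CoP adds per-axis Gaussian noise,
#' and the recorded angles add per-DoF Gaussian noise. The true CoM and
#' true angles are retained for scoring.
#'
#' @param subject A [sesc_subject()].
#' @param truth_model The `sesc_model` generating the data.
#' @param postures True posture matrix (radians).
#' @param noise A [noise_spec()].
#' @param d1 Root positions (m).
#' @return A [sesc_observations()] set with noisy `postures`, noisy `cop`,
#'   true `com`, and attribute `"true_postures"`.
#' @export
generate_observations <- function(subject, truth_model, postures,
                                  noise = noise_spec(), d1 = c(0, 0, 0)) {
  postures <- as_posture_matrix(postures, truth_model)
  k <- nrow(postures)
  com <- com_weighted_sum(truth_model, subject, postures, d1 = d1)
  d1m <- root_matrix(d1, k)
  with_seed(noise$seed, {
    cop <- com[, 1:2, drop = FALSE] +
      matrix(stats::rnorm(2L * k, 0, noise$cop_noise_sd_mm / 1000), k, 2L)
    ang <- postures +
      matrix(stats::rnorm(length(postures), 0,
                          noise$angle_noise_sd_deg * pi / 180),
             k, ncol(postures))
    colnames(ang) <- colnames(postures)
    obs <- sesc_observations(ang, cop = cop, com = com, d1 = d1m,
                             model = truth_model)
    attr(obs, "true_postures") <- postures
    obs
  })
}

#' Generate raw angle and CoP time series for a posture schedule
#'
#' Emulates a recording session: each scheduled posture is held for
#' `hold_s` seconds with within-criteria Gaussian noise, holds are joined
#' by smooth cosine ramps, joint angles are sampled at `rates[1]` and the
#' CoP at `rates[2]`. The scheduled holds (times and true channel values)
#' are recorded in the `"schedule"` attribute for round-trip tests.
#'
#' @param subject A [sesc_subject()].
#' @param truth_model Generating `sesc_model`.
#' @param schedule Posture matrix (radians), one row per hold.
#' @param hold_s Hold duration (s); must be at least the 1 s detection
#'   window.
#' @param ramp_s Ramp duration between holds (s).
#' @param noise A [noise_spec()] (`NULL` seed allowed).
#' @param rates `c(angle_hz, cop_hz)`.
#' @return List with `angles` and `cop` time series (boundary units: deg,
#'   mm) and attribute `"schedule"`.
#' @export
generate_timeseries <- function(subject, truth_model, schedule, hold_s = 6,
                                ramp_s = 2, noise = noise_spec(),
                                rates = c(60, 1000)) {
  schedule <- as_posture_matrix(schedule, truth_model)
  if (nrow(schedule) < 1L) stop("empty posture schedule")
  if (hold_s < 1) stop("'hold_s' must cover the 1 s detection window")
  n_hold <- nrow(schedule)
  seg_bounds <- function() {
    # hold i occupies [start_i, start_i + hold_s]
    (seq_len(n_hold) - 1L) * (hold_s + ramp_s)
  }
  starts <- seg_bounds()
  total_s <- starts[n_hold] + hold_s
  # clean angle trajectory at time t (vectorized over t), per DoF
  traj <- function(t) {
    out <- matrix(NA_real_, length(t), ncol(schedule),
                  dimnames = list(NULL, colnames(schedule)))
    for (i in seq_len(n_hold)) {
      in_hold <- t >= starts[i] & t <= starts[i] + hold_s
      out[in_hold, ] <- matrix(schedule[i, ], sum(in_hold),
                               ncol(schedule), byrow = TRUE)
      if (i < n_hold) {
        r0 <- starts[i] + hold_s
        in_ramp <- t > r0 & t < starts[i + 1L]
        if (any(in_ramp)) {
          u <- (t[in_ramp] - r0) / ramp_s
          s <- (1 - cos(pi * u)) / 2
          out[in_ramp, ] <- outer(1 - s, schedule[i, ]) +
            outer(s, schedule[i + 1L, ])
        }
      }
    }
    out
  }
  with_seed(noise$seed, {
    t_ang <- seq(0, total_s, by = 1 / rates[1L])
    ang <- traj(t_ang) * 180 / pi
    ang <- ang + matrix(stats::rnorm(length(ang), 0,
                                     noise$angle_noise_sd_deg),
                        nrow(ang), ncol(ang))
    colnames(ang) <- colnames(schedule)
    # CoP: horizontal true CoM along the trajectory, computed at the angle
    # rate and interpolated to the plate rate, plus noise
    com_slow <- com_weighted_sum(truth_model, subject, traj(t_ang))
    t_cop <- seq(0, total_s, by = 1 / rates[2L])
    cop <- vapply(1:2, function(j)
      stats::spline(t_ang, com_slow[, j], xout = t_cop)$y,
      numeric(length(t_cop))) * 1000
    cop <- cop + matrix(stats::rnorm(length(cop), 0, noise$cop_noise_sd_mm),
                        nrow(cop), 2L)
    colnames(cop) <- c("cop.x", "cop.y")
    out <- list(angles = sesc_timeseries(ang, rates[1L]),
                cop = sesc_timeseries(cop, rates[2L]))
    mid_idx <- vapply(starts + hold_s / 2, function(tm)
      which.min(abs(t_ang - tm)), integer(1))
    attr(out, "schedule") <- list(
      start_s = starts, hold_s = hold_s,
      angles_deg = schedule * 180 / pi,
      cop_mm = 1000 * com_slow[mid_idx, 1:2, drop = FALSE])
    out
  })
}

#' Simulate a cohort of subjects with observations
#'
#' Draws `n_subjects` synthetic subjects, `postures_per_subject` random
#' static postures each from the truth model, and noisy CoP/angle
#' observations. Per-subject ground truth (parameters and the closed-form
#' SESC vector of every preset) is kept for scoring.
#'
#' @param n_subjects Number of subjects.
#' @param postures_per_subject Static postures per subject.
#' @param truth_model_id Preset generating the data (default `"d"`).
#' @param noise A [noise_spec()].
#' @param seed Master seed; all subject/posture/noise seeds derive from it.
#' @param ranges Joint-angle ranges (degrees).
#' @return Object of class `sesc_cohort`: list of per-subject records
#'   (`subject`, `truth_model`, `observations`).
#' @export
simulate_cohort <- function(n_subjects = 18, postures_per_subject = 98,
                            truth_model_id = "d", noise = noise_spec(),
                            seed = 1, ranges = default_ranges()) {
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    seed_s <- as.integer((as.numeric(seed) * 1000 + s) %% 2147483629)
    subject <- sample_subject(seed = seed_s)
    truth_model <- build_preset(truth_model_id, subject)
    postures <- sample_postures(truth_model, postures_per_subject,
                                ranges = ranges, seed = seed_s + 1L)
    noise_s <- noise_spec(noise$cop_noise_sd_mm, noise$angle_noise_sd_deg,
                          seed = seed_s + 2L)
    obs <- generate_observations(subject, truth_model, postures,
                                 noise = noise_s)
    subjects[[s]] <- list(id = sprintf("S%02d", s), subject = subject,
                          truth_model = truth_model, observations = obs)
  }
  structure(list(subjects = subjects, truth_model_id = truth_model_id,
                 seed = seed, noise = noise),
            class = "sesc_cohort")
}

#' @export
print.sesc_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, truth model (%s), %d postures each\n",
              length(x$subjects), x$truth_model_id,
              nrow(x$subjects[[1L]]$observations$postures)))
  invisible(x)
}
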