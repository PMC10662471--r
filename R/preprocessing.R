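# Raw-signal preprocessing: zero-phase low-pass filtering of force-plate
# CoP, resampling to the motion-capture rate, unification of the plate and
# body frames at the L5 origin, static-window detection, and the
# train/test posture split.
#
# Time-series channel conventions (file-boundary units): joint-angle
# channels are named "<joint>.<axis>" in degrees; CoP channels "cop.x",
# "cop.y" in mm; root-position channels "l5.x", "l5.y", "l5.z" in mm.

#' Construct a uniformly sampled time series
#'
#' @param data Numeric matrix, one column per named channel.
#' @param rate Sampling rate in Hz (> 0).
#' @param start Time of the first sample (s).
#' @return Object of class `sesc_timeseries` with elements `data`, `rate`,
#'   `time`.
#' @export
sesc_timeseries <- function(data, rate, start = 0) {
  data <- as.matrix(data)
  if (is.null(colnames(data)) || anyDuplicated(colnames(data)))
    stop("channels must have unique names")
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be positive (Hz)")
  structure(list(data = data, rate = rate,
                 time = start + (seq_len(nrow(data)) - 1L) / rate),
            class = "sesc_timeseries")
}

#' @export
print.sesc_timeseries <- function(x, ...) {
  cat(sprintf("time series: %d samples @ %g Hz, %d channels (%s)\n",
              nrow(x$data), x$rate, ncol(x$data),
              paste(utils::head(colnames(x$data), 5L), collapse = ", ")))
  invisible(x)
}

is_cop_channel <- function(ch) startsWith(ch, "cop.")
is_root_channel <- function(ch) startsWith(ch, "l5.")

# Zero-phase filtering with controlled edges: remove the line through the
# record's endpoints (so the odd-reflection pad injects no step), filter the
# padded remainder forward-backward, and re-add the line (pure passband).
pad_filtfilt <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  line <- x[1L] + (x[n] - x[1L]) * (seq_len(n) - 1L) / (n - 1L)
  y <- x - line
  yp <- c(2 * y[1L] - rev(y[2:(pad + 1L)]),
          y,
          2 * y[n] - rev(y[(n - pad):(n - 1L)]))
  signal::filtfilt(bf, yp)[(pad + 1L):(pad + n)] + line
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters every channel forward and backward (zero phase, DC gain 1) with
#' a Butterworth design of the given order; the effective magnitude
#' response is the squared one-pass response. Edges are handled by odd
#' reflection so constants and slow passband content pass through
#' unchanged over the whole record.
#'
#' @param series A [sesc_timeseries()].
#' @param order Filter order of the one-pass design.
#' @param cutoff_hz Cut-off frequency (Hz); must be below the Nyquist rate.
#' @return Filtered `sesc_timeseries` at the same rate.
#' @export
lowpass_filter <- function(series, order = 4, cutoff_hz = 10) {
  stopifnot(inherits(series, "sesc_timeseries"))
  if (cutoff_hz >= series$rate / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff_hz, series$rate / 2))
  bf <- signal::butter(order, cutoff_hz / (series$rate / 2))
  pad <- ceiling(6 * series$rate / cutoff_hz)
  out <- apply(series$data, 2L, function(x) pad_filtfilt(bf, x, pad))
  sesc_timeseries(out, series$rate, start = series$time[1L])
}

#' Resample a time series to a lower rate
#'
#' Band-limited downsampling: a zero-phase Butterworth anti-alias filter at
#' 45% of the target rate, followed by spline interpolation at the new
#' uniform timestamps. Upsampling is refused.
#'
#' @param series A [sesc_timeseries()].
#' @param target_hz Target rate (Hz), at most the source rate.
#' @return Resampled `sesc_timeseries` spanning the same time support
#'   (within one sample period).
#' @export
resample_series <- function(series, target_hz = 60) {
  stopifnot(inherits(series, "sesc_timeseries"))
  if (target_hz > series$rate)
    stop("upsampling is not supported (target rate above source rate)")
  if (target_hz == series$rate) return(series)
  filtered <- lowpass_filter(series, order = 4,
                             cutoff_hz = 0.45 * target_hz)
  t_new <- seq(series$time[1L], series$time[length(series$time)],
               by = 1 / target_hz)
  out <- apply(filtered$data, 2L, function(x)
    stats::spline(series$time, x, xout = t_new)$y)
  out <- matrix(out, nrow = length(t_new),
                dimnames = list(NULL, colnames(series$data)))
  sesc_timeseries(out, target_hz, start = t_new[1L])
}

#' Unify the force-plate and body frames
#'
#' Re-expresses the CoP in the L5-origin global frame by subtracting the
#' root (L5) horizontal position channel-wise, and merges angle and CoP
#' channels onto the angle series' time base (spline interpolation over the
#' overlapping support). Units are preserved (deg for angles, mm for CoP).
#'
#' @param angle_series Angle `sesc_timeseries` (the target time base).
#' @param cop_series CoP `sesc_timeseries` with channels `cop.x`, `cop.y`
#'   (mm), already resampled or at any rate (interpolated here).
#' @param l5_series Optional root-position series with channels `l5.x`,
#'   `l5.y` (mm) on any time base; `NULL` means the frames already share an
#'   origin.
#' @return Merged `sesc_timeseries` at the angle series' rate.
#' @export
unify_frames <- function(angle_series, cop_series, l5_series = NULL) {
  stopifnot(inherits(angle_series, "sesc_timeseries"),
            inherits(cop_series, "sesc_timeseries"))
  t0 <- max(angle_series$time[1L], cop_series$time[1L])
  t1 <- min(angle_series$time[length(angle_series$time)],
            cop_series$time[length(cop_series$time)])
  if (!is.null(l5_series)) {
    t0 <- max(t0, l5_series$time[1L])
    t1 <- min(t1, l5_series$time[length(l5_series$time)])
  }
  if (t0 >= t1) stop("time supports of the series do not overlap")
  keep <- angle_series$time >= t0 & angle_series$time <= t1
  tt <- angle_series$time[keep]
  interp <- function(s, ch) stats::spline(s$time, s$data[, ch], xout = tt)$y
  cop <- vapply(c("cop.x", "cop.y"), function(ch) interp(cop_series, ch),
                numeric(length(tt)))
  if (!is.null(l5_series)) {
    l5 <- vapply(c("l5.x", "l5.y"), function(ch) interp(l5_series, ch),
                 numeric(length(tt)))
    cop <- cop - l5
  }
  merged <- cbind(angle_series$data[keep, , drop = FALSE], cop)
  colnames(merged) <- c(colnames(angle_series$data), "cop.x", "cop.y")
  sesc_timeseries(merged, angle_series$rate, start = tt[1L])
}

# Running per-channel SD over a w-sample window, stride 1 sample, via
# cumulative sums. Returns (n - w + 1) x channels matrix.
running_sd <- function(x, w) {
  n <- nrow(x)
  cs <- rbind(0, apply(x, 2L, cumsum))
  cs2 <- rbind(0, apply(x^2, 2L, cumsum))
  idx <- seq_len(n - w + 1L)
  s1 <- cs[idx + w, , drop = FALSE] - cs[idx, , drop = FALSE]
  s2 <- cs2[idx + w, , drop = FALSE] - cs2[idx, , drop = FALSE]
  v <- (s2 - s1^2 / w) / (w - 1L)
  v[v < 0] <- 0
  sqrt(v)
}

#' Detect static postures in a merged time series
#'
#' Slides a window (stride one sample) over the merged angle + CoP series
#' and marks it static when every angle channel's SD is below
#' `angle_sd_max_deg` and both CoP channels' SDs are below
#' `cop_sd_max_mm`. Overlapping and adjacent passing windows are merged
#' into runs; runs shorter than `min_hold_s` are discarded. One posture is
#' emitted per surviving run, valued as the channel means over the run's
#' central window.
#'
#' @param series Merged `sesc_timeseries` (angle channels in deg, `cop.*`
#'   in mm).
#' @param window_s Criterion window length (s).
#' @param angle_sd_max_deg Per-channel angle SD threshold (deg).
#' @param cop_sd_max_mm Per-axis CoP SD threshold (mm).
#' @param min_hold_s Minimum merged-run duration (s).
#' @return List with `windows` (data frame `start_s`, `end_s`,
#'   `duration_s`) and `postures` (runs x channels matrix of central-window
#'   means, boundary units).
#' @export
detect_static <- function(series, window_s = 1.0, angle_sd_max_deg = 1.5,
                          cop_sd_max_mm = 6.0, min_hold_s = 5.0) {
  stopifnot(inherits(series, "sesc_timeseries"))
  ch <- colnames(series$data)
  cop_ch <- is_cop_channel(ch)
  if (!any(cop_ch)) stop("series carries no CoP channels")
  if (!any(!cop_ch)) stop("series carries no angle channels")
  w <- max(2L, round(window_s * series$rate))
  if (nrow(series$data) < w)
    return(list(windows = data.frame(start_s = numeric(0),
                                     end_s = numeric(0),
                                     duration_s = numeric(0)),
                postures = matrix(numeric(0), 0L, ncol(series$data),
                                  dimnames = list(NULL, ch))))
  sds <- running_sd(series$data, w)
  pass <- rowSums(sds[, !cop_ch, drop = FALSE] >= angle_sd_max_deg) == 0L &
          rowSums(sds[, cop_ch, drop = FALSE] >= cop_sd_max_mm) == 0L
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- list(); means <- list()
  for (g in keep) {
    i0 <- starts[g]                 # first passing window start index
    i1 <- ends[g] + w - 1L          # last sample of last passing window
    dur <- (i1 - i0) / series$rate
    if (dur < min_hold_s) next
    mid <- (i0 + i1) %/% 2L
    c0 <- max(1L, mid - w %/% 2L)
    c1 <- min(nrow(series$data), c0 + w - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = series$time[i0], end_s = series$time[i1], duration_s = dur)
    means[[length(means) + 1L]] <-
      colMeans(series$data[c0:c1, , drop = FALSE])
  }
  postures <- if (length(means)) do.call(rbind, means)
              else matrix(numeric(0), 0L, ncol(series$data),
                          dimnames = list(NULL, ch))
  list(windows = if (length(rows)) do.call(rbind, rows)
                 else data.frame(start_s = numeric(0), end_s = numeric(0),
                                 duration_s = numeric(0)),
       postures = postures)
}

#' Convert detected static postures to an observation set
#'
#' Maps the boundary units of [detect_static()] output (deg, mm) onto the
#' internal conventions (radians, meters) for a given model.
#'
#' @param postures The `postures` matrix from [detect_static()].
#' @param model The model whose DoF channels the series carries.
#' @return A [sesc_observations()] set (no true CoM).
#' @export
observations_from_static <- function(postures, model) {
  ch <- colnames(postures)
  ang <- postures[, !is_cop_channel(ch), drop = FALSE] * pi / 180
  cop <- postures[, c("cop.x", "cop.y"), drop = FALSE] / 1000
  sesc_observations(as_posture_matrix(ang, model), cop = cop, model = model)
}

#' Split postures into identification and testing sets
#'
#' @param k Number of postures (or an object with that many rows).
#' @param train_fraction Fraction used for identification.
#' @param seed Optional seed making the random split reproducible without
#'   touching the caller's RNG state.
#' @param chronological If `TRUE`, take the first `round(train_fraction*k)`
#'   postures instead of a random subset.
#' @param model Optional model: a training set smaller than
#'   [sesc_min_postures()] raises a warning.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_postures <- function(k, train_fraction = 0.75, seed = NULL,
                           chronological = FALSE, model = NULL) {
  if (inherits(k, "sesc_observations")) k <- nrow(k$postures)
  if (!is.null(dim(k))) k <- nrow(k)
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 postures to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)")
  n_train <- round(train_fraction * k)
  n_train <- max(1L, min(k - 1L, n_train))
  if (chronological) {
    train <- seq_len(n_train)
  } else {
    train <- sort(with_seed(seed, sample.int(k, n_train)))
  }
  if (!is.null(model) && n_train < sesc_min_postures(model))
    warning(sprintf("training set (%d) is below the minimum %d postures for model (%s)",
                    n_train, sesc_min_postures(model), model$model_id))
  list(train = train, test = setdiff(seq_len(k), train))
}

# Evaluate 'expr' under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
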