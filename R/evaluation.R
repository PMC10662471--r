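# Agreement evaluation of CoM estimates against a reference (static CoP):
# RMS error, Pearson/Spearman correlations, and Bland-Altman analysis with
# fixed bias, 95% limits of agreement, and a proportional-bias regression of
# differences on pairwise means (pooled, plus per-subject slopes).

#' Root-mean-square error of paired values
#'
#' @param estimate,reference Numeric vectors of equal length (any common
#'   unit).
#' @return `sqrt(mean((estimate - reference)^2))`.
#' @export
rms_error <- function(estimate, reference) {
  if (length(estimate) == 0L) stop("empty input")
  if (length(estimate) != length(reference))
    stop("'estimate' and 'reference' must have equal length")
  if (!all(is.finite(estimate)) || !all(is.finite(reference)))
    stop("values must be finite")
  sqrt(mean((estimate - reference)^2))
}

#' Pearson and Spearman correlation of estimates with reference
#'
#' @param estimate,reference Numeric vectors (length >= 3, nonzero
#'   variance).
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p` (two-sided).
#' @export
agreement_correlations <- function(estimate, reference) {
  if (length(estimate) < 3L) stop("need at least 3 pairs")
  if (stats::sd(estimate) == 0 || stats::sd(reference) == 0)
    stop(errorCondition("correlation undefined: zero variance input",
                        class = c("sesc_zero_variance_error", "error",
                                  "condition")))
  pe <- stats::cor.test(estimate, reference, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(estimate, reference, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Computes differences `d = estimate - reference` and pairwise means
#' `m = (estimate + reference) / 2`; the fixed bias is `mean(d)`, the 95%
#' limits of agreement are `bias +/- 1.96 sd(d)`, and proportional bias is
#' quantified by the pooled regression of `d` on `m` (slope, intercept,
#' R-squared, two-sided p). When `subject` is given, per-subject slopes are
#' also fitted and summarized by their mean and between-subject SD — a
#' two-stage stand-in for a mixed-effects proportional-bias model.
#'
#' A degenerate estimator that returns a constant per subject forces the
#' per-subject slope to exactly -2: with constant estimate `e`,
#' `d = 2e - 2m` identically.
#'
#' @param estimate,reference Numeric vectors (same unit, length >= 3).
#' @param subject Optional subject identifier per pair.
#' @return Object of class `bland_altman`: list with `bias`, `loa_lower`,
#'   `loa_upper`, `slope`, `intercept`, `r_squared`, `p_value`, `n`, the
#'   per-pair `differences`/`means`, and (if `subject` given) a
#'   `per_subject` data frame plus `slope_mean`/`slope_sd`.
#' @export
bland_altman <- function(estimate, reference, subject = NULL) {
  if (length(estimate) < 3L) stop("need at least 3 pairs")
  if (length(estimate) != length(reference))
    stop("'estimate' and 'reference' must have equal length")
  d <- estimate - reference
  m <- (estimate + reference) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  reg <- stats::lm(d ~ m)
  # a degenerate estimator gives an exact line; the fit itself is the result
  sm <- suppressWarnings(summary(reg))
  p_val <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  out <- list(
    bias = bias,
    loa_lower = bias - 1.96 * s,
    loa_upper = bias + 1.96 * s,
    slope = unname(stats::coef(reg)[2L]),
    intercept = unname(stats::coef(reg)[1L]),
    r_squared = sm$r.squared,
    p_value = p_val,
    n = length(d),
    differences = d,
    means = m
  )
  if (!is.null(subject)) {
    per <- do.call(rbind, lapply(split(seq_along(d), subject), function(idx) {
      if (length(idx) < 2L || stats::sd(m[idx]) == 0)
        return(data.frame(slope = NA_real_, intercept = NA_real_,
                          n = length(idx)))
      co <- stats::coef(stats::lm(d[idx] ~ m[idx]))
      data.frame(slope = unname(co[2L]), intercept = unname(co[1L]),
                 n = length(idx))
    }))
    per$subject <- rownames(per)
    rownames(per) <- NULL
    out$per_subject <- per[, c("subject", "slope", "intercept", "n")]
    out$slope_mean <- mean(per$slope, na.rm = TRUE)
    out$slope_sd <- stats::sd(per$slope, na.rm = TRUE)
  }
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  fixed bias %.3f, LoA [%.3f, %.3f]\n",
              x$bias, x$loa_lower, x$loa_upper))
  cat(sprintf("  proportional bias: y = %.3fx %+.3f, R^2 = %.3f (p = %.3g)\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  if (!is.null(x$per_subject))
    cat(sprintf("  per-subject slope %.3f +/- %.3f (%d subjects)\n",
                x$slope_mean, x$slope_sd, nrow(x$per_subject)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference", ...) {
  graphics::plot(x$means, x$differences, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "red", lty = 2)
  graphics::abline(a = x$intercept, b = x$slope, col = "darkgreen")
  invisible(x)
}

#' Cross-model comparison table
#'
#' Summarizes several models' estimates on identical posture sets: per
#' model and axis, the across-subject mean, SD and quartiles of per-subject
#' RMS error, pooled correlations, and the Bland-Altman summary. Pairwise
#' per-subject RMS differences between models are preserved for paired
#' testing.
#'
#' @param results Named list (one element per model id) of data frames with
#'   columns `subject`, `posture`, `axis` (`"AP"`/`"ML"`), `estimate`,
#'   `reference` (mm).
#' @return List with `table` (one row per model x axis), `per_subject_rms`
#'   (data frame of per-subject RMS values), and `pairwise` (per-subject
#'   paired RMS differences between models).
#' @export
compare_models <- function(results) {
  if (length(results) < 2L) stop("need at least two models to compare")
  key <- lapply(results, function(r)
    paste(r$subject, r$posture, r$axis, sep = "/"))
  ref <- sort(key[[1L]])
  for (k in key[-1L])
    if (!identical(sort(k), ref))
      stop("models were evaluated on mismatched posture sets")
  rows <- list(); per_rms <- list()
  for (mid in names(results)) {
    r <- results[[mid]]
    for (ax in unique(r$axis)) {
      ra <- r[r$axis == ax, ]
      sub_rms <- vapply(split(ra, ra$subject), function(s)
        rms_error(s$estimate, s$reference), numeric(1))
      co <- agreement_correlations(ra$estimate, ra$reference)
      ba <- bland_altman(ra$estimate, ra$reference, subject = ra$subject)
      one_subject <- length(sub_rms) < 2L
      rows[[paste(mid, ax)]] <- data.frame(
        model = mid, axis = ax,
        rms_mean = mean(sub_rms),
        rms_sd = if (one_subject) NA_real_ else stats::sd(sub_rms),
        rms_q25 = unname(stats::quantile(sub_rms, 0.25)),
        rms_q75 = unname(stats::quantile(sub_rms, 0.75)),
        pearson_r = co$pearson_r, spearman_rho = co$spearman_rho,
        bias = ba$bias, loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        slope = ba$slope, r_squared = ba$r_squared,
        stringsAsFactors = FALSE
      )
      per_rms[[paste(mid, ax)]] <- data.frame(
        model = mid, axis = ax, subject = names(sub_rms), rms = sub_rms,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per_rms)
  rownames(per) <- NULL
  mids <- names(results)
  pairwise <- list()
  for (i in seq_along(mids)) for (j in seq_along(mids)) if (i < j) {
    for (ax in unique(per$axis)) {
      a <- per[per$model == mids[i] & per$axis == ax, ]
      b <- per[per$model == mids[j] & per$axis == ax, ]
      b <- b[match(a$subject, b$subject), ]
      pairwise[[sprintf("%s-%s/%s", mids[i], mids[j], ax)]] <- data.frame(
        subject = a$subject, axis = ax, model_1 = mids[i], model_2 = mids[j],
        rms_diff = a$rms - b$rms, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, per_subject_rms = per,
       pairwise = do.call(rbind, pairwise))
}
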