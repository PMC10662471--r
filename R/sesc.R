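# The SESC (statically equivalent serial chain) core. The branched chain's
# CoM is rewritten as the end effector of a virtual serial chain,
#
#     CoM = d1 + [R_1 ... R_n] %*% [v_1; ...; v_n] = d1 + B V,
#
# where R_j is the global rotation of joint j's frame, and V stacks n
# constant 3-vectors of subject-specific inertial parameters. V is
# identified once, by least squares over static postures, and the full 3D
# CoM is afterwards available from joint angles alone.

#' SESC design matrix block for one posture
#'
#' Column block j is the global rotation of joint j (the ordered product of
#' joint rotations along the root-to-j path; translations excluded).
#'
#' @param model A `sesc_model`.
#' @param posture A single posture (radians).
#' @return A `3 x 3n` matrix, `n` the model's joint count.
#' @export
sesc_design_block <- function(model, posture) {
  fk <- forward_transforms(model, posture)
  do.call(cbind, lapply(fk, `[[`, "R"))
}

# Stacked design over k postures. rows = "xyz" (3 per posture, full CoM
# observations) or "xy" (2 per posture, horizontal CoP observations).
sesc_design <- function(model, postures, rows = c("xyz", "xy")) {
  rows <- match.arg(rows)
  postures <- as_posture_matrix(postures, model)
  sel <- if (rows == "xy") c(1L, 2L) else 1:3
  blocks <- lapply(seq_len(nrow(postures)), function(i)
    sesc_design_block(model, postures[i, , drop = FALSE])[sel, , drop = FALSE])
  B <- do.call(rbind, blocks)
  colnames(B) <- paste(rep(model$joints$name, each = 3L), c("x", "y", "z"),
                       sep = ".")
  B
}

#' Closed-form true SESC vector of a subject
#'
#' For known inertial parameters the SESC vector has the closed form
#' `v_j = (m_j c_j + sum over children q of subtree_mass(q) * offset_q) / M`:
#' each joint carries its own segment's first moment plus the moments of all
#' distal subtrees hanging from it. By construction
#' `d1 + B V = com_weighted_sum()` for every posture; this identity is the
#' package's central oracle.
#'
#' @param model A `sesc_model`.
#' @param subject A [sesc_subject()].
#' @return Named numeric vector of length `3n` (m), names
#'   `"<joint>.<x|y|z>"`.
#' @export
sesc_true_vector <- function(model, subject) {
  segs <- model_segments(model, subject)
  M <- sum(vapply(segs, `[[`, numeric(1), "mass"))
  if (M <= 0) stop("total mass must be positive")
  joints <- model$joints
  # subtree masses
  sub_mass <- vapply(segs, `[[`, numeric(1), "mass")
  for (i in rev(seq_len(nrow(joints)))) {
    p <- joints$parent[i]
    if (!is.na(p)) sub_mass[p] <- sub_mass[p] + sub_mass[joints$name[i]]
  }
  V <- numeric(0)
  for (i in seq_len(nrow(joints))) {
    jn <- joints$name[i]
    v <- segs[[jn]]$mass * segs[[jn]]$com
    kids <- which(joints$parent == jn)
    for (q in kids) {
      off <- c(joints$ox[q], joints$oy[q], joints$oz[q])
      v <- v + sub_mass[joints$name[q]] * off
    }
    V <- c(V, v / M)
  }
  names(V) <- paste(rep(joints$name, each = 3L), c("x", "y", "z"), sep = ".")
  V
}

#' Minimum posture count for 2D identification
#'
#' With two scalar observations (CoP x and y) per posture and `3n` unknowns,
#' at least `ceiling(3n/2)` distinct static postures are required.
#'
#' @param model A `sesc_model`.
#' @return Integer posture count.
#' @export
sesc_min_postures <- function(model) {
  as.integer(ceiling(1.5 * nrow(model$joints)))
}

#' Bundle postures with CoP (and optional true CoM) observations
#'
#' The identification currency: static postures paired with force-plate CoP
#' readings, optionally carrying the true 3D CoM (synthetic data) for
#' scoring.
#'
#' @param postures Posture matrix (radians).
#' @param cop `k x 2` matrix of CoP AP/ML coordinates (m), or `NULL`.
#' @param com Optional `k x 3` matrix of true CoM positions (m).
#' @param d1 Root positions: 3-vector or `k x 3` matrix (m).
#' @param model The model whose DoF naming `postures` follows.
#' @return An object of class `sesc_observations`.
#' @export
sesc_observations <- function(postures, cop = NULL, com = NULL,
                              d1 = c(0, 0, 0), model = NULL) {
  if (!is.null(model)) postures <- as_posture_matrix(postures, model)
  k <- nrow(postures)
  if (!is.null(cop)) {
    cop <- as.matrix(cop)
    stopifnot(nrow(cop) == k, ncol(cop) == 2L)
    if (!all(is.finite(cop))) stop("CoP values must be finite")
  }
  if (!is.null(com)) {
    com <- as.matrix(com)
    stopifnot(nrow(com) == k, ncol(com) == 3L)
  }
  structure(list(postures = postures, cop = cop, com = com,
                 d1 = root_matrix(d1, k),
                 model_id = if (is.null(model)) NA_character_
                            else model$model_id),
            class = "sesc_observations")
}

#' @export
print.sesc_observations <- function(x, ...) {
  cat(sprintf("SESC observation set: %d postures, %d angle DoF%s%s\n",
              nrow(x$postures), ncol(x$postures),
              if (!is.null(x$cop)) ", CoP" else "",
              if (!is.null(x$com)) ", true CoM" else ""))
  invisible(x)
}

subset_observations <- function(obs, idx) {
  sesc_observations(obs$postures[idx, , drop = FALSE],
                    cop = if (!is.null(obs$cop)) obs$cop[idx, , drop = FALSE],
                    com = if (!is.null(obs$com)) obs$com[idx, , drop = FALSE],
                    d1 = obs$d1[idx, , drop = FALSE])
}

#' Identify the SESC vector of a subject
#'
#' Fits the constant subject-specific vector `V` by minimum-norm least
#' squares (Moore-Penrose pseudoinverse via a rank-revealing SVD with
#' relative singular-value cutoff `tol`).
#'
#' With `observe = "cop"` (the experimental situation) only the horizontal
#' CoM projection is available: the vertical row of each posture's design
#' block is dropped and the stacked `2k x 3n` system
#' `B' V = CoP - d1` is solved; the returned `V` is full length and
#' usable for 3D estimation. With `observe = "com"` all three rows are used
#' (the idealized situation with known 3D CoM).
#'
#' A rank-deficient system is an error for `observe = "com"`; for
#' `observe = "cop"` it is reported as a warning naming the unidentifiable
#' columns (e.g. every mediolateral component under a flexion-only model)
#' and the minimum-norm solution is returned — the estimator is then
#' degenerate along the deficient directions.
#'
#' @param observations A [sesc_observations()] set. Postures must follow
#'   `model`'s DoF naming (project first with [project_posture()] if they
#'   come from a richer model).
#' @param model The `sesc_model` to fit.
#' @param observe `"cop"` (2D horizontal observations) or `"com"` (full 3D).
#' @param tol Relative singular-value cutoff of the pseudoinverse.
#' @param enforce_min_postures If `TRUE` (default), fewer than
#'   [sesc_min_postures()] postures in the 2D case is an error of class
#'   `"sesc_shortage_error"`.
#'
#' @return An object of class `sesc`: list with the identified vector `V`,
#'   diagnostics (`rank`, `n_col`, `condition`, `deficient`,
#'   `residual_rms`), the `model`, posture count `k`, and training data.
#' @seealso [predict.sesc()], [sesc_true_vector()]
#' @export
sesc_fit <- function(observations, model, observe = c("cop", "com"),
                     tol = 1e-10, enforce_min_postures = TRUE) {
  observe <- match.arg(observe)
  stopifnot(inherits(observations, "sesc_observations"),
            inherits(model, "sesc_model"))
  k <- nrow(observations$postures)
  n <- nrow(model$joints)
  if (observe == "cop") {
    if (is.null(observations$cop))
      stop("observations carry no CoP; cannot identify from 2D data")
    if (enforce_min_postures && k < sesc_min_postures(model))
      stop(errorCondition(
        sprintf(paste0("%d postures are fewer than the minimum %d ",
                       "(= ceiling(3n/2), n = %d joints) required for 2D ",
                       "identification of model (%s)"),
                k, sesc_min_postures(model), n, model$model_id),
        class = c("sesc_shortage_error", "error", "condition")))
    B <- sesc_design(model, observations$postures, rows = "xy")
    y <- as.numeric(t(observations$cop - observations$d1[, 1:2]))
  } else {
    if (is.null(observations$com))
      stop("observations carry no 3D CoM; use observe = \"cop\"")
    if (nrow(observations$postures) * 3L < 3L * n)
      stop(errorCondition(
        sprintf("%d postures give %d rows, fewer than the %d unknowns",
                k, 3L * k, 3L * n),
        class = c("sesc_shortage_error", "error", "condition")))
    B <- sesc_design(model, observations$postures, rows = "xyz")
    y <- as.numeric(t(observations$com - observations$d1))
  }
  sol <- pinv_solve(B, y, tol = tol)
  if (sol$rank < sol$n_col) {
    msg <- sprintf(
      "rank-deficient design: rank %d of %d columns (deficiency %d); unidentifiable columns: %s",
      sol$rank, sol$n_col, sol$n_col - sol$rank,
      paste(colnames(B)[sol$deficient], collapse = ", "))
    if (observe == "com")
      stop(errorCondition(msg, class = c("sesc_rank_error", "error",
                                         "condition")))
    warning(warningCondition(msg, class = c("sesc_rank_warning", "warning",
                                            "condition")))
  }
  V <- stats::setNames(sol$x, colnames(B))
  res <- y - drop(B %*% V)
  fit <- structure(list(
    V = V,
    model = model,
    observe = observe,
    k = k,
    rank = sol$rank,
    n_col = sol$n_col,
    condition = sol$condition,
    deficient = stats::setNames(sol$deficient, colnames(B)),
    residual_rms = sqrt(mean(res^2)),
    residuals = res,
    observations = observations,
    call = match.call()
  ), class = "sesc")
  fit
}

#' @export
print.sesc <- function(x, ...) {
  cat(sprintf("SESC fit, model (%s): %d joints, %d DoF\n",
              x$model$model_id, nrow(x$model$joints), count_dof(x$model)))
  cat(sprintf("  identified from %d postures (%s observations)\n",
              x$k, if (x$observe == "cop") "2D CoP" else "3D CoM"))
  cat(sprintf("  rank %d / %d, condition %.3g, residual RMS %.3f mm\n",
              x$rank, x$n_col, x$condition, 1000 * x$residual_rms))
  if (any(x$deficient))
    cat("  degenerate directions:",
        paste(names(x$deficient)[x$deficient], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sesc <- function(object, ...) {
  structure(list(fit = object), class = "summary.sesc")
}

#' @export
print.summary.sesc <- function(x, ...) {
  print(x$fit)
  V <- x$fit$V
  tab <- data.frame(
    joint = sub("\\.[xyz]$", "", names(V)),
    component = sub("^.*\\.", "", names(V)),
    value_mm = round(1000 * unname(V), 3)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sesc <- function(object, ...) object$V

#' Estimate 3D CoM from joint angles
#'
#' Applies the affine SESC form `CoM = d1 + B V` to new postures, using the
#' identified (or a supplied) vector `V`. Only joint angles are needed; this
#' is the estimation-phase computation.
#'
#' @param object A fitted [sesc_fit()] object.
#' @param newdata Posture matrix, or a [sesc_observations()] set (its
#'   per-posture root positions `d1` are then used).
#' @param d1 Root positions for a plain posture matrix.
#' @param ... Unused.
#' @return A `k x 3` matrix of estimated CoM positions (m).
#' @export
predict.sesc <- function(object, newdata, d1 = c(0, 0, 0), ...) {
  if (missing(newdata)) newdata <- object$observations
  if (inherits(newdata, "sesc_observations")) {
    d1 <- newdata$d1
    newdata <- newdata$postures
  }
  estimate_com(object$model, object$V, newdata, d1 = d1)
}

#' @export
fitted.sesc <- function(object, ...) predict(object)

#' @export
residuals.sesc <- function(object, ...) object$residuals

#' Evaluate the SESC form directly
#'
#' `estimate_com()` is the bare affine map `d1 + B(posture) V`; it is what
#' [predict.sesc()] calls and is exported for use with an externally
#' obtained `V` (e.g. the closed-form [sesc_true_vector()]).
#'
#' @param model A `sesc_model`.
#' @param V SESC vector of length `3n` (m).
#' @param postures Posture matrix (radians).
#' @param d1 Root positions (3-vector or `k x 3`, m).
#' @return `k x 3` matrix of CoM positions (m).
#' @export
estimate_com <- function(model, V, postures, d1 = c(0, 0, 0)) {
  postures <- as_posture_matrix(postures, model)
  if (length(V) != 3L * nrow(model$joints))
    stop(sprintf("V has length %d; model (%s) needs %d",
                 length(V), model$model_id, 3L * nrow(model$joints)))
  d1 <- root_matrix(d1, nrow(postures))
  out <- matrix(NA_real_, nrow(postures), 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(nrow(postures))) {
    B <- sesc_design_block(model, postures[i, , drop = FALSE])
    out[i, ] <- d1[i, ] + drop(B %*% V)
  }
  out
}

#' Bland-Altman plot of estimates against reference
#'
#' Scatter of difference against pairwise mean along one horizontal axis,
#' with bias and 95% limits-of-agreement lines and the fitted
#' proportional-bias regression line.
#'
#' @param x A fitted `sesc` object.
#' @param newdata Observation set with CoP; defaults to the training set.
#' @param axis `"x"` (AP) or `"y"` (ML).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sesc <- function(x, newdata = NULL, axis = c("x", "y"), ...) {
  axis <- match.arg(axis)
  obs <- if (is.null(newdata)) x$observations else newdata
  if (is.null(obs$cop)) stop("observation set carries no CoP reference")
  est <- predict(x, obs)
  j <- if (axis == "x") 1L else 2L
  ba <- bland_altman(1000 * est[, j], 1000 * obs$cop[, j])
  plot(ba, xlab = sprintf("mean of estimate and CoP, %s axis (mm)",
                          if (axis == "x") "AP" else "ML"),
       ylab = "estimate - CoP (mm)", ...)
  invisible(ba)
}
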