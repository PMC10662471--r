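# Subject-specific inertial parameters: per-segment masses and local CoM
# offsets on the full reference skeleton, plus the subject's joint geometry.
# These are the ground truth the synthetic module draws and the quantities
# the SESC vector encodes.

#' Construct subject parameters
#'
#' @param total_mass Total body mass in kg (> 0).
#' @param segments Data frame with columns `joint` (attachment joint on the
#'   full skeleton), `frac` (mass fraction, summing to 1), `cx`, `cy`, `cz`
#'   (local CoM in the segment frame, m).
#' @param geometry Data frame in the [full_skeleton()] layout (`name`,
#'   `parent`, `ox`, `oy`, `oz`), meters.
#'
#' @return An object of class `sesc_subject`.
#' @export
sesc_subject <- function(total_mass, segments = full_segments(),
                         geometry = full_skeleton()) {
  if (!is.numeric(total_mass) || total_mass <= 0)
    stop("'total_mass' must be a positive number (kg)")
  if (any(segments$frac < 0)) stop("segment mass fractions must be >= 0")
  if (abs(sum(segments$frac) - 1) > 1e-8)
    stop("segment mass fractions must sum to 1")
  structure(list(total_mass = total_mass, segments = segments,
                 geometry = geometry),
            class = "sesc_subject")
}

#' @export
print.sesc_subject <- function(x, ...) {
  cat(sprintf("SESC subject: total mass %.1f kg, %d segments\n",
              x$total_mass, nrow(x$segments)))
  invisible(x)
}

# Lump the subject's full-skeleton segments onto the joints of a (possibly
# simpler) model. Each segment is assigned to the nearest model joint on its
# root-ward path; merged rigid bodies get a combined mass and a combined
# local CoM computed at the neutral pose (exact, because the skipped joints
# do not exist in the model and therefore never move).
model_segments <- function(model, subject) {
  skel <- subject$geometry
  parent_of <- structure(skel$parent, names = skel$name)
  off <- as.matrix(skel[, c("ox", "oy", "oz")])
  rownames(off) <- skel$name
  segs <- subject$segments
  owner <- character(nrow(segs))
  cum <- matrix(0, nrow(segs), 3L)
  for (i in seq_len(nrow(segs))) {
    j <- segs$joint[i]
    o <- c(0, 0, 0)
    while (!(j %in% model$joints$name)) {
      o <- o + off[j, ]
      j <- parent_of[[j]]
      if (is.na(j)) stop("segment '", segs$joint[i],
                         "' cannot be attached to model joints")
    }
    owner[i] <- j
    cum[i, ] <- o
  }
  M <- subject$total_mass
  out <- lapply(model$joints$name, function(jn) {
    idx <- which(owner == jn)
    m <- sum(segs$frac[idx]) * M
    com <- c(0, 0, 0)
    if (m > 0) {
      w <- segs$frac[idx] * M
      pts <- cum[idx, , drop = FALSE] +
        as.matrix(segs[idx, c("cx", "cy", "cz")])
      com <- colSums(pts * w) / m
    }
    list(joint = jn, mass = m, com = com)
  })
  names(out) <- model$joints$name
  out
}

#' Forward kinematics of a posture
#'
#' Computes the global homogeneous transform (rotation + translation pair)
#' of every joint frame by chaining joint rotations and constant offsets
#' along the unique root-to-joint path.
#'
#' @param model A `sesc_model`.
#' @param posture A single posture: named numeric vector or 1-row matrix of
#'   angles in radians covering [dof_names()] of the model.
#' @param d1 Global position of the root joint (m).
#'
#' @return Named list per joint with elements `R` (3x3 global rotation) and
#'   `t` (global position, m).
#' @export
forward_transforms <- function(model, posture, d1 = c(0, 0, 0)) {
  posture <- as_posture_matrix(posture, model)
  if (nrow(posture) != 1L) stop("'posture' must be a single posture")
  joints <- model$joints
  Rg <- vector("list", nrow(joints))
  tg <- vector("list", nrow(joints))
  names(Rg) <- names(tg) <- joints$name
  for (i in seq_len(nrow(joints))) {
    axes <- strsplit(joints$dof[i], "")[[1L]]
    ang <- posture[1L, paste(joints$name[i], axes, sep = ".")]
    Rj <- joint_rotation(axes, ang)
    p <- joints$parent[i]
    if (is.na(p)) {
      Rg[[i]] <- Rj
      tg[[i]] <- as.numeric(d1)
    } else {
      off <- c(joints$ox[i], joints$oy[i], joints$oz[i])
      Rg[[i]] <- Rg[[p]] %*% Rj
      tg[[i]] <- tg[[p]] + drop(Rg[[p]] %*% off)
    }
  }
  mapply(function(R, t) list(R = R, t = t), Rg, tg, SIMPLIFY = FALSE)
}

#' Whole-body CoM by the weighted-segment formula
#'
#' The classical segmental computation: the body CoM is the mass-weighted
#' mean of the global segment CoM positions,
#' `CoM = sum(m_i * C_i^G) / M`. This is the brute-force oracle against
#' which the SESC form is verified.
#'
#' @param model A `sesc_model`.
#' @param subject A [sesc_subject()].
#' @param postures Posture matrix (k postures, radians).
#' @param d1 Global root position (m): a 3-vector, or a `k x 3` matrix for
#'   per-posture root positions.
#'
#' @return A `k x 3` matrix of CoM positions (m), columns `x`, `y`, `z`.
#' @export
com_weighted_sum <- function(model, subject, postures, d1 = c(0, 0, 0)) {
  postures <- as_posture_matrix(postures, model)
  d1 <- root_matrix(d1, nrow(postures))
  segs <- model_segments(model, subject)
  M <- sum(vapply(segs, `[[`, numeric(1), "mass"))
  if (M <= 0) stop("total mass must be positive")
  out <- matrix(NA_real_, nrow(postures), 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(nrow(postures))) {
    fk <- forward_transforms(model, postures[i, , drop = FALSE], d1[i, ])
    acc <- c(0, 0, 0)
    for (s in segs)
      acc <- acc + s$mass * (fk[[s$joint]]$t + drop(fk[[s$joint]]$R %*% s$com))
    out[i, ] <- acc / M
  }
  out
}

# Recycle a root position spec into a k x 3 matrix.
root_matrix <- function(d1, k) {
  if (is.null(dim(d1))) d1 <- matrix(d1, nrow = k, ncol = 3L, byrow = TRUE)
  d1 <- as.matrix(d1)
  stopifnot(nrow(d1) == k, ncol(d1) == 3L)
  d1
}
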