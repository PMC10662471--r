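# Preset biomechanical structures. Four branched kinematic trees of graded
# complexity, all rooted at the lumbosacral joint (L5/S1):
#
#   (a) 7 joints / 7 segments,  7 DoF: L5/S1, shoulders, hips, ankles, all
#       hinge (flexion/extension about Y); thigh+shank lumped between hip
#       and ankle.
#   (b) 9 joints / 9 segments, 13 DoF: hinge L5/S1, knees, ankles; universal
#       (YX) shoulders and hips.
#   (c) 7 joints / 7 segments, 17 DoF: spherical (YXZ) L5/S1, shoulders,
#       hips; hinge knees; shank+foot lumped below the knee.
#   (d) 9 joints / 9 segments, 19 DoF: as (b) with L5/S1, shoulders and hips
#       upgraded to spherical.
#
# The prose description of model (a) lists L5/S1, shoulders and ankles; its
# stated 7 joints and the two 3-deep leg chains of the corresponding CoM
# expansion force the hips to be present as well, so the canonical joint set
# here includes them. Arms are single segments (no elbows); the head is
# lumped with the trunk.

# Full reference skeleton: every joint any preset can use, topologically
# ordered root-first. Offsets are in the parent segment frame, meters,
# for a neutral standing pose of a ~1.75 m adult; Z up, X anterior.
full_skeleton <- function() {
  data.frame(
    name   = c("l5s1", "shoulder_l", "shoulder_r", "hip_l", "hip_r",
               "knee_l", "knee_r", "ankle_l", "ankle_r"),
    parent = c(NA, "l5s1", "l5s1", "l5s1", "l5s1",
               "hip_l", "hip_r", "knee_l", "knee_r"),
    ox = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    oy = c(0, 0.20, -0.20, 0.09, -0.09, 0, 0, 0, 0),
    oz = c(0, 0.45, 0.45, -0.10, -0.10, -0.44, -0.44, -0.43, -0.43),
    stringsAsFactors = FALSE
  )
}

# Segments of the reference skeleton, one rigid body distal to each joint.
# Masses as fractions of total body mass, local CoM in the segment frame (m).
# Fractions follow common anthropometric proportions (trunk+head+pelvis,
# whole arm, thigh, shank, foot) and sum to 1.
full_segments <- function() {
  data.frame(
    joint = c("l5s1", "shoulder_l", "shoulder_r", "hip_l", "hip_r",
              "knee_l", "knee_r", "ankle_l", "ankle_r"),
    frac  = c(0.578, 0.050, 0.050, 0.100, 0.100,
              0.0465, 0.0465, 0.0145, 0.0145),
    cx = c(0.01, 0, 0, 0, 0, 0, 0, 0.05, 0.05),
    cy = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    cz = c(0.20, -0.28, -0.28, -0.19, -0.19, -0.19, -0.19, -0.04, -0.04),
    stringsAsFactors = FALSE
  )
}

# DoF sequences per preset, as strings over {y, x, z} in composition order.
preset_dof <- function(model_id) {
  switch(model_id,
    a = c(l5s1 = "y", shoulder = "y", hip = "y", ankle = "y"),
    b = c(l5s1 = "y", shoulder = "yx", hip = "yx", knee = "y", ankle = "y"),
    c = c(l5s1 = "yxz", shoulder = "yxz", hip = "yxz", knee = "y"),
    d = c(l5s1 = "yxz", shoulder = "yxz", hip = "yxz", knee = "y",
          ankle = "y"),
    stop(sprintf("unknown model id '%s' (expected one of a, b, c, d)",
                 model_id))
  )
}

joint_kind <- function(name) sub("_[lr]$", "", name)

#' Build a preset biomechanical model
#'
#' Constructs one of the four preset branched-chain structures as a
#' kinematic tree. Geometry (constant inter-joint offsets) is taken from
#' `subject` when given, otherwise from a neutral adult proportional
#' template. Joints absent from a preset (e.g. knees in model `"a"`) are
#' skipped and their offsets accumulated into the surviving child joint, so
#' every preset is a consistent rigid-body tree at the neutral pose.
#'
#' @param model_id One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param subject Optional [sesc_subject] supplying geometry.
#'
#' @return An object of class `sesc_model`: a list with `model_id` and a
#'   `joints` data frame (`name`, `parent`, `dof`, `ox`, `oy`, `oz`),
#'   root first.
#' @examples
#' m <- build_preset("b")
#' count_dof(m) # 13
#' @export
build_preset <- function(model_id, subject = NULL) {
  model_id <- as.character(model_id)
  dof_map <- preset_dof(model_id)
  skel <- if (is.null(subject)) full_skeleton() else subject$geometry
  keep <- joint_kind(skel$name) %in% names(dof_map)
  joints <- skel[keep, , drop = FALSE]
  # reattach across skipped joints, accumulating offsets (neutral pose)
  off <- as.matrix(skel[, c("ox", "oy", "oz")])
  rownames(off) <- skel$name
  parent_of <- structure(skel$parent, names = skel$name)
  for (i in seq_len(nrow(joints))) {
    p <- joints$parent[i]
    o <- off[joints$name[i], ]
    while (!is.na(p) && !(p %in% joints$name)) {
      o <- o + off[p, ]
      p <- parent_of[[p]]
    }
    joints$parent[i] <- p
    joints$ox[i] <- o[1L]; joints$oy[i] <- o[2L]; joints$oz[i] <- o[3L]
  }
  joints$dof <- unname(dof_map[joint_kind(joints$name)])
  structure(
    list(model_id = model_id,
         joints = joints[, c("name", "parent", "dof", "ox", "oy", "oz")]),
    class = "sesc_model"
  )
}

#' @export
print.sesc_model <- function(x, ...) {
  cat(sprintf("SESC biomechanical model (%s): %d joints, %d DoF\n",
              x$model_id, nrow(x$joints), count_dof(x)))
  print(x$joints, row.names = FALSE)
  invisible(x)
}

#' Total degrees of freedom of a model
#'
#' @param model An [build_preset()] model.
#' @return Integer, the sum of per-joint DoF counts.
#' @export
count_dof <- function(model) {
  stopifnot(inherits(model, "sesc_model"))
  sum(nchar(model$joints$dof))
}

# Ordered names of the model's angle coordinates: "<joint>.<axis>".
#' DoF coordinate names of a model
#'
#' @param model A `sesc_model`.
#' @return Character vector of `"<joint>.<axis>"` names, in joint order.
#' @export
dof_names <- function(model) {
  unlist(lapply(seq_len(nrow(model$joints)), function(i) {
    axes <- strsplit(model$joints$dof[i], "")[[1L]]
    paste(model$joints$name[i], axes, sep = ".")
  }), use.names = FALSE)
}

# Coerce a posture input (named vector / list / matrix) into a k x DoF
# matrix with the model's dof_names() columns, radians.
as_posture_matrix <- function(postures, model) {
  dn <- dof_names(model)
  if (is.list(postures) && !is.data.frame(postures))
    postures <- do.call(rbind, lapply(postures, function(p) p[dn]))
  if (is.null(dim(postures))) postures <- matrix(postures, nrow = 1L,
                                                 dimnames = list(NULL, names(postures)))
  postures <- as.matrix(postures)
  if (is.null(colnames(postures))) {
    if (ncol(postures) != length(dn))
      stop("unnamed posture matrix must have exactly ", length(dn),
           " columns for model (", model$model_id, ")")
    colnames(postures) <- dn
  }
  missing <- setdiff(dn, colnames(postures))
  if (length(missing))
    stop("posture is missing angles: ", paste(missing, collapse = ", "))
  out <- postures[, dn, drop = FALSE]
  if (!all(is.finite(out))) stop("posture angles must be finite")
  out
}

#' Neutral (all-zero) postures for a model
#'
#' @param model A `sesc_model`.
#' @param k Number of identical neutral postures.
#' @return A `k x DoF` matrix of zeros with [dof_names()] columns (radians).
#' @export
neutral_posture <- function(model, k = 1L) {
  dn <- dof_names(model)
  matrix(0, nrow = k, ncol = length(dn), dimnames = list(NULL, dn))
}

#' Project postures of a rich model onto a simpler model
#'
#' Re-expresses each target joint's rotation, computed from the source
#' model's angles, in the ZXY-fixed decomposition and retains exactly the
#' angle components named by the target joint's DoF sequence. Joints of the
#' source model absent from the target are dropped; their motion becomes
#' unmodeled error by design. Postures whose decomposition sits at gimbal
#' lock are flagged via the returned `"flagged"` attribute.
#'
#' @param postures Posture matrix for `from_model` (radians).
#' @param from_model,to_model `sesc_model` objects; every joint of
#'   `to_model` must exist in `from_model`.
#' @return Posture matrix for `to_model` with logical attribute `"flagged"`
#'   (one entry per posture).
#' @export
project_posture <- function(postures, from_model, to_model) {
  postures <- as_posture_matrix(postures, from_model)
  missing <- setdiff(to_model$joints$name, from_model$joints$name)
  if (length(missing))
    stop("target joints absent from source model: ",
         paste(missing, collapse = ", "))
  k <- nrow(postures)
  out <- neutral_posture(to_model, k)
  flagged <- logical(k)
  from_j <- from_model$joints
  for (jn in to_model$joints$name) {
    src_dof <- strsplit(from_j$dof[from_j$name == jn], "")[[1L]]
    tgt_dof <- strsplit(
      to_model$joints$dof[to_model$joints$name == jn], "")[[1L]]
    src_cols <- paste(jn, src_dof, sep = ".")
    for (i in seq_len(k)) {
      R <- joint_rotation(src_dof, postures[i, src_cols])
      ang <- euler_zxy(R)
      if (isTRUE(attr(ang, "gimbal"))) flagged[i] <- TRUE
      out[i, paste(jn, tgt_dof, sep = ".")] <- ang[tgt_dof]
    }
  }
  attr(out, "flagged") <- flagged
  out
}

#' Write / read a model description file
#'
#' YAML round-trip of a model's joint table, with offsets in millimeters at
#' the file boundary.
#'
#' @param model A `sesc_model`.
#' @param path File path.
#' @return `write_model_yaml()` returns `path` invisibly;
#'   `read_model_yaml()` returns a `sesc_model`.
#' @export
write_model_yaml <- function(model, path) {
  joints <- lapply(seq_len(nrow(model$joints)), function(i) {
    j <- model$joints[i, ]
    list(name = j$name,
         parent = if (is.na(j$parent)) "root" else j$parent,
         offset_mm = as.numeric(c(j$ox, j$oy, j$oz)) * 1000,
         dof = strsplit(j$dof, "")[[1L]])
  })
  yaml::write_yaml(list(model_id = model$model_id, joints = joints), path,
                   precision = 12L)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  joints <- do.call(rbind, lapply(y$joints, function(j) {
    data.frame(name = j$name,
               parent = if (identical(j$parent, "root")) NA_character_
                        else j$parent,
               dof = paste(j$dof, collapse = ""),
               ox = j$offset_mm[1L] / 1000,
               oy = j$offset_mm[2L] / 1000,
               oz = j$offset_mm[3L] / 1000,
               stringsAsFactors = FALSE)
  }))
  structure(list(model_id = y$model_id, joints = joints),
            class = "sesc_model")
}
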