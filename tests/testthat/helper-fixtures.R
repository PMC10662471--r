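# Small in-code fixtures shared across test files.

# Two-segment planar toy: unit masses, segments stacked along -Z.
# Hand-derived ground truth: v1 = (0,0,-0.375), v2 = (0,0,-0.125),
# CoM at zero angles = (0,0,-0.5).
toy_chain <- function() {
  geom <- data.frame(name = c("j1", "j2"), parent = c(NA, "j1"),
                     ox = c(0, 0), oy = c(0, 0), oz = c(0, -0.5),
                     stringsAsFactors = FALSE)
  model <- structure(list(
    model_id = "custom",
    joints = cbind(geom[, c("name", "parent")],
                   dof = c("y", "y"), geom[, c("ox", "oy", "oz")])),
    class = "sesc_model")
  subject <- sesc_subject(
    2,
    segments = data.frame(joint = c("j1", "j2"), frac = c(0.5, 0.5),
                          cx = 0, cy = 0, cz = -0.25,
                          stringsAsFactors = FALSE),
    geometry = geom)
  list(model = model, subject = subject)
}

# A well-conditioned custom 2-joint spherical chain (no structural B-column
# degeneracy), for full-3D identification tests.
spherical_chain <- function() {
  geom <- data.frame(name = c("j1", "j2"), parent = c(NA, "j1"),
                     ox = c(0, 0.1), oy = c(0, 0.05), oz = c(0, -0.4),
                     stringsAsFactors = FALSE)
  model <- structure(list(
    model_id = "custom",
    joints = cbind(geom[, c("name", "parent")],
                   dof = c("yxz", "yxz"), geom[, c("ox", "oy", "oz")])),
    class = "sesc_model")
  subject <- sesc_subject(
    10,
    segments = data.frame(joint = c("j1", "j2"), frac = c(0.7, 0.3),
                          cx = c(0.02, 0), cy = c(0, 0.01),
                          cz = c(-0.2, -0.25), stringsAsFactors = FALSE),
    geometry = geom)
  list(model = model, subject = subject)
}

subset_obs_for_test <- function(obs, idx) sescom:::subset_observations(obs, idx)

random_angles <- function(model, k, seed) {
  dn <- dof_names(model)
  set.seed(seed)
  matrix(stats::runif(k * length(dn), -1.2, 1.2), nrow = k,
         dimnames = list(NULL, dn))
}
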