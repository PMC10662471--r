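# File formats and the end-to-end pipeline: CSV datasets (degrees and
# millimeters at every file boundary), YAML configuration, JSON
# reports/manifests, and the orchestration simulate -> split -> identify
# per model -> estimate -> evaluate.

#' Default run configuration
#'
#' All tunable pipeline parameters with their defaults: Butterworth order 4
#' and 10 Hz cut-off, 60 Hz working rate, 1 s criterion window with
#' 1.5 deg / 6 mm SD thresholds, 5 s minimum hold, and a 75% identification
#' split.
#'
#' @param models Preset ids to fit.
#' @param butter_order,cutoff_hz,target_hz,window_s,angle_sd_max_deg,cop_sd_max_mm,min_hold_s,train_fraction
#'   Pipeline parameters (see [lowpass_filter()], [detect_static()],
#'   [split_postures()]).
#' @param seed Master seed.
#' @return Named list of class `sesc_config`.
#' @export
sesc_config <- function(models = c("a", "b", "c", "d"), butter_order = 4,
                        cutoff_hz = 10, target_hz = 60, window_s = 1,
                        angle_sd_max_deg = 1.5, cop_sd_max_mm = 6,
                        min_hold_s = 5, train_fraction = 0.75, seed = 1) {
  cfg <- list(models = models, butter_order = butter_order,
              cutoff_hz = cutoff_hz, target_hz = target_hz,
              window_s = window_s, angle_sd_max_deg = angle_sd_max_deg,
              cop_sd_max_mm = cop_sd_max_mm, min_hold_s = min_hold_s,
              train_fraction = train_fraction, seed = seed)
  num <- cfg[!(names(cfg) %in% c("models", "seed"))]
  if (any(!vapply(num, function(v) is.numeric(v) && v > 0, logical(1))))
    stop("all numeric configuration parameters must be positive")
  if (train_fraction >= 1) stop("'train_fraction' must be in (0, 1)")
  if (!all(models %in% c("a", "b", "c", "d")))
    stop("unknown model id(s): ",
         paste(setdiff(models, c("a", "b", "c", "d")), collapse = ", "))
  structure(cfg, class = "sesc_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are a schema error naming the key.
#'
#' @param path YAML file.
#' @return A [sesc_config()].
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sesc_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(sesc_config, y)
}

#' Write / read an observation dataset as CSV
#'
#' Long format, one row per subject x posture x channel, with angle
#' channels in degrees and `cop.x`/`cop.y` (and any `com.*`, `d1.*`)
#' channels in millimeters.
#'
#' @param cohort A `sesc_cohort` (or a named list of
#'   [sesc_observations()]).
#' @param path CSV file path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a named list of `sesc_observations`
#'   (angles radians, lengths meters).
#' @export
write_dataset_csv <- function(cohort, path) {
  obs_list <- if (inherits(cohort, "sesc_cohort"))
    stats::setNames(lapply(cohort$subjects, `[[`, "observations"),
                    vapply(cohort$subjects, `[[`, character(1), "id"))
  else cohort
  rows <- list()
  for (sid in names(obs_list)) {
    o <- obs_list[[sid]]
    k <- nrow(o$postures)
    wide <- cbind(o$postures * 180 / pi,
                  `cop.x` = o$cop[, 1L] * 1000, `cop.y` = o$cop[, 2L] * 1000)
    if (!is.null(o$com)) {
      com <- o$com * 1000
      colnames(com) <- paste0("com.", c("x", "y", "z"))
      wide <- cbind(wide, com)
    }
    d1 <- o$d1 * 1000
    colnames(d1) <- paste0("d1.", c("x", "y", "z"))
    wide <- cbind(wide, d1)
    rows[[sid]] <- data.frame(
      subject_id = sid,
      posture_id = rep(seq_len(k), times = ncol(wide)),
      channel = rep(colnames(wide), each = k),
      value = as.numeric(wide))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "posture_id", "channel", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("dataset schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  out <- lapply(split(df, df$subject_id), function(d) {
    wide <- stats::reshape(d[, c("posture_id", "channel", "value")],
                           idvar = "posture_id", timevar = "channel",
                           direction = "wide")
    wide <- wide[order(wide$posture_id), , drop = FALSE]
    names(wide) <- sub("^value\\.", "", names(wide))
    ch <- setdiff(names(wide), "posture_id")
    if (!all(c("cop.x", "cop.y") %in% ch))
      stop("dataset schema error: missing CoP channel(s)")
    ang_ch <- ch[!grepl("^(cop|com|d1)\\.", ch)]
    ang <- as.matrix(wide[, ang_ch, drop = FALSE]) * pi / 180
    cop <- as.matrix(wide[, c("cop.x", "cop.y")]) / 1000
    com <- if (all(paste0("com.", c("x", "y", "z")) %in% ch))
      as.matrix(wide[, paste0("com.", c("x", "y", "z"))]) / 1000
    d1 <- if (all(paste0("d1.", c("x", "y", "z")) %in% ch))
      as.matrix(wide[, paste0("d1.", c("x", "y", "z"))]) / 1000
    else c(0, 0, 0)
    sesc_observations(ang, cop = cop, com = com, d1 = d1)
  })
  out
}

#' Write an identified SESC vector as CSV
#'
#' @param fit A [sesc_fit()] object (or a named SESC vector in m).
#' @param path CSV file path; columns `joint`, `component`, `value_mm`.
#' @return `path`, invisibly.
#' @export
write_sesc_vector_csv <- function(fit, path) {
  V <- if (inherits(fit, "sesc")) fit$V else fit
  df <- data.frame(joint = sub("\\.[xyz]$", "", names(V)),
                   component = sub("^.*\\.", "", names(V)),
                   value_mm = unname(V) * 1000)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Emits the cohort dataset CSV and a manifest JSON (seeds, per-subject
#' total mass and true SESC vectors per preset). Rerunning with the same
#' configuration and seed reproduces the files exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_subjects,postures_per_subject,truth_model_id,noise,seed Passed
#'   to [simulate_cohort()].
#' @return Invisibly, a list with the cohort and the written paths.
#' @export
sesc_simulate <- function(out_dir, n_subjects = 18,
                          postures_per_subject = 98, truth_model_id = "d",
                          noise = noise_spec(), seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n_subjects, postures_per_subject,
                            truth_model_id, noise, seed)
  data_path <- file.path(out_dir, "dataset.csv")
  write_dataset_csv(cohort, data_path)
  manifest <- list(
    seed = seed, n_subjects = n_subjects,
    postures_per_subject = postures_per_subject,
    truth_model_id = truth_model_id,
    cop_noise_sd_mm = noise$cop_noise_sd_mm,
    angle_noise_sd_deg = noise$angle_noise_sd_deg,
    subjects = lapply(cohort$subjects, function(s) list(
      id = s$id, total_mass_kg = s$subject$total_mass,
      true_V_mm = lapply(stats::setNames(nm = c("a", "b", "c", "d")),
        function(m) as.list(round(
          1000 * sesc_true_vector(build_preset(m, s$subject), s$subject),
          6)))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, dataset = data_path,
                 manifest = manifest_path))
}

#' Run the full identification and evaluation pipeline
#'
#' For each subject and each requested preset: split the postures,
#' identify the SESC vector from the identification set (2D CoP), estimate
#' the CoM on the held-out set, and score the estimates against the
#' held-out CoP along the AP and ML axes. Postures recorded under a richer
#' truth model are projected onto each fitted model with
#' [project_posture()].
#'
#' @param cohort A `sesc_cohort`, or a named list of [sesc_observations()]
#'   (as from [read_dataset_csv()]) together with `truth_model`.
#' @param config A [sesc_config()].
#' @param truth_model Model describing the recorded angle channels when
#'   `cohort` is a plain observation list; inferred for a `sesc_cohort`.
#' @return List of class `sesc_report`: `comparison` (from
#'   [compare_models()]), `fits` (per subject x model), `config`
#'   provenance, and per-model `results` data frames.
#' @export
sesc_pipeline <- function(cohort, config = sesc_config(),
                          truth_model = NULL) {
  if (inherits(cohort, "sesc_cohort")) {
    obs_list <- stats::setNames(
      lapply(cohort$subjects, `[[`, "observations"),
      vapply(cohort$subjects, `[[`, character(1), "id"))
    truth_models <- stats::setNames(
      lapply(cohort$subjects, `[[`, "truth_model"), names(obs_list))
  } else {
    if (is.null(truth_model))
      stop("'truth_model' is required for a plain observation list")
    obs_list <- cohort
    truth_models <- stats::setNames(
      rep(list(truth_model), length(obs_list)), names(obs_list))
  }
  results <- stats::setNames(
    vector("list", length(config$models)), config$models)
  fits <- list()
  for (sid in names(obs_list)) {
    obs <- obs_list[[sid]]
    tm <- truth_models[[sid]]
    split <- split_postures(nrow(obs$postures),
                            train_fraction = config$train_fraction,
                            seed = config$seed)
    for (mid in config$models) {
      model <- build_preset(mid)
      proj <- project_posture(obs$postures, tm, model)
      pobs <- sesc_observations(proj, cop = obs$cop, com = obs$com,
                                d1 = obs$d1, model = model)
      fit <- withCallingHandlers(
        sesc_fit(subset_observations(pobs, split$train), model),
        sesc_rank_warning = function(w) invokeRestart("muffleWarning"))
      fits[[paste(sid, mid, sep = "/")]] <- fit
      test <- subset_observations(pobs, split$test)
      est <- predict(fit, test)
      for (ax in 1:2) {
        results[[mid]][[length(results[[mid]]) + 1L]] <- data.frame(
          subject = sid, posture = split$test,
          axis = c("AP", "ML")[ax],
          estimate = est[, ax] * 1000,
          reference = test$cop[, ax] * 1000,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- lapply(results, function(r) do.call(rbind, r))
  comparison <- if (length(results) >= 2L) compare_models(results)
  structure(list(comparison = comparison, results = results, fits = fits,
                 config = unclass(config)),
            class = "sesc_report")
}

#' @export
print.sesc_report <- function(x, ...) {
  cat("SESC pipeline report\n")
  cat(sprintf("  models: %s; train fraction %.2f; seed %s\n",
              paste(x$config$models, collapse = ", "),
              x$config$train_fraction, x$config$seed))
  if (!is.null(x$comparison)) {
    tab <- x$comparison$table
    tab[, -(1:2)] <- round(tab[, -(1:2)], 2)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Mirrors the comparison table (RMS statistics, correlations,
#' Bland-Altman bias / limits of agreement / proportional-bias regression)
#' plus a provenance block with every defaulted parameter.
#'
#' @param report A [sesc_pipeline()] report.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    provenance = report$config,
    comparison = report$comparison$table,
    per_subject_rms = report$comparison$per_subject_rms,
    pairwise_rms_differences = report$comparison$pairwise
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
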