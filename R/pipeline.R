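# End-to-end pipeline: simulate (or ingest) -> extract -> cluster ->
# correlate -> assess, with a provenance manifest so that a fixed config
# and seed reproduce byte-identical outputs.

#' Default pipeline configuration
#'
#' A flat list with one section per stage; [run_pipeline()] merges a user
#' config over these defaults. `cohort$input_dir = NULL` means simulate;
#' point it at a directory of session files + `scales.csv` to ingest
#' recorded data instead.
#'
#' @return Named list of stage configurations.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cohort = list(input_dir = NULL, n_subjects = 20L,
                  timepoints = c("pre", "post"),
                  gravity_fraction = 1 / 9, range_mode = c(0.30, 0.50),
                  target_catches = 10L, arm_length_m = 0.6,
                  affected_side = "right",
                  theta_means = c(0.10, 0.50, 0.90), theta_sd = 0.04,
                  retention_shape = c(8, 2)),
    indicators = list(catch_radius_m = 0.12, axis_band_m = 0.12,
                      stabilization_speed_mps = 0.05,
                      stabilization_dwell_s = 0.1,
                      smoothing_window_frames = 5L),
    cluster = list(k_candidates = 2:6, normalize = FALSE),
    assess = list(model_kind = "mlp", hidden_neurons = 2L, folds = 5L,
                  grouped = FALSE)
  )
}

merge_config <- function(user, defaults = default_config()) {
  if (is.null(user)) return(defaults)
  out <- defaults
  for (nm in names(user)) {
    out[[nm]] <- if (is.list(user[[nm]]) && is.list(defaults[[nm]])) {
      utils::modifyList(defaults[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  out
}

write_json_det <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

write_lines_bin <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n")
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full assessment pipeline
#'
#' Executes simulate (or ingest) -> extract -> cluster -> correlate ->
#' assess into a run directory, and writes a `manifest.json` recording
#' the seed, the canonical config and its hash, and an MD5 checksum per
#' output file; an identical config and seed reproduce identical
#' checksums. A stage failure aborts with the failing stage named;
#' outputs of completed stages are retained.
#'
#' @param config `NULL` (defaults), a list, or a path to a YAML file;
#'   merged over [default_config()].
#' @param out_dir Run directory (created).
#' @param seed Optional integer overriding `config$seed`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = "vrmotor_run",
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  write_json_det(cfg, cfg_path)
  outputs <- character(0)

  # simulate or ingest
  cc <- cfg$cohort
  if (is.null(cc$input_dir)) {
    cohort <- run_stage("simulate", {
      spec <- cohort_spec(
        n_subjects = cc$n_subjects, timepoints = cc$timepoints,
        settings = task_settings(
          gravity_fraction = cc$gravity_fraction,
          range_mode = cc$range_mode,
          target_catches = cc$target_catches,
          arm_length_m = cc$arm_length_m,
          affected_side = cc$affected_side),
        theta_means = cc$theta_means, theta_sd = cc$theta_sd,
        retention_shape = cc$retention_shape, seed = cfg$seed)
      co <- simulate_cohort(spec)
      outputs <- c(outputs, write_cohort(co, file.path(out_dir,
                                                       "sessions")))
      co
    })
    sessions <- cohort$sessions
    scales <- cohort$scales
  } else {
    run_stage("ingest", {
      stems <- sub("\\.csv$", "",
                   list.files(cc$input_dir, pattern = "\\.csv$",
                              full.names = TRUE))
      stems <- setdiff(stems, file.path(cc$input_dir,
                                        c("scales", "truth")))
      sessions <- lapply(sort(stems), read_session)
      scales <- read_scales(file.path(cc$input_dir, "scales.csv"))
    })
  }

  # extract
  icfg <- do.call(indicator_config, cfg$indicators)
  ind <- run_stage("extract", extract_cohort_indicators(sessions, icfg))
  ind_path <- file.path(out_dir, "indicators.csv")
  write_indicators(ind, ind_path)
  diag <- lapply(seq_len(nrow(ind)), function(i) {
    row <- ind[i, ]
    miss <- indicator_names()[is.na(as.numeric(row[, indicator_names()]))]
    list(subject = row$subject, timepoint = row$timepoint,
         n_attempts_used = row$n_attempts_used, missing = miss)
  })
  diag_path <- write_json_det(diag, file.path(out_dir,
                                              "diagnostics.json"))

  # cluster
  model <- run_stage("cluster", cluster_scales(
    scales, k_candidates = cfg$cluster$k_candidates,
    seed = cfg$seed, normalize = isTRUE(cfg$cluster$normalize)))
  labels <- assign_levels(model)
  lab_path <- write_lines_bin(
    c("subject,timepoint,level",
      sprintf("%s,%s,%d", labels$subject, labels$timepoint,
              labels$level)),
    file.path(out_dir, "labels.csv"))
  model_path <- write_json_det(
    list(k = model$k, seed = model$seed, normalize = model$normalize,
         mean_silhouette = model$mean_silhouette, wcss = model$wcss,
         centroids = model$centroids,
         silhouette_by_k = model$silhouette_by_k,
         sizes = as.list(attr(labels, "sizes"))),
    file.path(out_dir, "cluster_model.json"))

  # correlate
  targets <- left_join(scales, labels, by = c("subject", "timepoint"))
  corr <- run_stage("correlate",
                    suppressWarnings(spearman_matrix(ind, targets)))
  corr_path <- file.path(out_dir, "correlations.csv")
  correlation_report(corr, corr_path)

  # assess
  ac <- cfg$assess
  report <- run_stage("assess", {
    lab <- labels$level[match(paste(ind$subject, ind$timepoint),
                              paste(labels$subject, labels$timepoint))]
    evaluate_assessment(ind, lab, model_spec(
      ac$model_kind, hidden_neurons = ac$hidden_neurons,
      folds = ac$folds, grouped = isTRUE(ac$grouped), seed = cfg$seed))
  })
  assess_path <- write_json_det(
    c(as.list(glance(report)),
      list(per_class_accuracy = as.list(report$per_class_accuracy),
           seed = cfg$seed)),
    file.path(out_dir, "assessment.json"))
  conf <- as.matrix(report$confusion)
  conf_path <- write_lines_bin(
    c(paste(c("actual", paste0("pred_", colnames(conf))), collapse = ","),
      vapply(seq_len(nrow(conf)), function(i) {
        paste(c(rownames(conf)[i], conf[i, ]), collapse = ",")
      }, character(1))),
    file.path(out_dir, "confusion.csv"))

  outputs <- c(outputs, ind_path, diag_path, lab_path, model_path,
               corr_path, assess_path, conf_path)
  rel <- sub(paste0("^", out_dir, "/?"), "", outputs)
  sums <- unname(tools::md5sum(outputs))
  manifest <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    config = cfg,
    outputs = lapply(order(rel), function(i) {
      list(file = rel[i], md5 = sums[i])
    })
  )
  write_json_det(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
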