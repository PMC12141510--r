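#' Default configuration for the end-to-end analysis
#'
#' Bundles the simulation, preprocessing, modelling and LoD settings
#' used by [run_full_analysis()]. The calibration design is the
#' spiked-standard ladder (0-2 mM in 0.1 mM steps, 3 preparations per
#' level); the default panel emulates oils of differing carotene
#' content measured in triplicate.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param sim [sim_config()] shared by calibration and panel.
#' @param calibration List: conc_start, conc_end, conc_step, replicates.
#' @param profiles List of [origin_profile()]s for the panel.
#' @param max_lv Latent-variable cap for model selection.
#' @param lod_range Length-2 concentration window (mM) for the LoD
#'   sub-model.
#' @param nmr Optional data frame of NMR integrals (columns
#'   `sample_id`, `I_olefinic`, `I_bis_allylic`, `I_ch3`), or NULL to
#'   skip the NMR stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       sim = sim_config(),
                       calibration = list(conc_start = 0, conc_end = 2,
                                          conc_step = 0.1, replicates = 3),
                       profiles = list(
                         origin_profile("origin_A", 0.2, 0.05, n_samples = 5),
                         origin_profile("origin_B", 0.8, 0.10, n_samples = 5),
                         origin_profile("origin_C", 1.5, 0.15, n_samples = 5)),
                       max_lv = 10,
                       lod_range = c(0.1, 0.5),
                       nmr = NULL) {
  structure(list(seed = seed, sim = sim, calibration = calibration,
                 profiles = profiles, max_lv = max_lv,
                 lod_range = lod_range, nmr = nmr),
            class = "run_config")
}

config_to_json <- function(config, path) {
  ser <- list(seed = config$seed,
              sim = unclass(config$sim),
              calibration = config$calibration,
              profiles = lapply(config$profiles, unclass),
              max_lv = config$max_lv,
              lod_range = config$lod_range,
              has_nmr = !is.null(config$nmr))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Serialize a PLS model to JSON
#' @param model A `plsr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plsr_model <- function(model, path) {
  jsonlite::write_json(list(
    n_lv = model$n_lv, x_mean = model$x_mean, y_mean = model$y_mean,
    weights = model$W, x_loadings = model$P, y_loadings = model$q,
    coefficients = model$b, metrics = model$metrics
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the complete analysis on simulated data
#'
#' Chains the full study: simulate the spiked-standard calibration and a
#' multi-origin oil panel; preprocess (PCA path for discrimination, PLS
#' path for quantification); fit PCA on the panel; calibrate the PLS
#' model with grouped leave-one-preparation-out CV and score an
#' independent simulated test design for RMSEP; predict panel carotene
#' levels with effectively-zero flags; compute the restricted-range LoD;
#' rank the oils against PC-1; and, when integrals are supplied,
#' estimate NMR fatty-acid compositions. All outputs are CSV/JSON in
#' `out_dir`, alongside the serialized configuration and a run log.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory results (`calibration`,
#'   `model`, `pca`, `predictions`, `lod`, `ranking`, `nmr`).
#' @export
run_full_analysis <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("FAILED at stage '%s': %s", name, conditionMessage(e))
      writeLines(log_lines, logf)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  config_to_json(config, file.path(out_dir, "config.json"))
  note("seed: %d", config$seed)
  note("config md5: %s",
       unname(tools::md5sum(file.path(out_dir, "config.json"))))

  cal_cfg <- config$sim; cal_cfg$seed <- config$seed
  cal <- stage("simulate_calibration", do.call(simulate_calibration_set,
    c(config$calibration, list(config = cal_cfg))))
  test_cfg <- config$sim; test_cfg$seed <- config$seed + 1L
  cal_test <- stage("simulate_test", do.call(simulate_calibration_set,
    c(config$calibration, list(config = test_cfg))))
  panel_cfg <- config$sim; panel_cfg$seed <- config$seed + 2L
  panel <- stage("simulate_panel",
                 simulate_origin_panel(config$profiles, panel_cfg))
  write_spectra(cal, file.path(out_dir, "calibration_raw.csv"))
  write_spectra(panel, file.path(out_dir, "panel_raw.csv"))
  note("simulated %d calibration + %d test + %d panel spectra",
       n_spectra(cal), n_spectra(cal_test), n_spectra(panel))

  cal_pls <- stage("preprocess", preprocess_set(cal, "plsr_path"))
  test_pls <- stage("preprocess", preprocess_set(cal_test, "plsr_path"))
  panel_pls <- stage("preprocess", preprocess_set(panel, "plsr_path"))
  panel_pca <- stage("preprocess", preprocess_set(panel, "pca_path"))
  write_spectra(panel_pca, file.path(out_dir, "panel_preprocessed.csv"))

  pca <- stage("pca", fit_pca(panel_pca, n_components = 2))
  utils::write.csv(data.frame(spectrum_id = panel_pca$metadata$spectrum_id,
                              panel_pca$metadata[setdiff(names(panel_pca$metadata),
                                                         "spectrum_id")],
                              pc1 = pca$scores[, 1], pc2 = pca$scores[, 2]),
                   file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(wavenumber = pca$axis,
                              pc1 = pca$loadings[1, ],
                              pc2 = pca$loadings[2, ]),
                   file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
  note("PC-1 explains %.2f%% of variance",
       100 * pca$explained_variance_fraction[1])

  model <- stage("calibrate", calibration_metrics(
    spectra_matrix(cal_pls), cal_pls$metadata$true_conc_mM,
    X_test = spectra_matrix(test_pls),
    y_test = test_pls$metadata$true_conc_mM,
    groups = cal_pls$metadata$sample_id, max_lv = config$max_lv,
    train_ids = paste0("train_", cal_pls$metadata$sample_id),
    test_ids = paste0("test_", test_pls$metadata$sample_id)))
  write_plsr_model(model, file.path(out_dir, "plsr_model.json"))
  note("PLS-R: %d LV, R2 %.4f, Q2 %.4f, RMSECV %.4f mM, RMSEP %.4f mM",
       model$metrics$n_lv, model$metrics$r2, model$metrics$q2,
       model$metrics$rmsecv, model$metrics$rmsep)

  preds <- stage("predict",
                 predict(model, spectra_matrix(panel_pls), flag = TRUE))
  preds <- cbind(panel_pls$metadata[c("spectrum_id", "sample_id", "origin",
                                      "true_conc_mM")], preds)
  utils::write.csv(preds, file.path(out_dir, "panel_predictions.csv"),
                   row.names = FALSE)

  lod <- stage("lod", compute_lod(cal_pls, conc_min = config$lod_range[1],
                                  conc_max = config$lod_range[2],
                                  max_lv = config$max_lv))
  jsonlite::write_json(list(lod_mM = lod$lod, slope = lod$slope,
                            residual_sd_mM = lod$residual_sd,
                            n_used = lod$n_used,
                            conc_range_mM = config$lod_range),
                       file.path(out_dir, "lod.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("LoD %.4f mM on %.1f-%.1f mM sub-range", lod$lod,
       config$lod_range[1], config$lod_range[2])

  ranking <- stage("rank", rank_by_carotene(panel_pls$metadata$sample_id,
                                            preds$predicted_mM,
                                            pca$scores[, 1]))
  rk <- ranking
  rk$spearman_rho_vs_pc1 <- attr(ranking, "spearman_rho")
  utils::write.csv(rk, file.path(out_dir, "ranking.csv"), row.names = FALSE)
  note("Spearman rho (predicted carotene vs PC-1): %.4f",
       attr(ranking, "spearman_rho"))

  nmr <- NULL
  if (!is.null(config$nmr)) {
    nmr <- stage("nmr", batch_compositions(config$nmr))
    utils::write.csv(nmr, file.path(out_dir, "nmr_compositions.csv"),
                     row.names = FALSE)
    note("NMR compositions for %d samples", nrow(nmr))
  } else {
    note("NMR stage skipped: no integrals supplied")
  }

  writeLines(log_lines, logf)
  invisible(list(calibration = cal, model = model, pca = pca,
                 predictions = preds, lod = lod, ranking = ranking,
                 nmr = nmr))
}
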