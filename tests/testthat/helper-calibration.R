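# The spiked-standard calibration fitted under the study conditions
# (21 levels 0-2 mM in 0.1 mM steps, 3 preparations per level, 1% noise)
# is used by several tests; fit it once per session and cache it.
.cal_cache <- new.env(parent = emptyenv())

calibration_study_model <- function() {
  if (!is.null(.cal_cache$model)) return(.cal_cache$model)
  train <- preprocess_set(
    simulate_calibration_set(0, 2, 0.1, 3, sim_config(seed = 1)),
    "plsr_path")
  test <- preprocess_set(
    simulate_calibration_set(0, 2, 0.1, 3, sim_config(seed = 2)),
    "plsr_path")
  model <- calibration_metrics(
    spectra_matrix(train), train$metadata$true_conc_mM,
    X_test = spectra_matrix(test), y_test = test$metadata$true_conc_mM,
    groups = train$metadata$sample_id,
    train_ids = paste0("train_", train$metadata$sample_id),
    test_ids = paste0("test_", test$metadata$sample_id))
  .cal_cache$model <- model
  model
}
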