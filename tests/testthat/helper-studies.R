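# Segmentation-recovery study at CPU scale: tiny preset, 20 easy canal
# phantoms (32^3 crops, contrast gap 0.4, noise sd 0.05), 30 epochs.
# Trained models are cached so multiple test blocks can share one run.

.study_cache <- new.env(parent = emptyenv())

study_cohort <- function(seed) {
  key <- sprintf("cohort_seed%d", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- list(
      train_set = make_test_pairs(seed * 1000 + 1:20),
      heldout = make_test_pairs(seed * 1000 + 901:905))
  .study_cache[[key]]
}

recovery_study <- function(lambda, seed) {
  key <- sprintf("lambda%s_seed%d", format(lambda), seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cohort <- study_cohort(seed)
  train_set <- cohort$train_set
  heldout <- cohort$heldout
  model <- build_model(model_config("tiny"), seed = seed)
  run <- train(model, train_set, train_config("tiny", seed = seed),
               loss_config(lambda = lambda))
  reports <- lapply(heldout, function(p) {
    pred <- sliding_window_infer(run$model, p$volume, infer_config(32L, 16L))
    evaluate(pred, p$label)
  })
  res <- list(model = run$model, log = run$log, reports = reports)
  .study_cache[[key]] <- res
  res
}

report_stat <- function(reports, field) {
  vapply(reports, function(r) {
    v <- r[[field]]
    if (is.na(v)) 0 else v
  }, numeric(1))
}
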