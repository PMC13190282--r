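# The desk-scale study: a 32^3 phantom cohort of ~200 subjects with a 9:1
# subject-level split, segmentation pretraining and the multitask phase.
# Built once (several minutes) and shared by the acceptance suite and the
# module tests that need a trained model.
trained_study <- function() memo("trained_study", {
  cohort <- generate_cohort(phantom_config(grid_size = 32, n_subjects = 200,
                                           seed = 101))
  dataset <- assemble_imaging_dataset(cohort)
  plan <- make_splits(cohort$records, n_folds = 9, test_frac = 0.1, seed = 42)
  model <- build_unet(unet_config(input_size = 32,
                                  n_tabular = ncol(dataset$tabular)),
                      seed = 1)
  ids <- split_ids(plan, 1)
  tr_rows <- match(c(ids$train, ids$validation), dataset$subject_id)
  pre <- pretrain_segmentation(model, dataset$volumes[tr_rows],
                               dataset$labels[tr_rows],
                               train_config(seed = 1))
  fit <- train_multitask(pre$model, dataset, plan, fold = 1,
                         train_config(seed = 1))
  test_rows <- match(ids$test, dataset$subject_id)
  tab_std <- voxcog:::.tab_standardize(dataset$tabular,
                                       stats = fit$tab_stats)$X
  test_preds <- predict_subjects(fit$model, dataset, test_rows, tab_std)
  test_metrics <- evaluate_predictions(test_preds, dataset, test_rows)
  list(cohort = cohort, dataset = dataset, plan = plan, fit = fit,
       test_rows = test_rows, tab_std = tab_std, test_preds = test_preds,
       test_metrics = test_metrics)
})
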