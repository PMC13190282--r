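test_that("intensity normalisation is standard, affine-invariant, idempotent", {
  v <- array(rnorm(8^3, 5, 3), dim = rep(8, 3))
  n1 <- normalize_volume(v)
  expect_equal(mean(n1), 0, tolerance = 1e-10)
  expect_equal(sd(n1), 1, tolerance = 1e-10)
  expect_equal(normalize_volume(2.5 * v - 7), n1, tolerance = 1e-9)
  expect_equal(normalize_volume(n1), n1, tolerance = 1e-9)
  expect_error(normalize_volume(array(1, rep(4, 3))), "constant")
  vv <- normalize_volume(volume3d(v, voxel_size = c(1, 1, 1.2)))
  expect_s3_class(vv, "volume3d")
  expect_equal(vv$voxel_size, c(1, 1, 1.2))
})

test_that("elastic augmentation is identity at zero magnitude and label-closed", {
  co <- cohort16()
  vol <- co$volumes[[1]]$values
  lab <- co$labels[[1]]
  a0 <- elastic_augment(vol, lab, smooth_sd = 4, magnitude = 0)
  expect_identical(a0$volume, vol)
  expect_identical(a0$labels, lab)
  set.seed(14)
  a <- elastic_augment(vol, lab, smooth_sd = 4, magnitude = 2)
  expect_true(all(unique(as.integer(a$labels)) %in% unique(as.integer(lab))))
  expect_false(identical(a$volume, vol))
  expect_error(elastic_augment(vol, lab, smooth_sd = -1), ">= 0")
})

test_that("elastic warps roughly preserve brain volume", {
  co <- generate_cohort(phantom_config(grid_size = 32, n_subjects = 1,
                                       seed = 19))
  lab <- co$labels[[1]]
  vol <- co$volumes[[1]]$values
  n_brain <- sum(lab > 0)
  set.seed(15)
  counts <- replicate(50, {
    a <- elastic_augment(vol, lab, smooth_sd = 4, magnitude = 2)
    sum(a$labels > 0)
  })
  expect_true(all(abs(counts - n_brain) / n_brain < 0.10))
})

test_that("evaluation primitives match definitions and an external oracle", {
  obs <- c(1, 4, 7, 10)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 4), obs), 0)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  set.seed(16)
  scores <- runif(60)
  labels <- rbinom(60, 1, plogis(3 * (scores - 0.5)))
  if (length(unique(labels)) == 2) {
    oracle <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
    expect_equal(roc_auc(scores, labels), oracle, tolerance = 1e-10)
  }
  expect_true(is.na(roc_auc(scores, rep(1, 60))))
  cc <- confusion_counts(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(sum(cc), 4)
  expect_equal(unname(cc["tp"]), 1)
  expect_equal(unname(cc["fp"]), 1)
})

test_that("perfect predictions score perfectly across the report", {
  co <- cohort16()
  ds <- assemble_imaging_dataset(co)
  rows <- 1:6
  preds <- data.frame(subject_id = ds$subject_id[rows],
                      cognition = ds$targets$cog[rows],
                      alpha = ds$targets$alpha[rows],
                      diag_prob = ds$targets$diag[rows])
  attr(preds, "seg") <- lapply(rows, function(i)
    voxcog:::as_prob4(ds$labels[[i]]))
  m <- evaluate_predictions(preds, ds, rows)
  expect_equal(m$dice_weighted, 1)
  expect_equal(m$cog_r2, 1)
  expect_equal(m$cog_mae, 0)
  expect_equal(m$alpha_r2, 1)
  expect_equal(m$diag_accuracy, 1)
})

test_that("segmentation pretraining reduces the loss and checkpoints exactly", {
  co <- cohort16()
  model <- build_unet(unet_config(input_size = 16, depth = 2), seed = 2)
  rows <- 1:8
  fit <- pretrain_segmentation(model, co$volumes[rows], co$labels[rows],
                               train_config(epochs = 3, seed = 4))
  expect_lt(tail(fit$history$seg_loss, 1), fit$history$seg_loss[1])
  p <- file.path(withr::local_tempdir(), "seg.rds")
  save_model(fit$model, p)
  vol <- voxcog:::.norm_arr(co$volumes[[9]])
  expect_identical(unet_forward(load_model(p), vol)$seg_probs,
                   unet_forward(fit$model, vol)$seg_probs)
})

test_that("adding young controls to pretraining does not hurt disease Dice", {
  dis <- generate_cohort(phantom_config(grid_size = 16, n_subjects = 22,
                                        seed = 41))
  yo <- generate_cohort(phantom_config(grid_size = 16, n_subjects = 14,
                                       seed = 42, young_control = TRUE))
  train <- 1:16
  held <- 17:22
  cfg <- unet_config(input_size = 16, depth = 2)
  tc <- train_config(epochs = 2, seed = 5)
  f1 <- pretrain_segmentation(build_unet(cfg, 3), dis$volumes[train],
                              dis$labels[train], tc)
  f2 <- pretrain_segmentation(build_unet(cfg, 3),
                              c(dis$volumes[train], yo$volumes),
                              c(dis$labels[train], yo$labels), tc)
  dice_of <- function(m) mean(vapply(held, function(i)
    weighted_dice(unet_forward(m, voxcog:::.norm_arr(dis$volumes[[i]]))$seg_probs,
                  dis$labels[[i]]), numeric(1)))
  expect_gte(dice_of(f2$model), dice_of(f1$model) - 0.02)
})

test_that("multitask training is reproducible and leak-guarded", {
  co <- cohort16()
  ds <- assemble_imaging_dataset(co)
  plan <- make_splits(co$records, n_folds = 4, test_frac = 0.1, seed = 2)
  model <- build_unet(unet_config(input_size = 16, depth = 2,
                                  n_tabular = ncol(ds$tabular)), seed = 6)
  tc <- train_config(epochs = 1, finetune_epochs = 1, warmup_iters = 60,
                     warmup_min = 0, seed = 7)
  f1 <- train_multitask(model, ds, plan, fold = 1, tc)
  f2 <- train_multitask(model, ds, plan, fold = 1, tc)
  expect_identical(f1$train_ids, f2$train_ids)
  expect_equal(f1$metrics$cog_r2, f2$metrics$cog_r2)
  expect_true(all(f1$gamma_params$subject_ids %in% split_ids(plan, 1)$train))
  # corrupted plan with a duplicated subject is rejected
  bad <- plan
  bad$subject_id[2] <- bad$subject_id[1]
  expect_error(train_multitask(model, ds, bad, 1, tc), "leakage|once|partition")
})

test_that("fold metrics aggregate as mean and sd", {
  reps <- list(list(dice_weighted = 0.9, cog_r2 = 0.5, cog_mae = 3,
                    cog_pearson = 0.7, alpha_r2 = 0.2, diag_accuracy = 0.8,
                    diag_auc = 0.9),
               list(dice_weighted = 0.8, cog_r2 = 0.7, cog_mae = 2,
                    cog_pearson = 0.9, alpha_r2 = 0.4, diag_accuracy = 0.9,
                    diag_auc = 0.8))
  s <- summarize_folds(reps)
  expect_equal(s$mean[s$metric == "dice_weighted"], 0.85)
  expect_equal(s$sd[s$metric == "cog_r2"], sd(c(0.5, 0.7)))
})
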