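#' Run configuration
#'
#' A single hierarchical config (YAML on disk) drives the pipeline commands.
#' Sections: `paths` (cohort_dir, young_dir, out_dir), `phantom`, `model`,
#' `train`, `split`, `interpret`, plus a global `seed` recorded in every
#' output together with a hash of the config itself.
#'
#' @param path YAML file path, or NULL for defaults.
#' @param overrides named list of dotted keys (e.g. `phantom.n_subjects`)
#'   applied on top.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 42,
    paths = list(cohort_dir = "cohort", young_dir = NULL, out_dir = "out"),
    phantom = list(grid_size = 32, n_subjects = 100, severity_scale = 5,
                   noise_sd_intensity = 0.05, adas_meas_sd = 2,
                   hotspot_fraction = 0.15, n_young = 0),
    model = list(input_size = 32, n_tabular = 7),
    train = list(epochs = 2, finetune_epochs = 2, warmup_iters = 150,
                 lr = 1e-3, augment_magnitude = 1),
    split = list(n_folds = 9, test_frac = 0.1, fold = 1),
    interpret = list(patch = 5, stride = 5, n_occlusion_subjects = 5))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cfg <- modify_nested(cfg, parts, overrides[[key]])
  }
  structure(cfg, class = "run_config")
}

modify_nested <- function(x, parts, value) {
  if (length(parts) == 1) {
    x[[parts]] <- value
    return(x)
  }
  x[[parts[1]]] <- modify_nested(x[[parts[1]]] %||% list(), parts[-1], value)
  x
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

.stamp <- function(cfg) list(seed = cfg$seed, config_hash = config_hash(cfg))

#' Pipeline commands
#'
#' Thin command functions wiring the package end-to-end; each is idempotent
#' given the same config and seed, writes its artifacts under
#' `paths$out_dir` (or the cohort directory for `cmd_simulate`), and stamps
#' outputs with the seed and a config hash. A missing upstream artifact
#' raises an error naming the producing command. An executable wrapper is
#' installed at `system.file("cli", "voxcog", package = "voxcog")`.
#'
#' @param cfg a [read_run_config] configuration.
#' @return the main artifact path(s), invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(cfg) {
  ph <- cfg$phantom
  cohort <- generate_cohort(phantom_config(
    grid_size = ph$grid_size, n_subjects = ph$n_subjects, seed = cfg$seed,
    severity_scale = ph$severity_scale,
    noise_sd_intensity = ph$noise_sd_intensity,
    adas_meas_sd = ph$adas_meas_sd, hotspot_fraction = ph$hotspot_fraction))
  write_cohort(cohort, cfg$paths$cohort_dir)
  if ((ph$n_young %||% 0) > 0) {
    young <- generate_cohort(phantom_config(
      grid_size = ph$grid_size, n_subjects = ph$n_young,
      seed = cfg$seed + 1L, young_control = TRUE))
    write_cohort(young, cfg$paths$young_dir %||%
                   file.path(cfg$paths$cohort_dir, "young"))
  }
  invisible(cfg$paths$cohort_dir)
}

.require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact ", path, "; run `", producer, "` first")
  path
}

#' @rdname pipeline
#' @export
cmd_pretrain_seg <- function(cfg) {
  out <- cfg$paths$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  cohort <- read_cohort(.dir_of_cohort(cfg))
  vols <- cohort$volumes
  labs <- cohort$labels
  ydir <- cfg$paths$young_dir %||% file.path(cfg$paths$cohort_dir, "young")
  if (dir.exists(ydir)) {
    young <- read_cohort(ydir)
    vols <- c(vols, young$volumes)
    labs <- c(labs, young$labels)
  }
  model <- build_unet(unet_config(input_size = cfg$model$input_size,
                                  n_tabular = cfg$model$n_tabular),
                      seed = cfg$seed)
  tc <- train_config(epochs = cfg$train$epochs, seed = cfg$seed,
                     augment_magnitude = cfg$train$augment_magnitude)
  fit <- pretrain_segmentation(model, vols, labs, tc)
  ckpt <- file.path(out, "pretrained.rds")
  save_model(fit$model, ckpt)
  jsonlite::write_json(c(.stamp(cfg), list(history = fit$history)),
                       file.path(out, "pretrain_log.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(ckpt)
}

.dir_of_cohort <- function(cfg) {
  dir <- cfg$paths$cohort_dir
  .require_artifact(file.path(dir, "cohort.csv"), "cmd_simulate")
  dir
}

#' @rdname pipeline
#' @export
cmd_train <- function(cfg) {
  out <- cfg$paths$out_dir
  cohort <- read_cohort(.dir_of_cohort(cfg))
  model <- load_model(.require_artifact(file.path(out, "pretrained.rds"),
                                        "cmd_pretrain_seg"))
  dataset <- .dataset_from_cohort(cohort)
  plan <- make_splits(cohort$records, n_folds = cfg$split$n_folds,
                      test_frac = cfg$split$test_frac, seed = cfg$seed)
  tc <- train_config(epochs = cfg$train$epochs,
                     finetune_epochs = cfg$train$finetune_epochs,
                     warmup_iters = cfg$train$warmup_iters,
                     lr = cfg$train$lr, seed = cfg$seed,
                     augment_magnitude = cfg$train$augment_magnitude)
  fit <- train_multitask(model, dataset, plan, fold = cfg$split$fold,
                         config = tc)

  # tabular module with Gamma objective on demographics + true-label volumes
  vols <- t(vapply(cohort$labels, tissue_volumes, numeric(3)))
  fx <- assemble_features(cohort$records, volumes = vols)
  tr_rows <- match(fit$train_ids, dataset$subject_id)
  has <- dataset$targets$has_cog[tr_rows]
  cvt <- cv_tabular(fx$X[tr_rows[has], , drop = FALSE],
                    dataset$targets$cog[tr_rows[has]],
                    task = "cognition_gamma", seed = cfg$seed)
  tabm <- fit_tabular(fx$X[tr_rows[has], , drop = FALSE],
                      dataset$targets$cog[tr_rows[has]],
                      task = "cognition_gamma",
                      gamma_params = fit$gamma_params, seed = cfg$seed)
  weights <- compute_ensemble_weights(r2_im = max(fit$metrics$cog_r2, 0),
                                      r2_nim = max(cvt$r2, 0))
  ens <- ensemble_retrain(fit$model, tabm, weights, dataset, fx$X, tr_rows,
                          fit$gamma_params, fit$tab_stats,
                          config = train_config(finetune_epochs = 1,
                                                seed = cfg$seed))

  # separate longitudinal tabular model: demographics + volumes + z-scored
  # volumes against training-fold CN controls
  rec <- cohort$records
  tr_cn <- dataset$subject_id %in% fit$train_ids & rec$diagnosis == "CN"
  ctrl_ref <- control_reference(vols[tr_cn, , drop = FALSE],
                                subject_ids = dataset$subject_id[tr_cn])
  zx <- assemble_features(rec, volumes = vols,
                          zscores = zscore_volumes(vols, ctrl_ref))
  ha <- dataset$targets$has_alpha[tr_rows]
  alpha_tab <- NULL
  alpha_cv <- NA_real_
  if (sum(ha) >= 20) {
    alpha_tab <- fit_tabular(zx$X[tr_rows[ha], , drop = FALSE],
                             dataset$targets$alpha[tr_rows[ha]],
                             task = "alpha", seed = cfg$seed)
    alpha_cv <- cv_tabular(zx$X[tr_rows[ha], , drop = FALSE],
                           dataset$targets$alpha[tr_rows[ha]],
                           task = "alpha", seed = cfg$seed)$r2
  }
  alpha_weights <- tryCatch(
    compute_ensemble_weights(r2_im = max(fit$metrics$alpha_r2, 0),
                             r2_nim = max(alpha_cv, 0, na.rm = TRUE)),
    error = function(e) NULL)

  saveRDS(list(imaging = ens$model, tabular = ens$tab_model,
               weights = weights, gamma_params = fit$gamma_params,
               tab_stats = fit$tab_stats, plan = plan,
               alpha_tabular = alpha_tab, alpha_weights = alpha_weights,
               control_reference = ctrl_ref,
               stamp = .stamp(cfg)),
          file.path(out, "trained.rds"))
  write_split_plan(plan, file.path(out, "split_plan.json"))
  jsonlite::write_json(c(.stamp(cfg),
                         list(validation = unclass(fit$metrics)[
                           c("dice_weighted", "cog_r2", "cog_mae",
                             "alpha_r2", "diag_accuracy", "diag_auc")],
                           ensemble_weights = unclass(weights)[
                             c("r2_im", "r2_nim", "w_im", "w_nim")],
                           ensemble_log = ens$log)),
                       file.path(out, "train_metrics.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file.path(out, "trained.rds"))
}

.dataset_from_cohort <- function(cohort) {
  rec <- cohort$records
  fx <- assemble_features(rec)
  alpha_emp <- rep(NA_real_, nrow(rec))
  if (!is.null(cohort$adas_series)) {
    fits <- fit_alpha_series(cohort$adas_series)
    alpha_emp[match(fits$subject_id, rec$subject_id)] <- fits$alpha
  }
  targets <- data.frame(subject_id = rec$subject_id, cog = rec$adas0,
                        alpha = alpha_emp,
                        diag = as.integer(rec$diagnosis == "AD"),
                        has_cog = is.finite(rec$adas0),
                        has_alpha = is.finite(alpha_emp),
                        stringsAsFactors = FALSE)
  list(subject_id = rec$subject_id, volumes = cohort$volumes,
       labels = cohort$labels, tabular = fx$X, targets = targets)
}

.load_trained <- function(cfg) {
  readRDS(.require_artifact(file.path(cfg$paths$out_dir, "trained.rds"),
                            "cmd_train"))
}

#' @rdname pipeline
#' @param image_paths character vector of NIfTI paths for new subjects.
#' @param demographics data.frame (subject_id, age, sex, education, marital)
#'   aligned with `image_paths`.
#' @param months forecast horizons in months.
#' @export
cmd_predict <- function(cfg, image_paths, demographics,
                        months = c(6, 12, 24, 36)) {
  tr <- .load_trained(cfg)
  out <- cfg$paths$out_dir
  model <- tr$imaging
  fx <- assemble_features(demographics)
  tab <- .tab_standardize(fx$X, stats = tr$tab_stats)$X
  rows <- list()
  for (i in seq_along(image_paths)) {
    v <- read_volume(image_paths[i])
    arr <- as_volume_array(v)
    if (!all(dim(arr) == model$config$input_size))
      arr <- as_volume_array(resample_to_grid(v, model$config$input_size))
    fw <- unet_forward(model, .norm_arr(arr), tabular = tab[i, ],
                       need_seg = TRUE)
    seg <- prob_to_labels(fw$seg_probs)
    sid <- demographics$subject_id[i]
    write_volume(volume3d(seg + 0),
                 file.path(out, paste0(sid, "_seg.nii.gz")))
    vols <- tissue_volumes(seg)
    nim <- predict(tr$tabular, rbind(c(fx$X[i, ], vols)))
    cog <- ensemble_predict(fw$cognition, nim, tr$weights)
    alpha <- fw$alpha
    if (!is.null(tr$alpha_tabular) && !is.null(tr$alpha_weights)) {
      z <- zscore_volumes(vols, tr$control_reference)
      nim_a <- predict(tr$alpha_tabular, rbind(c(fx$X[i, ], vols, z)))
      alpha <- ensemble_predict(fw$alpha, nim_a, tr$alpha_weights)
    }
    fc <- forecast_adas(cog, alpha, months)
    rows[[i]] <- data.frame(subject_id = sid, diag_prob = fw$diag_prob,
                            cognition_imaging = fw$cognition,
                            cognition_tabular = nim,
                            cognition = cog, alpha = alpha,
                            t(setNames(fc, paste0("adas_m", months))))
  }
  bundle <- do.call(rbind, rows)
  path <- file.path(out, "predictions.csv")
  write.csv(bundle, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline
#' @export
cmd_evaluate <- function(cfg) {
  tr <- .load_trained(cfg)
  cohort <- read_cohort(.dir_of_cohort(cfg))
  dataset <- .dataset_from_cohort(cohort)
  tab <- .tab_standardize(dataset$tabular, stats = tr$tab_stats)$X
  ids <- split_ids(tr$plan, attr(tr$plan, "fold") %||% 1)
  test_rows <- match(ids$test, dataset$subject_id)
  preds <- predict_subjects(tr$imaging, dataset, test_rows, tab)
  metrics <- evaluate_predictions(preds, dataset, test_rows)
  path <- file.path(cfg$paths$out_dir, "test_metrics.json")
  jsonlite::write_json(c(.stamp(cfg), lapply(unclass(metrics), unname)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline
#' @export
cmd_explain <- function(cfg) {
  tr <- .load_trained(cfg)
  cohort <- read_cohort(.dir_of_cohort(cfg))
  dataset <- .dataset_from_cohort(cohort)
  out <- cfg$paths$out_dir
  tab <- .tab_standardize(dataset$tabular, stats = tr$tab_stats)$X
  ad <- which(cohort$records$diagnosis == "AD")
  ad <- head(ad, cfg$interpret$n_occlusion_subjects)
  if (length(ad) == 0) stop("no AD subjects to explain")
  maps <- lapply(ad, function(i) {
    vol <- .norm_arr(dataset$volumes[[i]])
    # counterfactual fill: mean intensity of the tissue the model itself
    # segments as GM, probing "what if this region looked intact"
    seg <- prob_to_labels(unet_forward(tr$imaging, vol,
                                       tabular = tab[i, ])$seg_probs)
    fill <- if (any(seg == 1L)) mean(vol[seg == 1L]) else 0
    occlusion_map(tr$imaging, vol, target = dataset$targets$cog[i],
                  tabular = tab[i, ], patch = cfg$interpret$patch,
                  stride = cfg$interpret$stride, fill = fill)
  })
  agg <- aggregate_occlusion(maps)
  write_volume(volume3d(agg$mean_map), file.path(out, "occlusion_mean.nii.gz"))

  vols <- t(vapply(cohort$labels, tissue_volumes, numeric(3)))
  fx <- assemble_features(cohort$records, volumes = vols)
  has <- dataset$targets$has_cog
  imp <- permutation_importance(tr$tabular, fx$X[has, , drop = FALSE],
                                dataset$targets$cog[has], seed = cfg$seed)
  write.csv(data.frame(feature = rownames(imp),
                       median_importance = apply(imp, 1, stats::median),
                       mean_importance = rowMeans(imp)),
            file.path(out, "permutation_importance.csv"), row.names = FALSE)
  norm_vols <- lapply(dataset$volumes[has], .norm_arr)
  rf <- receptive_field_summary(tr$imaging, norm_vols,
                                dataset$targets$cog[has], seed = cfg$seed)
  jsonlite::write_json(c(.stamp(cfg), list(
    bottleneck = lapply(rf$bottleneck[c("pseudolabel", "tertile")], as.vector),
    encoder_backprojection = as.vector(rf$encoder$backprojection))),
    file.path(out, "receptive_field.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
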