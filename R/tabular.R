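#' Tissue volumes from a label map
#'
#' Per-class voxel counts times the voxel volume, for the three tissue
#' classes segmented (GM, WM, CSF).
#'
#' @param labels 3D integer label array (0 background, 1 GM, 2 WM, 3 CSF).
#' @param voxel_size mm per axis.
#' @return named numeric vector (V_GM, V_WM, V_CSF) in mm^3.
#' @export
tissue_volumes <- function(labels, voxel_size = c(1, 1, 1)) {
  lab <- as.integer(labels)
  vv <- prod(rep_len(voxel_size, 3))
  c(V_GM = sum(lab == 1L) * vv, V_WM = sum(lab == 2L) * vv,
    V_CSF = sum(lab == 3L) * vv)
}

#' Healthy-control reference for tissue-volume z-scores
#'
#' Mean and sd of each tissue volume over the training-fold cognitively
#' normal subjects. Must be computed from training subjects only; the
#' subject ids used are recorded for the leakage audit.
#'
#' @param volumes numeric matrix (subjects x 3, columns V_GM, V_WM, V_CSF)
#'   of control subjects.
#' @param subject_ids optional provenance.
#' @return a `control_reference` list with `mean`, `sd`, `subject_ids`.
#' @export
control_reference <- function(volumes, subject_ids = NULL) {
  volumes <- as.matrix(volumes)
  if (nrow(volumes) < 2) stop("no (or too few) control subjects in the ",
                              "training fold; cannot build a z-score reference")
  s <- apply(volumes, 2, sd)
  if (any(s <= 0)) stop("control volumes are constant; sd must be > 0")
  structure(list(mean = colMeans(volumes), sd = s,
                 subject_ids = subject_ids), class = "control_reference")
}

#' Tissue-volume z-scores against healthy controls
#'
#' @param volumes matrix or vector of tissue volumes (V_GM, V_WM, V_CSF).
#' @param reference a [control_reference] from training-fold controls.
#' @return z-scores, same shape as `volumes`.
#' @export
zscore_volumes <- function(volumes, reference) {
  stopifnot(inherits(reference, "control_reference"))
  if (is.null(dim(volumes)))
    (volumes - reference$mean) / reference$sd
  else
    sweep(sweep(as.matrix(volumes), 2, reference$mean), 2, reference$sd, "/")
}

#' Assemble the tabular feature matrix
#'
#' One-hot encodes the categorical demographics (sex over F/M; marital status
#' over married/divorced/other, case-normalised, with unknown categories
#' mapped to "other" with a warning) and appends continuous age and years of
#' education, plus optional tissue volumes and their z-scores. Baseline
#' cognition and diagnosis are never included (they are the outcome
#' variables). Subject ids are returned separately and are not part of the
#' feature matrix.
#'
#' @param records data.frame with subject_id, age, sex, education, marital.
#' @param volumes optional matrix of tissue volumes (subjects x 3).
#' @param zscores optional matrix of tissue-volume z-scores.
#' @return list with `X` (numeric matrix) and `subject_ids`.
#' @export
assemble_features <- function(records, volumes = NULL, zscores = NULL) {
  sex <- toupper(trimws(as.character(records$sex)))
  if (!all(sex %in% c("F", "M"))) stop("sex must be F or M")
  mar <- tolower(trimws(as.character(records$marital)))
  unknown <- !mar %in% c("married", "divorced", "other")
  if (any(unknown)) {
    warning("unknown marital categories mapped to 'other': ",
            paste(unique(mar[unknown]), collapse = ", "))
    mar[unknown] <- "other"
  }
  X <- cbind(age = records$age, education = records$education,
             sex_F = as.numeric(sex == "F"), sex_M = as.numeric(sex == "M"),
             marital_married = as.numeric(mar == "married"),
             marital_divorced = as.numeric(mar == "divorced"),
             marital_other = as.numeric(mar == "other"))
  if (!is.null(volumes)) X <- cbind(X, as.matrix(volumes))
  if (!is.null(zscores)) {
    z <- as.matrix(zscores)
    colnames(z) <- paste0("z_", colnames(z))
    X <- cbind(X, z)
  }
  list(X = X, subject_ids = records$subject_id)
}

#' Boosting hyperparameters of the tabular module
#'
#' Conservative defaults sized for cohorts of a few hundred subjects with a
#' handful of weakly informative features: shallow trees with row and column
#' subsampling. Deeper unsubsampled trees overfit this regime to the point
#' of negative out-of-fold R-squared.
#'
#' @param nrounds number of trees; `max_depth` tree depth; `eta` learning
#'   rate; `subsample`, `colsample_bytree` stochastic-boosting fractions.
#' @return list of parameters.
#' @export
tabular_params <- function(nrounds = 300, max_depth = 3, eta = 0.05,
                           subsample = 0.8, colsample_bytree = 0.8) {
  list(nrounds = nrounds, max_depth = max_depth, eta = eta,
       subsample = subsample, colsample_bytree = colsample_bytree)
}

#' Fit the gradient-boosted tabular model
#'
#' Gradient boosting on the demographic + volumetric features. For the
#' cognition task the objective is either plain squared error or the
#' Gamma-prior loss used as a custom objective: the trees are grown in log
#' space (y = exp(f)), which keeps predictions positive, with the analytic
#' gradient and Hessian of the loss.
#'
#' @param X numeric feature matrix (no subject ids).
#' @param y target vector (scores, rates, or 0/1 diagnosis).
#' @param task one of cognition_mse, cognition_gamma, alpha, diagnosis.
#' @param params a [tabular_params].
#' @param gamma_params a [gamma_loss_params]; estimated from `y` when NULL
#'   (pass fold-specific parameters to respect the leakage rules).
#' @param seed RNG seed; fits are deterministic given the seed.
#' @return a `voxcog_xgb` model.
#' @export
fit_tabular <- function(X, y, task = c("cognition_gamma", "cognition_mse",
                                       "alpha", "diagnosis"),
                        params = tabular_params(), gamma_params = NULL,
                        seed = 1) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (nrow(X) < 20) stop("need at least 20 training rows")
  if (length(y) != nrow(X)) stop("target length mismatch")
  if (sd(y) == 0) {
    warning("constant target; returning a constant predictor")
    return(structure(list(constant = y[1], task = task,
                          feature_names = colnames(X)),
                     class = "voxcog_xgb"))
  }
  base_params <- list(max_depth = params$max_depth, eta = params$eta,
                      subsample = params$subsample,
                      colsample_bytree = params$colsample_bytree,
                      nthread = 1, seed = seed)
  link <- "identity"
  if (task == "cognition_gamma") {
    if (is.null(gamma_params))
      gamma_params <- estimate_gamma_params(y)
    ylab <- pmax(y, 0)
    base <- log(max(mean(ylab), 1e-3))
    obj <- function(preds, dtrain) {
      lab <- xgboost::getinfo(dtrain, "label")
      gamma_loss_grad_hess(preds, lab, gamma_params)
    }
    dtrain <- xgboost::xgb.DMatrix(X, label = ylab, nthread = 1)
    # max_delta_step caps the per-leaf Newton step: the analytic Hessian of
    # the loss is not positive everywhere (it is floored), so uncapped steps
    # can blow up in log space
    booster <- xgboost::xgb.train(
      params = c(base_params, list(base_score = base, objective = obj,
                                   max_delta_step = 0.5)),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
    link <- "exp"
  } else {
    objective <- switch(task, cognition_mse = "reg:squarederror",
                        alpha = "reg:squarederror",
                        diagnosis = "binary:logistic")
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    booster <- xgboost::xgb.train(
      params = c(base_params, list(objective = objective)),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
  }
  structure(list(booster = booster, task = task, link = link,
                 feature_names = colnames(X), gamma_params = gamma_params),
            class = "voxcog_xgb")
}

#' @export
predict.voxcog_xgb <- function(object, newdata, ...) {
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(as.matrix(newdata))))
  newdata <- as.matrix(newdata)
  p <- predict(object$booster, xgboost::xgb.DMatrix(newdata, nthread = 1))
  if (object$link == "exp") exp(p) else p
}

#' Cross-validated R-squared of a tabular model
#'
#' K-fold CV over the provided rows; Gamma-loss parameters are re-estimated
#' inside each training fold so no validation label leaks into them.
#'
#' @inheritParams fit_tabular
#' @param k number of folds.
#' @return list with `r2` (overall, on pooled out-of-fold predictions),
#'   `fold_r2`, and `pred` (out-of-fold predictions).
#' @export
cv_tabular <- function(X, y, task = "cognition_gamma",
                       params = tabular_params(), k = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- rep(NA_real_, n)
  fold_r2 <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_tabular(X[tr, , drop = FALSE], y[tr], task = task,
                       params = params, seed = seed + f)
    pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    fold_r2[f] <- r_squared(pred[!tr], y[!tr])
  }
  list(r2 = r_squared(pred, y), fold_r2 = fold_r2, pred = pred)
}

#' R-squared-based ensemble weights
#'
#' Normalised convex weights of the imaging and non-imaging modules from
#' their cross-validated R-squared values (negatives clipped to zero). With
#' the published CV values of the tabular Gamma-loss model (0.31) and the
#' demographics-augmented imaging model (0.72) this yields approximately a
#' 30%/70% split.
#'
#' @param r2_im,r2_nim cross-validated R-squared of each module.
#' @return an `ensemble_weights` list with `r2_im`, `r2_nim`, `w_im`,
#'   `w_nim` (weights sum to 1).
#' @export
compute_ensemble_weights <- function(r2_im, r2_nim) {
  r2_im <- max(r2_im, 0)
  r2_nim <- max(r2_nim, 0)
  if (r2_im + r2_nim <= 0)
    stop("both modules have nonpositive R-squared; no informative module")
  structure(list(r2_im = r2_im, r2_nim = r2_nim,
                 w_im = r2_im / (r2_im + r2_nim),
                 w_nim = r2_nim / (r2_im + r2_nim)),
            class = "ensemble_weights")
}

#' Combine module predictions with ensemble weights
#'
#' Convex combination of the imaging and non-imaging predictions using the
#' normalised R-squared weights; for the diagnosis task the combination acts
#' on probabilities (decision threshold 0.5). Predictions must be aligned by
#' subject; named vectors are checked.
#'
#' @param im_preds,nim_preds numeric vectors (optionally named by subject).
#' @param w an [compute_ensemble_weights] result.
#' @param task unused placeholder kept for symmetry with the fitting API.
#' @return combined predictions.
#' @export
ensemble_predict <- function(im_preds, nim_preds, w, task = "cognition") {
  stopifnot(inherits(w, "ensemble_weights"))
  if (length(im_preds) != length(nim_preds)) stop("misaligned predictions")
  if (!is.null(names(im_preds)) && !is.null(names(nim_preds)) &&
      !identical(names(im_preds), names(nim_preds)))
    stop("misaligned subject ids between modules")
  w$w_im * im_preds + w$w_nim * nim_preds
}

#' Ensemble retraining under the R-squared-weighted loss
#'
#' Final phase: the imaging module is fine-tuned under the ensemble loss
#' (its gradient is the multitask gradient scaled by the imaging module's
#' R-squared weight; the expanding arm stays frozen and segmentation has no
#' ensemble), and the tabular module is refitted. The per-epoch log records
#' the exact ensemble loss recomposed from its components.
#'
#' @param model trained imaging model (after [train_multitask]).
#' @param tab_model fitted tabular model.
#' @param weights an [compute_ensemble_weights] result.
#' @param dataset imaging dataset (see [train_multitask]).
#' @param tab_X tabular feature matrix aligned with `dataset`.
#' @param train_rows integer rows used for retraining.
#' @param gamma_params fold Gamma-loss parameters.
#' @param tab_stats training-fold standardisation statistics for the
#'   imaging model's demographic inputs.
#' @param config a [train_config] (only the fine-tune fields are used).
#' @return list with retrained `model`, `tab_model` and the per-epoch `log`.
#' @export
ensemble_retrain <- function(model, tab_model, weights, dataset, tab_X,
                             train_rows, gamma_params, tab_stats,
                             config = train_config(finetune_epochs = 1)) {
  stopifnot(inherits(weights, "ensemble_weights"))
  w <- config$loss_weights
  model <- apply_freeze_policy(model, "multitask")
  opt <- adam_init(model$params, lr = config$lr_finetune,
                   weight_decay = config$weight_decay)
  tg <- dataset$targets
  tab <- .tab_standardize(dataset$tabular, stats = tab_stats)$X
  log <- list()
  r2im <- min(max(weights$r2_im, 0), 1)
  with_seed(config$seed + 2L, {
    for (ep in seq_len(config$finetune_epochs)) {
      comp_im <- 0
      for (i in sample(train_rows)) {
        vol <- .norm_arr(dataset$volumes[[i]])
        tabi <- if (model$config$n_tabular > 0) tab[i, ] else NULL
        fw <- unet_forward(model, vol, tabular = tabi, need_seg = TRUE,
                           keep_cache = TRUE)
        tmat <- as_prob4(dataset$labels[[i]])
        nv <- ncol(tmat)
        tg_i <- list(cog = tg$cog[i], alpha = tg$alpha[i], diag = tg$diag[i],
                     has_cog = tg$has_cog[i], has_alpha = tg$has_alpha[i])
        sl <- .scalar_losses(list(cog = fw$cognition, cog_raw = fw$cog_raw,
                                  alpha = fw$alpha, diag_raw = fw$diag_raw),
                             tg_i, gamma_params, w)
        l_seg <- segmentation_ce_loss(fw$seg_probs, tmat)
        l_im <- multitask_loss(sl$l_cog, l_seg, sl$l_alpha, sl$l_diag, w)
        g <- unet_backward(model, fw$cache, list(
          d_seg_logits = r2im * w$lambda_seg * (fw$seg_probs - tmat) / nv,
          d_cog = r2im * sl$d_cog, d_alpha = r2im * sl$d_alpha,
          d_diag_raw = r2im * sl$d_diag_raw))
        model$params <- adam_step(opt, model$params, g, model$trainable)
        comp_im <- comp_im + l_im
      }
      l_im_mean <- comp_im / length(train_rows)
      pred_nim <- predict(tab_model, tab_X[train_rows, , drop = FALSE])
      has <- tg$has_cog[train_rows]
      l_nim <- if (tab_model$task == "cognition_gamma")
        gamma_loss(pmax(pred_nim[has], 1e-8), tg$cog[train_rows][has],
                   gamma_params)
      else mse_cognition_loss(pred_nim[has], tg$cog[train_rows][has])
      log[[ep]] <- data.frame(epoch = ep, l_im = l_im_mean, l_nim = l_nim,
                              ensemble_loss = ensemble_loss(
                                l_im_mean, l_nim, weights$r2_im,
                                weights$r2_nim))
    }
  })
  if (weights$w_nim > 0) {
    has <- tg$has_cog[train_rows]
    tab_model <- fit_tabular(tab_X[train_rows, , drop = FALSE][has, ,
                                                               drop = FALSE],
                             tg$cog[train_rows][has], task = tab_model$task,
                             gamma_params = gamma_params,
                             seed = config$seed)
  }
  list(model = model, tab_model = tab_model,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

#' Leakage audit over fold artifacts
#'
#' Verifies that (1) the split plan partitions subjects disjointly and (2)
#' every fold-derived statistic (Gamma-loss parameters, z-score control
#' references, and any object exposing a `subject_ids` field) was computed
#' exclusively from that fold's training subjects.
#'
#' @param plan a [make_splits] plan.
#' @param artifacts named list per fold: each element a list of objects with
#'   `subject_ids` provenance, plus a `fold` index.
#' @return TRUE invisibly; errors with a description on any violation.
#' @export
audit_leakage <- function(plan, artifacts) {
  validate_split_plan(plan)
  for (a in artifacts) {
    ids <- split_ids(plan, a$fold)
    for (obj in a$objects) {
      used <- obj$subject_ids
      if (is.null(used))
        stop("artifact without subject provenance cannot be audited")
      bad <- setdiff(used, ids$train)
      if (length(bad) > 0)
        stop("leakage: fold-", a$fold, " artifact used non-training ",
             "subjects: ", paste(head(bad, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}
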