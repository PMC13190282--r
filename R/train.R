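#' Standard intensity normalisation
#'
#' Rescales a volume to zero mean and unit variance. Applied to every input
#' before it enters the network (training, validation and test alike);
#' affine-transformed copies of the same volume normalise to the same output.
#'
#' @param v [volume3d] or 3D array.
#' @return same type as input.
#' @export
normalize_volume <- function(v) {
  arr <- as_volume_array(v)
  s <- sd(arr)
  if (s == 0) stop("constant volume cannot be normalised")
  out <- (arr - mean(arr)) / s
  if (inherits(v, "volume3d")) volume3d(out, v$voxel_size, v$origin) else out
}

#' Elastic deformation augmentation
#'
#' One smoothed random displacement field, applied identically to the image
#' (trilinear) and its label map (nearest neighbour, so no new labels are
#' invented). Used during training steps only; magnitude 0 is the identity.
#'
#' @param volume [volume3d] or 3D array.
#' @param labels 3D integer label array (or NULL).
#' @param smooth_sd Gaussian smoothing sd of the field, voxels.
#' @param magnitude maximum absolute displacement of each smoothed component,
#'   voxels.
#' @return list with `volume` and `labels` (warped).
#' @export
elastic_augment <- function(volume, labels = NULL, smooth_sd = 4,
                            magnitude = 2) {
  if (smooth_sd < 0 || magnitude < 0) stop("parameters must be >= 0")
  arr <- as_volume_array(volume)
  if (magnitude == 0)
    return(list(volume = arr, labels = labels))
  dims <- dim(arr)
  n <- prod(dims)
  fields <- lapply(1:3, function(i) {
    f <- .cpp_gauss_smooth(rnorm(n), as.integer(dims), smooth_sd)
    f / max(max(abs(f)), 1e-12) * magnitude
  })
  warped <- array(.cpp_warp(as.numeric(arr), as.integer(dims), fields[[1]],
                            fields[[2]], fields[[3]], FALSE), dim = dims)
  lab_out <- NULL
  if (!is.null(labels)) {
    lab_out <- array(as.integer(round(
      .cpp_warp(as.numeric(labels), as.integer(dims), fields[[1]],
                fields[[2]], fields[[3]], TRUE))), dim = dims)
  }
  list(volume = warped, labels = lab_out)
}

#' Training configuration
#'
#' Desk-scale defaults: batch size 1 (per-subject Adam steps), learning rate
#' 0.001, short epoch counts sized for CPU runs on 32^3 phantoms. The
#' multitask phase runs a fully connected head warm-up on cached bottleneck
#' features before joint fine-tuning of the contracting arm, with early
#' stopping on the validation multitask loss (patience 5).
#'
#' @param epochs segmentation-pretraining epochs.
#' @param finetune_epochs joint multitask fine-tuning epochs.
#' @param warmup_iters full-batch Adam iterations of the head warm-up.
#' @param warmup_min iterations before warm-up early stopping may trigger
#'   (the scalar heads have very different loss scales and the slower ones
#'   need a minimum budget).
#' @param lr Adam learning rate (pretraining and warm-up).
#' @param lr_finetune learning rate of the joint fine-tuning phase.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param patience early-stopping patience (validation loss checks).
#' @param augment_sd,augment_magnitude elastic augmentation parameters
#'   (voxels); magnitude 0 disables augmentation.
#' @param loss_weights a [multitask_weights].
#' @param seed seed for shuffling and augmentation draws.
#' @param verbose print per-epoch losses.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 3, finetune_epochs = 2, warmup_iters = 600,
                         warmup_min = 200, lr = 1e-3, lr_finetune = 2e-4,
                         weight_decay = 1e-4,
                         patience = 10, augment_sd = 4, augment_magnitude = 1,
                         loss_weights = multitask_weights(), seed = 1,
                         verbose = FALSE) {
  stopifnot(epochs >= 1, finetune_epochs >= 0, augment_sd >= 0,
            augment_magnitude >= 0)
  structure(list(epochs = epochs, finetune_epochs = finetune_epochs,
                 warmup_iters = warmup_iters, warmup_min = warmup_min,
                 lr = lr,
                 lr_finetune = lr_finetune, weight_decay = weight_decay,
                 patience = patience, augment_sd = augment_sd,
                 augment_magnitude = augment_magnitude,
                 loss_weights = loss_weights, seed = seed,
                 verbose = verbose), class = "train_config")
}

.norm_arr <- function(v) as_volume_array(normalize_volume(v))

#' Segmentation pretraining
#'
#' Trains all layers on the cross-entropy segmentation loss alone, over the
#' disease cohort optionally enlarged with a zero-atrophy young-control
#' cohort (which increases the diversity and size of the segmentation-only
#' training sample). Elastic augmentation is applied at each training step.
#'
#' @param model a [build_unet] model.
#' @param volumes list of volumes (cohort order).
#' @param labels list of matching label arrays.
#' @param config a [train_config].
#' @return list with the trained `model` and a `history` data.frame of
#'   per-epoch mean segmentation loss.
#' @export
pretrain_segmentation <- function(model, volumes, labels, config = train_config()) {
  stopifnot(length(volumes) == length(labels), length(volumes) >= 1)
  model <- apply_freeze_policy(model, "seg_pretrain")
  opt <- adam_init(model$params, lr = config$lr,
                   weight_decay = config$weight_decay)
  n <- length(volumes)
  hist <- numeric(config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      tot <- 0
      for (i in ord) {
        vol <- as_volume_array(volumes[[i]])
        lab <- labels[[i]]
        if (config$augment_magnitude > 0) {
          aug <- elastic_augment(vol, lab, config$augment_sd,
                                 config$augment_magnitude)
          vol <- aug$volume
          lab <- aug$labels
        }
        vol <- .norm_arr(vol)
        fw <- unet_forward(model, vol, tabular = rep(0, model$config$n_tabular),
                           need_seg = TRUE, keep_cache = TRUE)
        tmat <- as_prob4(lab)
        nv <- ncol(tmat)
        loss <- segmentation_ce_loss(fw$seg_probs, tmat)
        d_logits <- (fw$seg_probs - tmat) / nv
        g <- unet_backward(model, fw$cache, list(d_seg_logits = d_logits))
        model$params <- adam_step(opt, model$params, g, model$trainable)
        tot <- tot + loss
      }
      hist[ep] <- tot / n
      if (config$verbose)
        message(sprintf("pretrain epoch %d: seg CE %.4f", ep, hist[ep]))
    }
  })
  list(model = model, history = data.frame(epoch = seq_len(config$epochs),
                                           seg_loss = hist))
}

# Standardise the continuous tabular columns using training-fold statistics.
.tab_standardize <- function(X, stats = NULL, train_rows = NULL) {
  cont <- intersect(c("age", "education"), colnames(X))
  if (is.null(stats)) {
    rows <- train_rows %||% seq_len(nrow(X))
    stats <- list(mean = colMeans(X[rows, cont, drop = FALSE]),
                  sd = pmax(apply(X[rows, cont, drop = FALSE], 2, sd), 1e-8))
  }
  for (j in cont) X[, j] <- (X[, j] - stats$mean[[j]]) / stats$sd[[j]]
  list(X = X, stats = stats)
}

# Forward the scalar heads over cached bottleneck features (matrix n x 8192
# plus tabular block), returning predictions and intermediate activations.
.fc_forward <- function(p, Xt) {
  H1 <- pmax(p$fc1_W %*% Xt + p$fc1_b, 0)
  H2 <- pmax(p$fc2_W %*% H1 + p$fc2_b, 0)
  cog_raw <- as.numeric(p$head_cog_W %*% H2 + p$head_cog_b)
  list(H1 = H1, H2 = H2, cog_raw = cog_raw, cog = softplus(cog_raw),
       alpha = as.numeric(p$head_alpha_W %*% H2 + p$head_alpha_b),
       diag_raw = as.numeric(p$head_diag_W %*% H2 + p$head_diag_b))
}

# Scalar multitask loss (no segmentation term) and output-side gradients for
# a batch of head predictions.
.scalar_losses <- function(fwd, tg, gp, w) {
  n <- length(fwd$cog)
  has_c <- tg$has_cog
  has_a <- tg$has_alpha
  l_cog <- if (any(has_c)) gamma_loss(pmax(fwd$cog[has_c], 1e-8),
                                      tg$cog[has_c], gp) else 0
  l_alpha <- if (any(has_a)) alpha_loss(fwd$alpha[has_a], tg$alpha[has_a])
             else 0
  p_diag <- plogis(fwd$diag_raw)
  l_diag <- diagnosis_logloss(p_diag, tg$diag)
  d_cog <- rep(0, n)
  if (any(has_c)) {
    y <- pmax(fwd$cog[has_c], 1e-8)
    d_cog[has_c] <- ((y - tg$cog[has_c]) / gp$sigma^2 - 1 / y + 1 / gp$gamma) /
      sum(has_c)
  }
  d_alpha <- rep(0, n)
  if (any(has_a))
    d_alpha[has_a] <- 2 * (fwd$alpha[has_a] - tg$alpha[has_a]) / sum(has_a)
  d_diag_raw <- (p_diag - tg$diag) / n
  list(l_cog = l_cog, l_alpha = l_alpha, l_diag = l_diag,
       loss = w$lambda_cog * l_cog + w$lambda_alpha * l_alpha +
         w$lambda_diag * l_diag,
       d_cog = w$lambda_cog * d_cog, d_alpha = w$lambda_alpha * d_alpha,
       d_diag_raw = w$lambda_diag * d_diag_raw)
}

#' Multitask training phase
#'
#' Starting from a segmentation-pretrained checkpoint, freezes the expanding
#' arm, estimates the Gamma-loss parameters from the training-fold cognition
#' labels only, warm-starts the fully connected heads on cached bottleneck
#' features, then jointly fine-tunes the contracting arm and heads on the
#' combined loss (cognition + segmentation + decline rate + diagnosis).
#' Model selection uses validation-fold losses only; the set-aside test
#' partition is never touched here.
#'
#' @param model pretrained `unet3d`.
#' @param dataset list with `volumes`, `labels`, `tabular` (numeric matrix,
#'   rows in cohort order), `targets` (data.frame with subject_id, cog,
#'   alpha, diag, has_cog, has_alpha) and `subject_id`.
#' @param plan a [make_splits] plan over the dataset's subjects.
#' @param fold validation fold index.
#' @param config a [train_config].
#' @return list with the trained `model`, `gamma_params`, `tab_stats`,
#'   per-epoch `history`, and `metrics` on the validation fold.
#' @export
train_multitask <- function(model, dataset, plan, fold = 1,
                            config = train_config()) {
  validate_split_plan(plan)
  ids <- split_ids(plan, fold)
  all_ids <- dataset$subject_id
  if (length(intersect(ids$train, ids$validation)) > 0 ||
      length(intersect(ids$train, ids$test)) > 0)
    stop("leakage: overlapping subjects across partitions")
  tr <- match(ids$train, all_ids)
  va <- match(ids$validation, all_ids)
  tr <- tr[!is.na(tr)]
  va <- va[!is.na(va)]
  if (length(tr) < 2) stop("too few training subjects")
  tg <- dataset$targets
  w <- config$loss_weights

  gp <- estimate_gamma_params(tg$cog[tr][tg$has_cog[tr]],
                              subject_ids = all_ids[tr][tg$has_cog[tr]])
  ts <- .tab_standardize(dataset$tabular, train_rows = tr)
  tab <- ts$X
  # decline-rate targets are standardised (training-fold statistics) for the
  # head; predictions are de-standardised via model$alpha_stats
  a_tr <- tg$alpha[tr][tg$has_alpha[tr]]
  alpha_stats <- list(mean = mean(a_tr), sd = max(sd(a_tr), 1e-8))
  tg$alpha <- (tg$alpha - alpha_stats$mean) / alpha_stats$sd
  model$alpha_stats <- NULL
  model <- apply_freeze_policy(model, "multitask")

  norm_vols <- lapply(dataset$volumes, .norm_arr)
  feats <- t(vapply(norm_vols, function(v) extract_bottleneck(model, v),
                    numeric(model$config$flat_len)))
  Xt_tr <- t(cbind(feats[tr, , drop = FALSE], tab[tr, , drop = FALSE]))
  Xt_va <- t(cbind(feats[va, , drop = FALSE], tab[va, , drop = FALSE]))
  tg_tr <- lapply(tg[c("cog", "alpha", "diag", "has_cog", "has_alpha")],
                  function(col) col[tr])
  tg_va <- lapply(tg[c("cog", "alpha", "diag", "has_cog", "has_alpha")],
                  function(col) col[va])

  fc_names <- grep("^(fc|head_)", names(model$params), value = TRUE)
  fc_mask <- setNames(names(model$params) %in% fc_names, names(model$params))
  opt <- adam_init(model$params, lr = config$lr,
                   weight_decay = config$weight_decay)
  best <- list(loss = Inf, params = model$params)
  stall <- 0
  warm_hist <- numeric(0)
  for (it in seq_len(config$warmup_iters)) {
    p <- model$params
    fw <- .fc_forward(p, Xt_tr)
    sl <- .scalar_losses(fw, tg_tr, gp, w)
    n <- length(fw$cog)
    d_cog_raw <- sl$d_cog * plogis(fw$cog_raw)
    d_H2 <- crossprod(p$head_cog_W, matrix(d_cog_raw, 1)) +
      crossprod(p$head_alpha_W, matrix(sl$d_alpha, 1)) +
      crossprod(p$head_diag_W, matrix(sl$d_diag_raw, 1))
    g <- list(
      head_cog_W = matrix(d_cog_raw, 1) %*% t(fw$H2),
      head_cog_b = sum(d_cog_raw),
      head_alpha_W = matrix(sl$d_alpha, 1) %*% t(fw$H2),
      head_alpha_b = sum(sl$d_alpha),
      head_diag_W = matrix(sl$d_diag_raw, 1) %*% t(fw$H2),
      head_diag_b = sum(sl$d_diag_raw))
    d_Z2 <- d_H2 * (fw$H2 > 0)
    g$fc2_W <- d_Z2 %*% t(fw$H1)
    g$fc2_b <- rowSums(d_Z2)
    d_Z1 <- crossprod(p$fc2_W, d_Z2) * (fw$H1 > 0)
    g$fc1_W <- d_Z1 %*% t(Xt_tr)
    g$fc1_b <- rowSums(d_Z1)
    model$params <- adam_step(opt, model$params, g, fc_mask)
    if (it %% 10 == 0 || it == config$warmup_iters) {
      vl <- .scalar_losses(.fc_forward(model$params, Xt_va), tg_va, gp, w)$loss
      warm_hist <- c(warm_hist, vl)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = model$params)
        stall <- 0
      } else stall <- stall + 1
      if (stall >= config$patience && it >= (config$warmup_min %||% 0)) break
    }
  }
  model$params <- best$params

  # joint fine-tuning through the contracting arm (expanding arm frozen)
  opt2 <- adam_init(model$params, lr = config$lr_finetune,
                    weight_decay = config$weight_decay)
  hist <- list()
  best_ft <- list(loss = best$loss, params = model$params)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$finetune_epochs)) {
      ord <- sample(tr)
      comp <- c(cog = 0, seg = 0, alpha = 0, diag = 0)
      for (i in ord) {
        vol <- as_volume_array(dataset$volumes[[i]])
        lab <- dataset$labels[[i]]
        if (config$augment_magnitude > 0) {
          aug <- elastic_augment(vol, lab, config$augment_sd,
                                 config$augment_magnitude)
          vol <- aug$volume
          lab <- aug$labels
        }
        vol <- .norm_arr(vol)
        tabi <- if (model$config$n_tabular > 0) tab[i, ] else NULL
        fw <- unet_forward(model, vol, tabular = tabi, need_seg = TRUE,
                           keep_cache = TRUE)
        tmat <- as_prob4(lab)
        nv <- ncol(tmat)
        tg_i <- list(cog = tg$cog[i], alpha = tg$alpha[i], diag = tg$diag[i],
                     has_cog = tg$has_cog[i], has_alpha = tg$has_alpha[i])
        sl <- .scalar_losses(list(cog = fw$cognition, cog_raw = fw$cog_raw,
                                  alpha = fw$alpha, diag_raw = fw$diag_raw),
                             tg_i, gp, w)
        l_seg <- segmentation_ce_loss(fw$seg_probs, tmat)
        d_logits <- w$lambda_seg * (fw$seg_probs - tmat) / nv
        g <- unet_backward(model, fw$cache,
                           list(d_seg_logits = d_logits, d_cog = sl$d_cog,
                                d_alpha = sl$d_alpha,
                                d_diag_raw = sl$d_diag_raw))
        model$params <- adam_step(opt2, model$params, g, model$trainable)
        comp <- comp + c(sl$l_cog, l_seg, sl$l_alpha, sl$l_diag)
      }
      comp <- comp / length(tr)
      val <- .validation_scalar_loss(model, dataset, tg, va, tab, gp, w)
      hist[[ep]] <- data.frame(epoch = ep, l_cog = comp[1], l_seg = comp[2],
                               l_alpha = comp[3], l_diag = comp[4],
                               train_loss = multitask_loss(comp[1], comp[2],
                                                           comp[3], comp[4], w),
                               val_loss = val)
      if (config$verbose)
        message(sprintf("finetune epoch %d: train %.4f val %.4f", ep,
                        hist[[ep]]$train_loss, val))
      if (val < best_ft$loss - 1e-6) {
        best_ft <- list(loss = val, params = model$params)
      }
    }
  })
  if (config$finetune_epochs > 0) model$params <- best_ft$params
  model$alpha_stats <- alpha_stats
  preds <- predict_subjects(model, dataset, va, tab)
  metrics <- evaluate_predictions(preds, dataset, va)
  list(model = model, gamma_params = gp, tab_stats = ts$stats,
       history = if (length(hist)) do.call(rbind, hist) else NULL,
       warmup_val_loss = warm_hist, metrics = metrics, fold = fold,
       train_ids = all_ids[tr], validation_ids = all_ids[va])
}

.validation_scalar_loss <- function(model, dataset, tg, va, tab, gp, w) {
  if (length(va) == 0) return(NA_real_)
  tot <- 0
  for (i in va) {
    vol <- .norm_arr(dataset$volumes[[i]])
    tabi <- if (model$config$n_tabular > 0) tab[i, ] else NULL
    fw <- unet_forward(model, vol, tabular = tabi, need_seg = FALSE)
    tg_i <- list(cog = tg$cog[i], alpha = tg$alpha[i],
                 diag = tg$diag[i], has_cog = tg$has_cog[i],
                 has_alpha = tg$has_alpha[i])
    sl <- .scalar_losses(list(cog = fw$cognition, cog_raw = fw$cog_raw,
                              alpha = fw$alpha, diag_raw = fw$diag_raw),
                         tg_i, gp, w)
    tot <- tot + sl$loss
  }
  tot / length(va)
}

#' Predict all outputs for a set of subjects
#'
#' @param model trained `unet3d`.
#' @param dataset as in [train_multitask].
#' @param rows integer row indices of the subjects to predict.
#' @param tab standardised tabular matrix (defaults to the dataset's raw
#'   tabular block; pass the matrix standardised with training-fold
#'   statistics for honest evaluation).
#' @param need_seg also return segmentations.
#' @return data.frame of per-subject predictions, with a `seg` attribute
#'   (list of 4 x N probability matrices) when `need_seg` is TRUE.
#' @export
predict_subjects <- function(model, dataset, rows, tab = dataset$tabular,
                             need_seg = TRUE) {
  out <- data.frame(subject_id = dataset$subject_id[rows],
                    cognition = NA_real_, alpha = NA_real_,
                    diag_prob = NA_real_, stringsAsFactors = FALSE)
  segs <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    vol <- .norm_arr(dataset$volumes[[i]])
    tabi <- if (model$config$n_tabular > 0) tab[i, ] else NULL
    fw <- unet_forward(model, vol, tabular = tabi, need_seg = need_seg)
    out$cognition[k] <- fw$cognition
    out$alpha[k] <- fw$alpha
    out$diag_prob[k] <- fw$diag_prob
    if (need_seg) segs[[k]] <- fw$seg_probs
  }
  attr(out, "seg") <- if (need_seg) segs else NULL
  out
}

#' Coefficient of determination, mean absolute error, AUC
#'
#' Evaluation primitives: R-squared is 1 - SS_res / SS_tot (the mean
#' predictor scores exactly 0), AUC is computed by a full threshold sweep
#' with trapezoidal integration and is reported as NA when the truth has a
#' single class.
#'
#' @param pred,obs numeric vectors.
#' @return scalar metric.
#' @export
r_squared <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  if (length(obs) < 2) return(NA_real_)
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' @rdname r_squared
#' @export
mae <- function(pred, obs) mean(abs(pred - obs))

#' @param scores classifier scores; `labels` 0/1 truth.
#' @rdname r_squared
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / neg,
                numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Confusion counts at a 0.5 threshold
#' @param prob predicted probabilities; `labels` 0/1 truth.
#' @return named vector (tp, fp, fn, tn).
#' @export
confusion_counts <- function(prob, labels) {
  pred <- as.integer(prob >= 0.5)
  c(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1), tn = sum(pred == 0 & labels == 0))
}

#' Full metrics report for a prediction set
#'
#' Computes the evaluation suite on one subject subset: weighted and
#' per-class Dice for segmentation, R-squared / MAE / Pearson r for baseline
#' cognition, R-squared for the decline rate, and accuracy / AUC / confusion
#' counts for diagnosis.
#'
#' @param preds a [predict_subjects] result.
#' @param dataset the dataset the rows refer to.
#' @param rows the same row indices used for prediction.
#' @param dice_weights per-class Dice weights.
#' @return a `metrics_report` list.
#' @export
evaluate_predictions <- function(preds, dataset, rows,
                                 dice_weights = c(1, 1, 1, 1)) {
  tg <- dataset$targets
  segs <- attr(preds, "seg")
  dice <- dice_pc <- NULL
  if (!is.null(segs) && !is.null(dataset$labels)) {
    dv <- vapply(seq_along(rows), function(k)
      weighted_dice(segs[[k]], dataset$labels[[rows[k]]], dice_weights),
      numeric(1))
    dice <- mean(dv)
    pc <- vapply(seq_along(rows), function(k)
      per_class_dice(segs[[k]], dataset$labels[[rows[k]]]), numeric(4))
    dice_pc <- rowMeans(pc)
  }
  hc <- tg$has_cog[rows]
  ha <- tg$has_alpha[rows]
  cogp <- preds$cognition[hc]
  cogt <- tg$cog[rows][hc]
  diag_t <- tg$diag[rows]
  structure(list(
    dice_weighted = dice, dice_per_class = dice_pc,
    cog_r2 = r_squared(cogp, cogt),
    cog_mae = if (any(hc)) mae(cogp, cogt) else NA_real_,
    cog_pearson = if (sum(hc) > 2) suppressWarnings(cor(cogp, cogt))
                  else NA_real_,
    alpha_r2 = r_squared(preds$alpha[ha], tg$alpha[rows][ha]),
    diag_accuracy = mean((preds$diag_prob >= 0.5) == (diag_t == 1)),
    diag_auc = roc_auc(preds$diag_prob, diag_t),
    diag_confusion = confusion_counts(preds$diag_prob, diag_t),
    n = length(rows)), class = "metrics_report")
}

#' Aggregate fold-wise metrics as mean and sd
#' @param reports list of `metrics_report` objects (one per fold).
#' @return data.frame with metric, mean, sd.
#' @export
summarize_folds <- function(reports) {
  nums <- c("dice_weighted", "cog_r2", "cog_mae", "cog_pearson", "alpha_r2",
            "diag_accuracy", "diag_auc")
  rows <- lapply(nums, function(m) {
    v <- vapply(reports, function(r) r[[m]] %||% NA_real_, numeric(1))
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = sd(v[is.finite(v)]))
  })
  do.call(rbind, rows)
}

#' Assemble the imaging training dataset from a phantom cohort
#'
#' Builds normalisable volumes, labels, one-hot demographics, and the target
#' table (baseline cognition; empirical decline rate fitted per subject from
#' its longitudinal series; AD vs non-AD diagnosis label). Baseline cognition
#' and diagnosis are outcomes, never inputs. Subject IDs are kept alongside
#' (not inside) the feature matrix.
#'
#' @param cohort a [generate_cohort] result (with images).
#' @param alpha_offset log-offset used when fitting decline rates.
#' @return dataset list for [train_multitask].
#' @export
assemble_imaging_dataset <- function(cohort, alpha_offset = 1) {
  rec <- cohort$records
  fx <- assemble_features(rec)
  alpha_emp <- rep(NA_real_, nrow(rec))
  if (!is.null(cohort$adas_series)) {
    fits <- fit_alpha_series(cohort$adas_series, offset = alpha_offset)
    alpha_emp[match(fits$subject_id, rec$subject_id)] <- fits$alpha
  }
  targets <- data.frame(
    subject_id = rec$subject_id,
    cog = rec$adas0,
    alpha = alpha_emp,
    diag = as.integer(rec$diagnosis == "AD"),
    has_cog = is.finite(rec$adas0),
    has_alpha = is.finite(alpha_emp),
    stringsAsFactors = FALSE)
  list(subject_id = rec$subject_id, volumes = cohort$volumes,
       labels = cohort$labels, tabular = fx$X, targets = targets)
}
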