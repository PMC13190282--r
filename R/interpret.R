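#' Occlusion map of the cognition prediction
#'
#' Slides an occluding cube over the volume (default 5x5x5, stride 5),
#' replaces its contents with the fill value (0 in normalised-intensity
#' space, i.e. the volume mean), and records the increase in squared
#' cognition error attributed to every voxel of the patch. Deterministic
#' given model, volume and patch geometry. Negative changes (occlusion
#' accidentally improving the prediction) are floored at zero so maps are
#' nonnegative before cohort normalisation.
#'
#' @param model trained `unet3d`.
#' @param volume normalised input volume ([volume3d] or array) at the model's
#'   input size.
#' @param target empirical cognition score of this subject.
#' @param tabular tabular inputs (if the model uses them).
#' @param patch occlusion cube edge, voxels.
#' @param stride patch stride, voxels.
#' @param fill replacement intensity.
#' @return an `occlusion_result`: `score` (3D array), `baseline_pred`,
#'   `patch`, `stride`, `fill`.
#' @export
occlusion_map <- function(model, volume, target, tabular = NULL, patch = 5,
                          stride = 5, fill = 0) {
  arr <- as_volume_array(volume)
  dims <- dim(arr)
  if (any(patch > dims)) stop("patch larger than the volume")
  if (model$config$n_tabular > 0 && is.null(tabular))
    tabular <- rep(0, model$config$n_tabular)
  base_pred <- unet_forward(model, arr, tabular = tabular,
                            need_seg = FALSE)$cognition
  base_err <- (base_pred - target)^2
  score <- array(0, dim = dims)
  starts <- lapply(dims, function(d) unique(pmin(seq(1, d, by = stride),
                                                 d - patch + 1L)))
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    xi <- sx:(sx + patch - 1)
    yi <- sy:(sy + patch - 1)
    zi <- sz:(sz + patch - 1)
    occluded <- arr
    occluded[xi, yi, zi] <- fill
    pred <- unet_forward(model, occluded, tabular = tabular,
                         need_seg = FALSE)$cognition
    inc <- max((pred - target)^2 - base_err, 0)
    score[xi, yi, zi] <- score[xi, yi, zi] + inc
  }
  structure(list(score = score, baseline_pred = base_pred, patch = patch,
                 stride = stride, fill = fill), class = "occlusion_result")
}

#' Aggregate occlusion maps across a cohort
#'
#' Normalises the per-subject maps jointly so the cohort-global maximum
#' equals the ceiling (10), then averages voxelwise on the common grid. If
#' every map is identically zero (a model that ignores the image) the zero
#' map is returned unscaled.
#'
#' @param maps list of [occlusion_map] results (or raw score arrays).
#' @param ceiling normalisation ceiling (default 10).
#' @return list with `mean_map` (array), `maps_scaled` (list), `global_max`.
#' @export
aggregate_occlusion <- function(maps, ceiling = 10) {
  if (length(maps) == 0) stop("no maps to aggregate (empty subject filter)")
  arrs <- lapply(maps, function(m)
    if (inherits(m, "occlusion_result")) m$score else m)
  gmax <- max(vapply(arrs, max, numeric(1)))
  scaled <- if (gmax > 0) lapply(arrs, function(a) a * ceiling / gmax)
            else arrs
  mean_map <- Reduce(`+`, scaled) / length(scaled)
  list(mean_map = mean_map, maps_scaled = scaled, global_max = gmax)
}

#' Average an occlusion map within atlas regions
#'
#' @param map 3D score array.
#' @param atlas 3D integer label array on the same grid (0 = background,
#'   excluded).
#' @return data.frame region, mean_score, n_voxels.
#' @export
atlas_average <- function(map, atlas) {
  if (!all(dim(map) == dim(atlas))) stop("atlas must be on the same grid")
  regions <- sort(unique(as.integer(atlas)))
  regions <- regions[regions != 0]
  if (length(regions) == 0) stop("atlas has no labelled regions")
  rows <- lapply(regions, function(r) {
    sel <- atlas == r
    data.frame(region = r, mean_score = mean(map[sel]), n_voxels = sum(sel))
  })
  do.call(rbind, rows)
}

#' Permutation importance of tabular features
#'
#' For each feature, the decrease in R-squared when that single column is
#' resampled (permuted), repeated for `n_iter` iterations (default 25);
#' the distribution over iterations is returned.
#'
#' @param model a fitted `voxcog_xgb`.
#' @param X feature matrix; `y` target.
#' @param n_iter permutation iterations.
#' @param seed RNG seed.
#' @return matrix (features x iterations) of R-squared decreases.
#' @export
permutation_importance <- function(model, X, y, n_iter = 25, seed = 1) {
  X <- as.matrix(X)
  base_r2 <- r_squared(predict(model, X), y)
  with_seed(seed, {
    res <- matrix(NA_real_, ncol(X), n_iter,
                  dimnames = list(colnames(X), NULL))
    for (j in seq_len(ncol(X))) {
      for (it in seq_len(n_iter)) {
        Xp <- X
        Xp[, j] <- X[sample(nrow(X)), j]
        res[j, it] <- base_r2 - r_squared(predict(model, Xp), y)
      }
    }
    res
  })
}

#' Inclusion importance of the imaging module
#'
#' Difference in overall R-squared between the best ensemble model and the
#' best tabular-only model on the same validation subjects: the boost from
#' including the imaging module. May be negative.
#'
#' @param r2_ensemble,r2_tabular_only R-squared values.
#' @return the difference.
#' @export
inclusion_importance <- function(r2_ensemble, r2_tabular_only) {
  r2_ensemble - r2_tabular_only
}

#' Receptive-field feature-manifold summary
#'
#' Samples spatial positions of the deepest encoder layer and the bottleneck
#' over the cohort, reduces each layer's channel vectors to 3 principal
#' components, clusters them into k pseudolabels (k-means, k = 3), attaches
#' the subject's cognition tertile (low/medium/high), and projects the
#' bottleneck pseudolabels back onto the corresponding parent positions of
#' the previous layer for visualisation.
#'
#' @param model trained `unet3d`.
#' @param volumes list of normalised volumes.
#' @param scores per-subject cognition scores (for the tertile grouping).
#' @param n number of sampled (subject, position) pairs (default 250; sampled
#'   with replacement, with a warning, if fewer are available).
#' @param pca_dim number of principal components (default 3).
#' @param k number of k-means pseudolabels (default 3).
#' @param seed RNG seed.
#' @return list per layer with `projection` (n x pca_dim), `pseudolabel`,
#'   `tertile`, `subject`, plus `backprojection` mapping bottleneck
#'   pseudolabels onto encoder positions.
#' @export
receptive_field_summary <- function(model, volumes, scores, n = 250,
                                    pca_dim = 3, k = 3, seed = 1) {
  cfg <- model$config
  depth <- cfg$depth
  n_sub <- length(volumes)
  tert <- cut(scores, quantile(scores, c(0, 1/3, 2/3, 1)),
              labels = c("low", "medium", "high"), include.lowest = TRUE)
  # collect activations: deepest encoder skip (pre-pool) and bottleneck
  enc_feats <- vector("list", n_sub)
  bott_feats <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    fw <- unet_forward(model, as_volume_array(volumes[[i]]),
                       tabular = rep(0, cfg$n_tabular), need_seg = FALSE,
                       keep_cache = TRUE)
    enc_feats[[i]] <- fw$cache$skips[[depth]]     # ch x (8^3)
    bott_feats[[i]] <- matrix(fw$bottleneck, nrow = cfg$bottleneck_channels)
  }
  n_bott_pos <- ncol(bott_feats[[1]])
  total <- n_sub * n_bott_pos
  with_seed(seed, {
    replace <- total < n
    if (replace) warning("fewer patches than requested; sampling with ",
                         "replacement")
    pick <- sample(total, n, replace = replace)
    sub <- (pick - 1) %/% n_bott_pos + 1
    pos <- (pick - 1) %% n_bott_pos + 1
    layer_summary <- function(feat_list, positions) {
      F <- t(vapply(seq_len(n), function(j)
        feat_list[[sub[j]]][, positions[j]],
        numeric(nrow(feat_list[[1]]))))
      pr <- prcomp(F, rank. = pca_dim)
      cl <- kmeans(pr$x, centers = min(k, nrow(unique(pr$x))), nstart = 5)
      list(projection = pr$x, pseudolabel = cl$cluster,
           tertile = tert[sub], subject = sub)
    }
    bott <- layer_summary(bott_feats, pos)
    # parent positions in the encoder grid (2x finer): take the first child
    bd <- 4L  # bottleneck spatial edge
    ed <- bd * 2L
    bx <- (pos - 1) %% bd
    by <- ((pos - 1) %/% bd) %% bd
    bz <- (pos - 1) %/% (bd * bd)
    parent <- (2 * bx) + ed * ((2 * by) + ed * (2 * bz)) + 1
    enc <- layer_summary(enc_feats, parent)
    enc$backprojection <- bott$pseudolabel
    list(bottleneck = bott, encoder = enc, k = k, pca_dim = pca_dim)
  })
}
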