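# A hand-wired model whose cognition output reads exactly one 4^3 input
# block: encoder convs pass the input through on channel 1 (centre-tap
# identity), pools take block maxima, and the cognition head weights the
# single bottleneck cell `cell` (1-based, within the 4^3 grid).
single_block_reader <- function(cell, input_size = 16) {
  cfg <- unet_config(input_size = input_size, depth = 2)
  m <- build_unet(cfg, seed = 1)
  for (nm in names(m$params)) m$params[[nm]][] <- 0
  centre <- 13  # offset (0,0,0) among the 27, 0-based k = 13
  m$params$enc1_a_W[1, 14] <- 1            # channel 1 <- input (centre tap)
  m$params$enc1_b_W[1, 13 * 16 + 1] <- 1   # channel 1 <- channel 1
  m$params$enc2_a_W[1, 13 * 16 + 1] <- 1
  m$params$enc2_b_W[1, 13 * 32 + 1] <- 1
  m$params$bott_a_W[1, 13 * 32 + 1] <- 1
  m$params$bott_b_W[1, 13 * 128 + 1] <- 1
  feat <- (cell - 1) * 128 + 1             # flatten order: channel fastest
  m$params$fc1_W[1, feat] <- 1
  m$params$fc2_W[1, 1] <- 1
  m$params$head_cog_W[1, 1] <- 1
  m
}

test_that("occlusion scores appear exactly on patches reading the model's region", {
  cell <- 1 + 1 + 4 * 1 + 16 * 1  # bottleneck cell (2,2,2) 1-based
  m <- single_block_reader(cell)
  vol <- array(1, dim = rep(16, 3))  # positive everywhere; ReLU transparent
  res <- occlusion_map(m, vol, target = unet_forward(m, vol)$cognition,
                       patch = 4, stride = 4, fill = 0)
  # the receptive block of cell (2,2,2) is input voxels 5..8 on each axis
  nz <- which(res$score > 0, arr.ind = TRUE)
  expect_true(nrow(nz) > 0)
  expect_true(all(nz >= 5 & nz <= 8))
  # occluding with the original values is a no-op
  res2 <- occlusion_map(m, vol, target = 10, patch = 4, stride = 4, fill = 1)
  expect_true(all(res2$score == 0))
  # constant-head model: all-zero map
  cm <- constant_head_model(16)
  res3 <- occlusion_map(cm, array(rnorm(16^3), rep(16, 3)), target = 10,
                        patch = 4, stride = 4)
  expect_true(all(res3$score == 0))
  expect_error(occlusion_map(m, vol, 10, patch = 32), "larger")
})

test_that("cohort aggregation normalizes to the ceiling and averages", {
  m1 <- array(runif(4^3), rep(4, 3))
  m2 <- array(runif(4^3, 0, 2), rep(4, 3))
  agg <- aggregate_occlusion(list(m1, m2))
  expect_equal(max(vapply(agg$maps_scaled, max, numeric(1))), 10)
  expect_equal(agg$mean_map,
               (agg$maps_scaled[[1]] + agg$maps_scaled[[2]]) / 2)
  one <- aggregate_occlusion(list(m1))
  expect_equal(max(one$mean_map), 10)
  zz <- aggregate_occlusion(list(array(0, rep(4, 3))))
  expect_true(all(zz$mean_map == 0))
  expect_error(aggregate_occlusion(list()), "empty")
})

test_that("atlas averaging matches hand-computed region means", {
  map <- array(0, rep(4, 3))
  atlas <- array(0L, rep(4, 3))
  atlas[1:32] <- 1L
  atlas[33:48] <- 2L
  map[1:32] <- 2
  map[33:48] <- c(rep(1, 8), rep(5, 8))
  av <- atlas_average(map, atlas)
  expect_equal(av$mean_score[av$region == 1], 2)
  expect_equal(av$mean_score[av$region == 2], 3)
  expect_equal(av$n_voxels, c(32, 16))
  uni <- atlas_average(array(7, rep(4, 3)), array(1L, rep(4, 3)))
  expect_equal(uni$mean_score, 7)
  expect_error(atlas_average(map, atlas[1:2, , ]), "same grid")
  expect_error(atlas_average(map, array(0L, rep(4, 3))), "region")
})

test_that("permutation importance isolates informative features", {
  set.seed(20)
  n <- 250
  X <- cbind(age = rnorm(n, 70, 8), education = rnorm(n, 16, 2),
             dead = rep(1, n))
  y <- 3 * X[, "age"] + rnorm(n, 0, 3)
  fit <- fit_tabular(X, y, task = "cognition_mse", seed = 3)
  imp <- permutation_importance(fit, X, y, n_iter = 25, seed = 4)
  expect_equal(dim(imp), c(3L, 25L))
  expect_true(all(imp["dead", ] == 0))         # constant feature: exact zero
  med <- apply(imp, 1, median)
  expect_equal(names(which.max(med)), "age")
  # stochastic stability: medians agree across seeds within noise
  imp2 <- permutation_importance(fit, X, y, n_iter = 25, seed = 5)
  expect_lt(max(abs(apply(imp2, 1, median) - med)), 0.05)
})

test_that("duplicating a feature splits its importance", {
  set.seed(21)
  n <- 300
  X <- cbind(sig = rnorm(n), noise = rnorm(n))
  y <- 2 * X[, "sig"] + rnorm(n, 0, 0.5)
  f1 <- fit_tabular(X, y, task = "cognition_mse", seed = 6)
  base_med <- median(permutation_importance(f1, X, y, seed = 7)["sig", ])
  X2 <- cbind(X, sig_copy = X[, "sig"])
  f2 <- fit_tabular(X2, y, task = "cognition_mse", seed = 6)
  imp2 <- apply(permutation_importance(f2, X2, y, seed = 7), 1, median)
  expect_lte(imp2[["sig"]], base_med + 0.02)
  expect_lte(imp2[["sig_copy"]], base_med + 0.02)
})

test_that("inclusion importance is a plain difference with free sign", {
  expect_equal(inclusion_importance(0.83, 0.31), 0.52)
  expect_equal(inclusion_importance(0.4, 0.4), 0)
  expect_lt(inclusion_importance(0.2, 0.31), 0)
})

test_that("receptive-field summary clusters and projects across layers", {
  co <- cohort16()
  m <- build_unet(unet_config(input_size = 16, depth = 2), seed = 8)
  vols <- lapply(co$volumes[1:10], voxcog:::.norm_arr)
  scores <- co$records$adas0[1:10]
  rf <- receptive_field_summary(m, vols, scores, n = 100, seed = 9)
  expect_length(rf$bottleneck$pseudolabel, 100)
  expect_equal(ncol(rf$bottleneck$projection), 3)
  expect_length(rf$encoder$backprojection, 100)
  expect_setequal(levels(rf$bottleneck$tertile), c("low", "medium", "high"))
  # untrained network: pseudolabels do not align with cognition tertiles
  ari <- mclust::adjustedRandIndex(rf$bottleneck$pseudolabel,
                                   rf$bottleneck$tertile)
  expect_lt(abs(ari), 0.25)
  # k = 1 collapses to a single pseudolabel
  rf1 <- receptive_field_summary(m, vols, scores, n = 50, k = 1, seed = 9)
  expect_equal(unique(rf1$bottleneck$pseudolabel), 1L)
  expect_warning(
    receptive_field_summary(m, vols[1:2], scores[1:2], n = 500, seed = 9),
    "replacement")
})

test_that("a trained model's bottleneck clusters align with cognition better than chance", {
  st <- trained_study()
  rows <- match(split_ids(st$plan, 1)$train[1:60], st$dataset$subject_id)
  vols <- lapply(st$dataset$volumes[rows], voxcog:::.norm_arr)
  scores <- st$dataset$targets$cog[rows]
  rf_tr <- receptive_field_summary(st$fit$model, vols, scores, n = 200,
                                   seed = 10)
  un <- build_unet(st$fit$model$config, seed = 77)
  rf_un <- receptive_field_summary(un, vols, scores, n = 200, seed = 10)
  ari_tr <- mclust::adjustedRandIndex(rf_tr$bottleneck$pseudolabel,
                                      rf_tr$bottleneck$tertile)
  ari_un <- mclust::adjustedRandIndex(rf_un$bottleneck$pseudolabel,
                                      rf_un$bottleneck$tertile)
  expect_gt(ari_tr, ari_un)
})
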