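test_that("tissue volumes are voxel counts times voxel volume", {
  lab <- array(0L, dim = c(10, 10, 2))
  lab[1:100] <- 1L
  lab[101:180] <- 2L
  lab[181:200] <- 3L
  expect_equal(tissue_volumes(lab),
               c(V_GM = 100, V_WM = 80, V_CSF = 20))
  expect_equal(unname(tissue_volumes(lab, c(1, 1, 1.2))[1]), 120)
  lab2 <- lab; lab2[lab2 == 2L] <- 0L
  expect_equal(unname(tissue_volumes(lab2)["V_WM"]), 0)
  perm <- array(sample(as.integer(lab)), dim = dim(lab))
  expect_equal(tissue_volumes(perm), tissue_volumes(lab))
})

test_that("z-scores are computed against a training-fold control reference", {
  set.seed(2)
  ctrl <- matrix(rnorm(60, c(5000, 7000, 3000), 100), ncol = 3, byrow = TRUE)
  colnames(ctrl) <- c("V_GM", "V_WM", "V_CSF")
  ref <- control_reference(ctrl, subject_ids = sprintf("C%02d", 1:20))
  expect_equal(unname(zscore_volumes(ref$mean, ref)), c(0, 0, 0))
  expect_equal(unname(zscore_volumes(ref$mean - ref$sd, ref)), c(-1, -1, -1))
  expect_length(ref$subject_ids, 20)
  expect_error(control_reference(ctrl[1, , drop = FALSE]), "control")
  cc <- ctrl; cc[, 1] <- 5000
  expect_error(control_reference(cc), "sd")
})

test_that("feature assembly one-hot encodes and excludes outcomes", {
  rec <- data.frame(subject_id = c("a", "b", "c"),
                    age = c(70, 75, 80), sex = c("F", "m", "M"),
                    education = c(16, 12, 20),
                    marital = c("Married", "divorced", "widowed"),
                    diagnosis = c("CN", "MCI", "AD"),
                    adas0 = c(5, 10, 20))
  expect_warning(fx <- assemble_features(rec), "widowed")
  expect_equal(unname(rowSums(fx$X[, c("sex_F", "sex_M")])), rep(1, 3))
  expect_equal(unname(rowSums(fx$X[, grep("marital", colnames(fx$X))])),
               rep(1, 3))
  expect_equal(unname(fx$X[3, "marital_other"]), 1)
  expect_false(any(grepl("adas|diag|subject", colnames(fx$X))))
  expect_equal(fx$subject_ids, rec$subject_id)
})

test_that("the boosted regressor learns signal and ignores noise", {
  set.seed(8)
  n <- 200
  X <- cbind(age = rnorm(n, 70, 8), education = rnorm(n, 16, 2),
             junk = rnorm(n))
  y_lin <- 2 * X[, "age"] + rnorm(n, 0, 0.5)
  fit <- fit_tabular(X, y_lin, task = "cognition_mse", seed = 1)
  expect_gt(r_squared(predict(fit, X), y_lin), 0.95)
  y_noise <- rnorm(n)
  expect_lte(cv_tabular(X, y_noise, task = "cognition_mse", seed = 1)$r2, 0.1)
  expect_warning(fitc <- fit_tabular(X, rep(3, n), task = "cognition_mse"),
                 "constant")
  expect_equal(predict(fitc, X), rep(3, n))
  expect_error(fit_tabular(X[1:10, ], y_lin[1:10]), "20")
  # determinism under a fixed seed
  f1 <- fit_tabular(X, y_lin, task = "cognition_gamma", seed = 9)
  f2 <- fit_tabular(X, y_lin, task = "cognition_gamma", seed = 9)
  expect_equal(predict(f1, X), predict(f2, X))
})

test_that("gamma-objective boosting stays positive and tracks skewed targets", {
  set.seed(10)
  n <- 300
  x <- rnorm(n)
  y <- pmax(rgamma(n, 2, scale = 4) + 2 * x, 0.1)
  X <- cbind(x = x, noise = rnorm(n))
  fit <- fit_tabular(X, y, task = "cognition_gamma", seed = 2)
  p <- predict(fit, X)
  expect_true(all(p > 0))
  expect_gt(cor(p, y), 0.4)
})

test_that("ensemble weights normalize published-style R2 values", {
  w <- compute_ensemble_weights(0.72, 0.31)
  expect_equal(w$w_im, 0.72 / 1.03, tolerance = 1e-12)
  expect_equal(w$w_nim, 0.31 / 1.03, tolerance = 1e-12)
  expect_equal(compute_ensemble_weights(0.4, 0.4)$w_im, 0.5)
  expect_equal(compute_ensemble_weights(0.5, 0)$w_im, 1)
  expect_equal(compute_ensemble_weights(0.5, -0.3)$w_nim, 0)
  w2 <- compute_ensemble_weights(0.1 * 0.72, 0.1 * 0.31)
  expect_equal(w2$w_im, w$w_im)
  expect_error(compute_ensemble_weights(-0.1, 0), "informative")
})

test_that("ensemble prediction is a convex combination aligned by subject", {
  w <- compute_ensemble_weights(0.6, 0.3)
  a <- c(s1 = 10, s2 = 20)
  b <- c(s1 = 16, s2 = 14)
  comb <- ensemble_predict(a, b, w)
  expect_true(all(comb >= pmin(a, b) & comb <= pmax(a, b)))
  expect_equal(ensemble_predict(a, a, w), a)
  w0 <- compute_ensemble_weights(0.6, 0)
  expect_equal(ensemble_predict(a, b, w0), a)
  names(b) <- c("s2", "s1")
  expect_error(ensemble_predict(a, b, w), "misaligned")
  expect_error(ensemble_predict(a, b[1], w), "misaligned")
})

test_that("ensembling does not lose much against the best module", {
  st <- trained_study()
  ds <- st$dataset
  rec <- st$cohort$records
  ids <- split_ids(st$plan, 1)
  tr <- match(ids$train, ds$subject_id)
  te <- st$test_rows
  vols <- t(vapply(st$cohort$labels, tissue_volumes, numeric(3)))
  fx <- assemble_features(rec, volumes = vols)
  y <- ds$targets$cog
  cvt <- cv_tabular(fx$X[tr, ], y[tr], task = "cognition_gamma", seed = 1)
  tabm <- fit_tabular(fx$X[tr, ], y[tr], task = "cognition_gamma",
                      gamma_params = st$fit$gamma_params, seed = 1)
  w <- compute_ensemble_weights(r2_im = max(st$fit$metrics$cog_r2, 1e-3),
                                r2_nim = max(cvt$r2, 1e-3))
  im_te <- st$test_preds$cognition
  nim_te <- predict(tabm, fx$X[te, ])
  ens <- ensemble_predict(im_te, nim_te, w)
  r2_ens <- r_squared(ens, y[te])
  r2_best <- max(r_squared(im_te, y[te]), r_squared(nim_te, y[te]))
  expect_gte(r2_ens, r2_best - 0.05)
})

test_that("ensemble retraining logs the exact weighted loss and respects freezes", {
  st <- trained_study()
  ds <- st$dataset
  ids <- split_ids(st$plan, 1)
  tr <- match(ids$train, ds$subject_id)[1:30]
  vols <- t(vapply(st$cohort$labels, tissue_volumes, numeric(3)))
  fx <- assemble_features(st$cohort$records, volumes = vols)
  tabm <- fit_tabular(fx$X[tr, ], ds$targets$cog[tr],
                      task = "cognition_gamma",
                      gamma_params = st$fit$gamma_params, seed = 1)
  w <- compute_ensemble_weights(0.6, 0.3)
  out <- ensemble_retrain(st$fit$model, tabm, w, ds, fx$X, tr,
                          st$fit$gamma_params, st$fit$tab_stats,
                          train_config(finetune_epochs = 1, seed = 3))
  lg <- out$log
  expect_equal(lg$ensemble_loss,
               ensemble_loss(lg$l_im, lg$l_nim, w$r2_im, w$r2_nim))
  # the expanding arm stayed frozen
  for (nm in grep("^dec|^final", names(out$model$params), value = TRUE))
    expect_identical(out$model$params[[nm]], st$fit$model$params[[nm]])
  # with zero tabular weight the tabular model is untouched
  w_im_only <- compute_ensemble_weights(0.6, 0)
  out2 <- ensemble_retrain(st$fit$model, tabm, w_im_only, ds, fx$X, tr,
                           st$fit$gamma_params, st$fit$tab_stats,
                           train_config(finetune_epochs = 1, seed = 3))
  expect_identical(out2$tab_model, tabm)
})
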