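test_that("configuration invariants force the 4^3 bottleneck", {
  expect_error(unet_config(input_size = 48), class = "voxcog_config_error")
  expect_error(unet_config(input_size = 32, depth = 4),
               class = "voxcog_config_error")
  cfg <- unet_config(input_size = 16, depth = 2)
  expect_equal(cfg$flat_len, 8192)
  expect_equal(cfg$enc_channels, c(16L, 32L))
})

test_that("parameter count matches the closed-form architecture arithmetic", {
  count_for <- function(input_size, depth, n_tab = 0) {
    ch <- pmin(16 * 2^(seq_len(depth) - 1), 128)
    n <- 0; cin <- 1
    for (i in seq_len(depth)) {
      n <- n + ch[i] * 27 * cin + ch[i] + ch[i] * 27 * ch[i] + ch[i]
      cin <- ch[i]
    }
    n <- n + 128 * 27 * cin + 128 + 128 * 27 * 128 + 128
    prev <- 128
    for (i in rev(seq_len(depth))) {
      n <- n + 8 * ch[i] * prev + ch[i] +            # upconv
        ch[i] * 27 * 2 * ch[i] + ch[i] +             # conv a on concat
        ch[i] * 27 * ch[i] + ch[i]                   # conv b
      prev <- ch[i]
    }
    n <- n + 4 * ch[1] + 4                           # final 1x1x1
    n + 256 * (8192 + n_tab) + 256 + 64 * 256 + 64 + 3 * (64 + 1)
  }
  m64 <- build_unet(unet_config(input_size = 64, depth = 4), seed = 1)
  expect_equal(n_parameters(m64), count_for(64, 4))
  m32 <- build_unet(unet_config(input_size = 32, n_tabular = 7), seed = 1)
  expect_equal(n_parameters(m32), count_for(32, 3, 7))
})

test_that("forward pass yields normalized segmentation and positive cognition", {
  m <- build_unet(unet_config(input_size = 16, depth = 2), seed = 2)
  vol <- array(rnorm(16^3), dim = rep(16, 3))
  fw <- unet_forward(m, vol)
  expect_equal(colSums(fw$seg_probs), rep(1, 16^3), tolerance = 1e-6)
  expect_gt(fw$cognition, 0)
  expect_true(fw$diag_prob > 0 && fw$diag_prob < 1)
  # determinism in evaluation
  fw2 <- unet_forward(m, vol)
  expect_identical(fw$cognition, fw2$cognition)
  expect_identical(fw$seg_probs, fw2$seg_probs)
  expect_error(unet_forward(m, array(0, rep(8, 3))), "resampled")
})

test_that("zeroed heads and dead tabular inputs behave as wired", {
  cfg <- unet_config(input_size = 16, depth = 2, n_tabular = 3)
  m <- build_unet(cfg, seed = 3)
  m$params$head_cog_W[] <- 0
  m$params$head_cog_b[] <- 0
  vol <- array(rnorm(16^3), dim = rep(16, 3))
  expect_equal(unet_forward(m, vol, tabular = rnorm(3))$cognition, log(2))
  # zero the tabular columns of fc1: permuting tabular inputs is a no-op
  m2 <- build_unet(cfg, seed = 4)
  m2$params$fc1_W[, 8192 + 1:3] <- 0
  tab <- c(1, 2, 3)
  a <- unet_forward(m2, vol, tabular = tab)
  b <- unet_forward(m2, vol, tabular = rev(tab))
  expect_identical(a$cognition, b$cognition)
  expect_identical(a$alpha, b$alpha)
  expect_error(unet_forward(m2, vol, tabular = 1:2), "tabular")
})

test_that("freeze policy freezes exactly the expanding arm and is an involution", {
  m <- build_unet(unet_config(input_size = 16, depth = 2), seed = 5)
  orig <- m$trainable
  mt <- apply_freeze_policy(m, "multitask")
  frozen <- names(mt$trainable)[!mt$trainable]
  expect_true(all(grepl("^dec|^final", frozen)))
  expect_true(all(grepl("^dec|^final", names(mt$trainable))
                  [!mt$trainable]))
  expect_false(any(mt$trainable[grepl("^dec|^final", names(mt$trainable))]))
  expect_true(all(mt$trainable[grepl("^enc|^bott|^fc|^head", names(mt$trainable))]))
  back <- apply_freeze_policy(mt, "seg_pretrain")
  expect_identical(back$trainable, orig)
})

test_that("bottleneck features are stable, sized 8192 and input-sensitive", {
  st <- trained_study()
  vol <- voxcog:::.norm_arr(st$dataset$volumes[[1]])
  b1 <- extract_bottleneck(st$fit$model, vol)
  expect_length(b1, 8192)
  expect_identical(b1, extract_bottleneck(st$fit$model, vol))
  # zeroing the hotspot region changes the representation of a trained model
  bbox <- st$cohort$ground_truth$hotspot_bbox
  vol2 <- vol
  vol2[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2], bbox[1, 3]:bbox[2, 3]] <- 0
  expect_gt(sum(abs(b1 - extract_bottleneck(st$fit$model, vol2))), 1e-3)
})

test_that("convolution is equivariant to x-flips for symmetric kernels", {
  d <- 8
  C <- 2
  X <- matrix(rnorm(C * d^3), C)
  # weights symmetric under dx -> -dx: average a random kernel with its flip
  W <- matrix(rnorm(3 * 27 * C), 3)
  k_of <- function(dx, dy, dz) (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:1) {
    k1 <- dx + 3 * dy + 9 * dz
    k2 <- (2 - dx) + 3 * dy + 9 * dz
    cols1 <- k1 * C + 1:C
    cols2 <- k2 * C + 1:C
    avg <- (W[, cols1] + W[, cols2]) / 2
    W[, cols1] <- avg
    W[, cols2] <- avg
  }
  arr <- array(X[1, ], dim = rep(d, 3))  # flip map on voxel order
  flip_idx <- as.numeric(array(seq_len(d^3), rep(d, 3))[d:1, , ])
  Xf <- X[, flip_idx, drop = FALSE]
  Y <- voxcog:::.cpp_conv3_fwd(X, W, rep(0, 3), d, d, d)
  Yf <- voxcog:::.cpp_conv3_fwd(Xf, W, rep(0, 3), d, d, d)
  expect_equal(Yf, Y[, flip_idx], tolerance = 1e-5)
})

test_that("checkpoints round-trip through disk", {
  m <- build_unet(unet_config(input_size = 16, depth = 2), seed = 6)
  p <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_model(m, p)
  back <- load_model(p)
  vol <- array(rnorm(16^3), dim = rep(16, 3))
  expect_identical(unet_forward(back, vol)$cognition,
                   unet_forward(m, vol)$cognition)
  expect_error(load_model(file.path(tempdir(), "nope.rds")), "not found")
})
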