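test_that("MSE cognition and alpha losses are exact and invariant", {
  expect_equal(mse_cognition_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_cognition_loss(c(0, 0), c(3, 4)), 12.5)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(mse_cognition_loss(x + 5, y + 5), mse_cognition_loss(x, y))
  expect_error(mse_cognition_loss(1:3, 1:2), "mismatch")
  expect_equal(alpha_loss(0, 0.1), 0.01)
  expect_equal(alpha_loss(x, y), alpha_loss(y, x))
})

test_that("gamma loss has the stated closed forms and limits", {
  gp <- gamma_loss_params(sigma = 5, gamma = 9)
  expect_equal(gamma_loss(9, 9, gp), 1)
  expect_error(gamma_loss(c(1, -1), c(1, 1), gp), "positive")
  # prior-only limit: minimizer tends to gamma as sigma grows
  grid <- seq(0.01, 50, by = 1e-3)
  gp_inf <- gamma_loss_params(sigma = 1e6, gamma = 7)
  vals <- vapply(grid, function(y) gamma_loss(y, 20, gp_inf), numeric(1))
  expect_lt(abs(grid[which.min(vals)] - 7), 1e-2)
  # likelihood-dominates limit: minimizer tends to the empirical score
  gp_0 <- gamma_loss_params(sigma = 1e-3, gamma = 7)
  vals <- vapply(grid, function(y) gamma_loss(y, 20, gp_0), numeric(1))
  expect_lt(abs(grid[which.min(vals)] - 20), 1e-2)
})

test_that("gamma parameter estimation is fold-local MLE with measurement sigma", {
  set.seed(5)
  draws <- rgamma(1e5, shape = 2, scale = 5)
  gp <- estimate_gamma_params(draws)
  expect_lt(abs(gp$gamma - 5) / 5, 0.02)
  expect_equal(gp$sigma, adas_measurement_sd())
  expect_equal(estimate_gamma_params(draws, sigma = "sd")$sigma, sd(draws))
  expect_error(estimate_gamma_params(rep(4, 10), sigma = "sd"), "constant")
  expect_error(estimate_gamma_params(rep(0, 10)), "mean")
  gp2 <- estimate_gamma_params(draws[1:100], subject_ids = sprintf("S%d", 1:100))
  expect_length(gp2$subject_ids, 100)
})

test_that("boosting gradient is stationary at the minimizer and hessian floored", {
  gp <- gamma_loss_params(sigma = 4, gamma = 6)
  root <- uniroot(function(y) (y - 15) / 16 - 1 / y + 1 / 6, c(1e-6, 100),
                  tol = 1e-14)$root
  gh <- gamma_loss_grad_hess(log(root), 15, gp)
  expect_lt(abs(gh$grad), 1e-9)
  # floor: far below the empirical score the analytic hessian is negative
  gh_low <- gamma_loss_grad_hess(log(1), 100, gp)
  expect_gte(gh_low$hess, 1e-6)
  f <- seq(-3, 4, length.out = 50)
  expect_true(all(gamma_loss_grad_hess(f, rep(20, 50), gp)$hess >= 1e-6))
})

test_that("segmentation cross entropy behaves like a proper score", {
  lab <- array(sample(0:3, 4^3, TRUE), dim = c(4, 4, 4))
  t <- voxcog:::as_prob4(lab)
  expect_equal(segmentation_ce_loss(t, lab), 0)
  expect_equal(segmentation_ce_loss(matrix(0.25, 4, ncol(t)), t), log(4))
  # moving mass toward the true class lowers the loss
  p1 <- 0.7 * t + 0.3 * 0.25
  p2 <- 0.4 * t + 0.6 * 0.25
  expect_lt(segmentation_ce_loss(p1, t), segmentation_ce_loss(p2, t))
  expect_warning(
    segmentation_ce_loss(voxcog:::as_prob4(1 - (lab > 0)), t), "clamping")
})

test_that("weighted Dice matches hand counts and its symmetries", {
  lab <- array(sample(0:3, 5^3, TRUE), dim = c(5, 5, 5))
  expect_equal(weighted_dice(lab, lab), 1)
  a <- rbind(1, 0, 0, 0)[, rep(1, 6)]
  b <- rbind(0, 1, 0, 0)[, rep(1, 6)]
  expect_equal(weighted_dice(a, b), 0)
  pA <- c(1, 0, 0, 0); tA <- c(1, 1, 0, 0)
  p <- rbind(pA, 1 - pA, 0, 0)
  t <- rbind(tA, 1 - tA, 0, 0)
  expect_equal(weighted_dice(p, t), 2 * (1 + 2) / (3 + 5))
  expect_equal(weighted_dice(p, t), weighted_dice(t, p))
  w <- c(2, 1, 3, 1)
  expect_equal(weighted_dice(p, t, w), weighted_dice(p, t, 10 * w))
  expect_error(weighted_dice(numeric(0), numeric(0)), "empty")
  pc <- per_class_dice(lab, lab)
  expect_equal(unname(pc[c(1, 2)]), c(1, 1))
})

test_that("diagnosis log loss matches hand arithmetic", {
  expect_equal(diagnosis_logloss(0.5, 1), log(2))
  expect_equal(diagnosis_logloss(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2)
  expect_lt(diagnosis_logloss(c(1, 0), c(1, 0)), 1e-10)
})

test_that("multitask and ensemble losses combine linearly", {
  w <- multitask_weights()
  expect_equal(multitask_loss(0, 0, 0, 0, w), 0)
  expect_equal(multitask_loss(2, 2, 4, 4, w), 4)
  w2 <- multitask_weights(1, 1, 0.5, 0.5)
  expect_equal(multitask_loss(2, 2, 4, 4, w2),
               2 * multitask_loss(2, 2, 4, 4, w))
  expect_error(multitask_weights(0, 0, 0, 0), "not all zero")
  expect_error(multitask_loss(Inf, 0, 0, 0), "finite")
  expect_equal(ensemble_loss(1, 2, 0.72, 0.31), 0.72 + 0.62)
  expect_equal(ensemble_loss(3, 5, 0.4, 0.4), 0.4 * 8)
  expect_equal(ensemble_loss(3, 5, 0.6, 0), 1.8)
  expect_error(ensemble_loss(1, 1, -0.2, 0), "informative")
})
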