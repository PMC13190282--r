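test_that("cohorts are bit-identical under a fixed configuration", {
  cfg <- phantom_config(grid_size = 16, n_subjects = 4, seed = 3)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("configuration contract is enforced", {
  expect_error(phantom_config(grid_size = 15), class = "voxcog_config_error")
  expect_error(phantom_config(grid_size = 24), class = "voxcog_config_error")
  expect_error(phantom_config(severity_scale = 0),
               class = "voxcog_config_error")
  expect_error(phantom_config(noise_sd_intensity = -1),
               class = "voxcog_config_error")
  expect_error(phantom_config(visit_months = c(6, 12)),
               class = "voxcog_config_error")
})

test_that("young controls have zero atrophy and the template GM fraction", {
  yo <- generate_cohort(phantom_config(grid_size = 16, n_subjects = 8,
                                       seed = 5, young_control = TRUE))
  expect_true(all(yo$records$severity == 0))
  expect_true(all(yo$records$gm_count == yo$ground_truth$template_gm_count))
  expect_true(all(is.na(yo$records$adas0)))
  expect_null(yo$adas_series)
})

test_that("severity draws follow the shape-2 density with mean 2*scale", {
  set.seed(9)
  co <- generate_cohort(phantom_config(grid_size = 16, n_subjects = 10000,
                                       seed = 17, severity_scale = 5,
                                       make_images = FALSE))
  expect_lt(abs(mean(co$records$severity) - 10) / 10, 0.02)
})

test_that("GM voxel count decreases strictly with severity on a fixed template", {
  counts <- vapply(c(0, 0.5, 1, 2, 5, 10, 20, 30), function(s)
    sum(voxcog:::.phantom_subject_labels(32, rep(16.5, 3), 0.62, s,
                                         0.15, 5)$lab == 1L), numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("severity and baseline cognition are strongly coupled at low noise", {
  co <- generate_cohort(phantom_config(grid_size = 16, n_subjects = 500,
                                       seed = 23, adas_meas_sd = 1,
                                       make_images = FALSE))
  expect_gt(cor(co$records$severity, co$records$adas0), 0.9)
})

test_that("diagnosis bands partition severity at the stated cutoffs", {
  co <- labels_cohort()
  r <- co$records
  expect_true(all(r$diagnosis[r$severity < 5] == "CN"))
  expect_true(all(r$diagnosis[r$severity >= 5 & r$severity < 15] == "MCI"))
  expect_true(all(r$diagnosis[r$severity >= 15] == "AD"))
  expect_true(all(c("CN", "MCI", "AD") %in% r$diagnosis))
})

test_that("trajectories of non-improving MCI/AD subjects worsen on average", {
  co <- labels_cohort()
  r <- co$records
  sel <- r$diagnosis %in% c("MCI", "AD") & r$alpha_true >= 0
  ser <- co$adas_series[co$adas_series$subject_id %in% r$subject_id[sel], ]
  last <- ser[ser$month == max(ser$month), ]
  base <- ser[ser$month == 0, ]
  stopifnot(identical(last$subject_id, base$subject_id))
  expect_gt(mean(last$adas - base$adas), 0)
  expect_gt(mean(last$adas >= base$adas), 0.9)
})

test_that("baseline cognition marginal is Gamma-shaped (KS check)", {
  co <- labels_cohort(5000, seed = 31)
  y <- co$records$adas0
  gp <- estimate_gamma_params(y)
  expect_lt(ks_distance_to_gamma(y, gp$gamma), 0.05)
})

test_that("KS distance has the right limits and single-atom arithmetic", {
  # samples placed exactly at reference-CDF inverse of a uniform grid
  for (n in c(100, 1000, 10000)) {
    q <- qgamma((seq_len(n) - 0.5) / n, shape = 2, scale = 5)
    d <- ks_distance_to_gamma(q, 5)
    expect_lt(d, 1 / n)
  }
  # constant samples: D = max(F(c), 1 - F(c)), one ECDF atom
  f5 <- pgamma(5, 2, scale = 5)
  expect_equal(ks_distance_to_gamma(rep(5, 50), 5), max(f5, 1 - f5))
  expect_error(ks_distance_to_gamma(numeric(0), 5), "empty")
  expect_error(ks_distance_to_gamma(rep(1, 5), 5), "at least 10")
})

test_that("cohort round-trips through the on-disk layout", {
  co <- generate_cohort(phantom_config(grid_size = 16, n_subjects = 3,
                                       seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_cohort(dir)
  expect_equal(back$records$subject_id, co$records$subject_id)
  expect_equal(back$labels[[2]], co$labels[[2]])
  expect_equal(back$volumes[[1]]$values, co$volumes[[1]]$values,
               tolerance = 1e-6)
  expect_equal(back$records$adas0, co$records$adas0, tolerance = 1e-6)
})
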