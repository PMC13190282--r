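# Shared fixtures, built in code and memoised across test files.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# small imaged cohort at 16^3 for fast module tests
cohort16 <- function() memo("cohort16", {
  generate_cohort(phantom_config(grid_size = 16, n_subjects = 24, seed = 7))
})

# tabular-only cohort (no image synthesis) for statistical tests
labels_cohort <- function(n = 500, seed = 21) {
  memo(paste0("labels", n, "_", seed), {
    generate_cohort(phantom_config(grid_size = 32, n_subjects = n,
                                   seed = seed, make_images = FALSE))
  })
}

# model whose scalar heads are constant in the input (image ignored)
constant_head_model <- function(input_size = 32, n_tabular = 0) {
  m <- build_unet(unet_config(input_size = input_size,
                              n_tabular = n_tabular), seed = 99)
  m$params$fc1_W[] <- 0
  m$params$fc1_b[] <- 0
  m
}
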