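#' Multitask 3D UNet configuration
#'
#' Encoder-decoder with a contracting path of `depth` blocks (two 3x3x3
#' convolutions with padding 1, each followed by ReLU, then 2x2x2 max
#' pooling), a 128-channel bottleneck at fixed 4^3 spatial size, an expanding
#' path of 2x2x2 up-convolutions plus skip concatenations, and a final 1x1x1
#' convolution to 4 channels (3 tissue classes + background) with per-voxel
#' soft-max. The bottleneck is flattened into a feature vector of length
#' 8192 (= 128 * 4^3), optionally concatenated with tabular demographics,
#' and passed through three fully connected layers to the scalar heads:
#' cognition (softplus, so predictions stay positive for the Gamma loss),
#' decline rate (linear) and diagnosis (sigmoid).
#'
#' @param input_size voxels per axis; `input_size / 2^depth` must equal 4.
#' @param depth number of pooling levels (default `log2(input_size / 4)`:
#'   4 at 64^3, 3 at 32^3).
#' @param base_channels channels of the first encoder block; doubled at each
#'   level (default 16, giving 16-32-64-128).
#' @param bottleneck_channels fixed at 128 so the flattened feature length is
#'   8192.
#' @param fc_widths widths of the two hidden fully connected layers.
#' @param n_tabular number of tabular inputs concatenated to the flattened
#'   bottleneck (0 for image-only models).
#' @param heads character subset of segmentation, cognition, alpha,
#'   diagnosis; at least one.
#' @return a `unet_config`.
#' @export
unet_config <- function(input_size = 32, depth = NULL, base_channels = 16,
                        bottleneck_channels = 128, fc_widths = c(256, 64),
                        n_tabular = 0,
                        heads = c("segmentation", "cognition", "alpha",
                                  "diagnosis")) {
  if (is.null(depth)) depth <- log2(input_size / 4)
  if (depth %% 1 != 0 || depth < 1)
    stop_config("input_size / 2^depth must be 4; got input ", input_size)
  depth <- as.integer(depth)
  if (input_size / 2^depth != 4)
    stop_config("input_size / 2^depth must be 4 (bottleneck fixed at 4^3); ",
                "got ", input_size, " / 2^", depth)
  heads <- match.arg(heads, several.ok = TRUE)
  if (length(heads) < 1) stop_config("at least one head must be enabled")
  enc_channels <- pmin(base_channels * 2^(seq_len(depth) - 1),
                       bottleneck_channels)
  flat_len <- bottleneck_channels * 4^3
  structure(list(input_size = as.integer(input_size), depth = depth,
                 enc_channels = as.integer(enc_channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 flat_len = as.integer(flat_len),
                 fc_widths = as.integer(fc_widths),
                 n_tabular = as.integer(n_tabular), heads = heads),
            class = "unet_config")
}

.he_init <- function(nout, nin) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

#' Build a multitask 3D UNet
#'
#' Initialises all parameters (He initialisation, zero biases) under the
#' given seed. The returned model is a plain parameter container; all
#' computation happens in [unet_forward].
#'
#' @param config a [unet_config].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `unet3d` with elements `config`, `params`
#'   (named list of matrices/vectors) and `trainable` (named logical).
#' @export
build_unet <- function(config, seed = 1) {
  stopifnot(inherits(config, "unet_config"))
  ch <- config$enc_channels
  depth <- config$depth
  cb <- config$bottleneck_channels
  with_seed(seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(depth)) {
      p[[paste0("enc", i, "_a_W")]] <- .he_init(ch[i], 27 * cin)
      p[[paste0("enc", i, "_a_b")]] <- numeric(ch[i])
      p[[paste0("enc", i, "_b_W")]] <- .he_init(ch[i], 27 * ch[i])
      p[[paste0("enc", i, "_b_b")]] <- numeric(ch[i])
      cin <- ch[i]
    }
    p[["bott_a_W"]] <- .he_init(cb, 27 * cin)
    p[["bott_a_b"]] <- numeric(cb)
    p[["bott_b_W"]] <- .he_init(cb, 27 * cb)
    p[["bott_b_b"]] <- numeric(cb)
    prev <- cb
    for (i in rev(seq_len(depth))) {
      p[[paste0("dec", i, "_up_W")]] <- .he_init(8 * ch[i], prev)
      p[[paste0("dec", i, "_up_b")]] <- numeric(ch[i])
      p[[paste0("dec", i, "_a_W")]] <- .he_init(ch[i], 27 * 2 * ch[i])
      p[[paste0("dec", i, "_a_b")]] <- numeric(ch[i])
      p[[paste0("dec", i, "_b_W")]] <- .he_init(ch[i], 27 * ch[i])
      p[[paste0("dec", i, "_b_b")]] <- numeric(ch[i])
      prev <- ch[i]
    }
    p[["final_W"]] <- .he_init(4, ch[1])
    p[["final_b"]] <- numeric(4)
    nin <- config$flat_len + config$n_tabular
    p[["fc1_W"]] <- .he_init(config$fc_widths[1], nin)
    p[["fc1_b"]] <- numeric(config$fc_widths[1])
    p[["fc2_W"]] <- .he_init(config$fc_widths[2], config$fc_widths[1])
    p[["fc2_b"]] <- numeric(config$fc_widths[2])
    for (hd in c("cog", "alpha", "diag")) {
      p[[paste0("head_", hd, "_W")]] <- .he_init(1, config$fc_widths[2])
      p[[paste0("head_", hd, "_b")]] <- numeric(1)
    }
    structure(list(config = config, params = p,
                   trainable = setNames(rep(TRUE, length(p)), names(p))),
              class = "unet3d")
  })
}

#' Number of model parameters
#' @param model a `unet3d`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

softmax4 <- function(L) {
  mx <- pmax(L[1, ], L[2, ], L[3, ], L[4, ])
  E <- exp(L - rep(mx, each = 4))
  E / rep(colSums(E), each = 4)
}

#' Forward pass of the multitask UNet
#'
#' Deterministic in evaluation; expects a volume already resampled to
#' `config$input_size` and intensity-normalised. The segmentation branch can
#' be skipped (`need_seg = FALSE`) when only scalar outputs are required,
#' e.g. during occlusion mapping.
#'
#' @param model a [build_unet] model.
#' @param volume [volume3d] or 3D array at the configured input size.
#' @param tabular numeric vector of length `config$n_tabular` (or NULL).
#' @param need_seg compute the decoder/segmentation branch.
#' @param keep_cache retain intermediate activations (for backprop).
#' @return list with `seg_probs` (4 x N matrix with a `vol_dim` attribute, or
#'   NULL), `cognition` (> 0), `alpha`, `diag_prob`, `bottleneck` (flattened
#'   feature vector of length 8192) and, if requested, `cache`.
#' @export
unet_forward <- function(model, volume, tabular = NULL, need_seg = TRUE,
                         keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  arr <- as_volume_array(volume)
  if (!all(dim(arr) == cfg$input_size))
    stop("volume must be resampled to ", cfg$input_size, "^3, got ",
         paste(dim(arr), collapse = "x"))
  if (cfg$n_tabular > 0) {
    if (is.null(tabular) || length(tabular) != cfg$n_tabular)
      stop("expected ", cfg$n_tabular, " tabular inputs")
  } else tabular <- numeric(0)
  depth <- cfg$depth
  g <- cfg$input_size
  cache <- list(dims = list(), skips = list(), relu_in = list(),
                pool_idx = list())
  cur <- matrix(as.numeric(arr), nrow = 1)
  dims <- c(g, g, g)
  for (i in seq_len(depth)) {
    xin <- cur
    a1 <- .cpp_conv3_fwd(xin, p[[paste0("enc", i, "_a_W")]],
                         p[[paste0("enc", i, "_a_b")]],
                         dims[1], dims[2], dims[3])
    r1 <- pmax(a1, 0)
    a2 <- .cpp_conv3_fwd(r1, p[[paste0("enc", i, "_b_W")]],
                         p[[paste0("enc", i, "_b_b")]],
                         dims[1], dims[2], dims[3])
    r2 <- pmax(a2, 0)
    pl <- .cpp_pool_fwd(r2, dims[1], dims[2], dims[3])
    cache$dims[[i]] <- dims
    cache$skips[[i]] <- r2
    cache$relu_in[[i]] <- list(x = xin, r1 = r1, m1 = a1 > 0, m2 = a2 > 0)
    cache$pool_idx[[i]] <- pl$idx
    cur <- pl$y
    dims <- dims %/% 2L
  }
  bx <- cur
  b1 <- .cpp_conv3_fwd(bx, p$bott_a_W, p$bott_a_b, dims[1], dims[2], dims[3])
  br1 <- pmax(b1, 0)
  b2 <- .cpp_conv3_fwd(br1, p$bott_b_W, p$bott_b_b, dims[1], dims[2], dims[3])
  br2 <- pmax(b2, 0)
  cache$bott <- list(x = bx, r1 = br1, m1 = b1 > 0, m2 = b2 > 0, dims = dims)
  flat <- as.numeric(br2)
  fcin <- c(flat, as.numeric(tabular))
  z1 <- as.numeric(p$fc1_W %*% fcin + p$fc1_b)
  h1 <- pmax(z1, 0)
  z2 <- as.numeric(p$fc2_W %*% h1 + p$fc2_b)
  h2 <- pmax(z2, 0)
  cog_raw <- as.numeric(p$head_cog_W %*% h2 + p$head_cog_b)
  alpha <- as.numeric(p$head_alpha_W %*% h2 + p$head_alpha_b)
  diag_raw <- as.numeric(p$head_diag_W %*% h2 + p$head_diag_b)
  cache$fc <- list(fcin = fcin, h1 = h1, m1 = z1 > 0, h2 = h2, m2 = z2 > 0,
                   cog_raw = cog_raw)

  seg <- NULL
  if (need_seg) {
    cur2 <- br2
    dcur <- dims
    dec_cache <- list()
    for (i in rev(seq_len(depth))) {
      up <- .cpp_upconv_fwd(cur2, p[[paste0("dec", i, "_up_W")]],
                            p[[paste0("dec", i, "_up_b")]],
                            dcur[1], dcur[2], dcur[3])
      dcur2 <- dcur * 2L
      catm <- rbind(up, cache$skips[[i]])
      a1 <- .cpp_conv3_fwd(catm, p[[paste0("dec", i, "_a_W")]],
                           p[[paste0("dec", i, "_a_b")]],
                           dcur2[1], dcur2[2], dcur2[3])
      r1 <- pmax(a1, 0)
      a2 <- .cpp_conv3_fwd(r1, p[[paste0("dec", i, "_b_W")]],
                           p[[paste0("dec", i, "_b_b")]],
                           dcur2[1], dcur2[2], dcur2[3])
      r2 <- pmax(a2, 0)
      dec_cache[[i]] <- list(xin = cur2, dims_low = dcur, catm = catm,
                             r1 = r1, m1 = a1 > 0, m2 = a2 > 0, out = r2)
      cur2 <- r2
      dcur <- dcur2
    }
    logits <- p$final_W %*% cur2 + p$final_b
    seg <- softmax4(logits)
    attr(seg, "vol_dim") <- c(g, g, g)
    cache$dec <- dec_cache
    cache$final_in <- cur2
    cache$seg_probs <- seg
  }
  # the decline-rate head is trained on a standardised target for
  # conditioning; de-standardise when the fitted scale is attached
  if (!is.null(model$alpha_stats))
    alpha <- alpha * model$alpha_stats$sd + model$alpha_stats$mean
  out <- list(seg_probs = seg, cognition = softplus(cog_raw), alpha = alpha,
              diag_prob = plogis(diag_raw), cog_raw = cog_raw,
              diag_raw = diag_raw, bottleneck = flat)
  if (keep_cache) out$cache <- cache
  out
}

#' Extract the flattened bottleneck feature vector
#'
#' Encoder-only forward pass returning the length-8192 representation of the
#' most spatially compressed block, used by the scalar heads and by the
#' interpretability module.
#'
#' @inheritParams unet_forward
#' @return numeric vector of length `config$flat_len`.
#' @export
extract_bottleneck <- function(model, volume) {
  unet_forward(model, volume, tabular = rep(0, model$config$n_tabular),
               need_seg = FALSE)$bottleneck
}

# Backward pass. `d_out` carries gradients at the output side:
#   d_cog (w.r.t. cognition after softplus), d_alpha, d_diag_raw (w.r.t. the
#   diagnosis logit) and d_seg_logits (4 x N, w.r.t. the pre-softmax logits).
# Returns a named gradient list congruent with model$params (decoder grads
# are present only when d_seg_logits is supplied).
unet_backward <- function(model, cache, d_out) {
  cfg <- model$config
  p <- model$params
  depth <- cfg$depth
  g <- list()
  fc <- cache$fc

  d_cog_raw <- (d_out$d_cog %||% 0) * plogis(fc$cog_raw)
  d_alpha <- d_out$d_alpha %||% 0
  # chain through the de-standardisation of the decline-rate head
  if (!is.null(model$alpha_stats)) d_alpha <- d_alpha * model$alpha_stats$sd
  d_diag_raw <- d_out$d_diag_raw %||% 0
  h2 <- fc$h2
  g$head_cog_W <- matrix(d_cog_raw * h2, nrow = 1)
  g$head_cog_b <- d_cog_raw
  g$head_alpha_W <- matrix(d_alpha * h2, nrow = 1)
  g$head_alpha_b <- d_alpha
  g$head_diag_W <- matrix(d_diag_raw * h2, nrow = 1)
  g$head_diag_b <- d_diag_raw
  d_h2 <- d_cog_raw * as.numeric(p$head_cog_W) +
    d_alpha * as.numeric(p$head_alpha_W) +
    d_diag_raw * as.numeric(p$head_diag_W)
  d_z2 <- d_h2 * fc$m2
  g$fc2_W <- outer(d_z2, fc$h1)
  g$fc2_b <- d_z2
  d_h1 <- as.numeric(crossprod(p$fc2_W, d_z2))
  d_z1 <- d_h1 * fc$m1
  g$fc1_W <- outer(d_z1, fc$fcin)
  g$fc1_b <- d_z1
  d_fcin <- as.numeric(crossprod(p$fc1_W, d_z1))
  bdims <- cache$bott$dims
  d_br2 <- matrix(d_fcin[seq_len(cfg$flat_len)], nrow = cfg$bottleneck_channels)

  skip_grads <- vector("list", depth)
  if (!is.null(d_out$d_seg_logits)) {
    dL <- d_out$d_seg_logits
    g$final_W <- dL %*% t(cache$final_in)
    g$final_b <- rowSums(dL)
    d_cur <- crossprod(p$final_W, dL)
    for (i in seq_len(depth)) {
      dc <- cache$dec[[i]]
      dlow <- dc$dims_low
      dhigh <- dlow * 2L
      d_a2 <- d_cur * dc$m2
      bw2 <- .cpp_conv3_bwd(dc$r1, p[[paste0("dec", i, "_b_W")]], d_a2,
                            dhigh[1], dhigh[2], dhigh[3])
      g[[paste0("dec", i, "_b_W")]] <- bw2$dW
      g[[paste0("dec", i, "_b_b")]] <- bw2$db
      d_a1 <- bw2$dX * dc$m1
      bw1 <- .cpp_conv3_bwd(dc$catm, p[[paste0("dec", i, "_a_W")]], d_a1,
                            dhigh[1], dhigh[2], dhigh[3])
      g[[paste0("dec", i, "_a_W")]] <- bw1$dW
      g[[paste0("dec", i, "_a_b")]] <- bw1$db
      ci <- cfg$enc_channels[i]
      d_up <- bw1$dX[seq_len(ci), , drop = FALSE]
      d_skip <- bw1$dX[ci + seq_len(ci), , drop = FALSE]
      skip_grads[[i]] <- d_skip
      uw <- .cpp_upconv_bwd(dc$xin, p[[paste0("dec", i, "_up_W")]], d_up,
                            dlow[1], dlow[2], dlow[3])
      g[[paste0("dec", i, "_up_W")]] <- uw$dW
      g[[paste0("dec", i, "_up_b")]] <- uw$db
      d_cur <- uw$dX
    }
    d_br2 <- d_br2 + d_cur
  }

  d_b2 <- d_br2 * cache$bott$m2
  bb <- .cpp_conv3_bwd(cache$bott$r1, p$bott_b_W, d_b2,
                       bdims[1], bdims[2], bdims[3])
  g$bott_b_W <- bb$dW
  g$bott_b_b <- bb$db
  d_b1 <- bb$dX * cache$bott$m1
  ba <- .cpp_conv3_bwd(cache$bott$x, p$bott_a_W, d_b1,
                       bdims[1], bdims[2], bdims[3])
  g$bott_a_W <- ba$dW
  g$bott_a_b <- ba$db
  d_pool <- ba$dX

  for (i in rev(seq_len(depth))) {
    dims <- cache$dims[[i]]
    n_full <- prod(dims)
    d_r2 <- .cpp_pool_bwd(d_pool, cache$pool_idx[[i]], n_full)
    if (!is.null(skip_grads[[i]]))
      d_r2 <- d_r2 + skip_grads[[i]]
    rc <- cache$relu_in[[i]]
    d_a2 <- d_r2 * rc$m2
    bw2 <- .cpp_conv3_bwd(rc$r1, p[[paste0("enc", i, "_b_W")]], d_a2,
                          dims[1], dims[2], dims[3])
    g[[paste0("enc", i, "_b_W")]] <- bw2$dW
    g[[paste0("enc", i, "_b_b")]] <- bw2$db
    d_a1 <- bw2$dX * rc$m1
    bw1 <- .cpp_conv3_bwd(rc$x, p[[paste0("enc", i, "_a_W")]], d_a1,
                          dims[1], dims[2], dims[3])
    g[[paste0("enc", i, "_a_W")]] <- bw1$dW
    g[[paste0("enc", i, "_a_b")]] <- bw1$db
    d_pool <- bw1$dX
  }
  g
}

#' Layer-freezing policy for the training phases
#'
#' During segmentation pretraining every layer is trainable. In the
#' multitask phase the expanding arm (up-convolutions, decoder convolutions
#' and the final 1x1x1 classifier), which serves only the segmentation task,
#' is frozen; the contracting arm and the fully connected layers remain
#' trainable.
#'
#' @param model a `unet3d`.
#' @param phase "seg_pretrain" or "multitask".
#' @return the model with its `trainable` flags updated.
#' @export
apply_freeze_policy <- function(model, phase = c("seg_pretrain", "multitask")) {
  phase <- match.arg(phase)
  nm <- names(model$params)
  if (phase == "seg_pretrain") {
    model$trainable[] <- TRUE
  } else {
    model$trainable[] <- TRUE
    frozen <- grepl("^dec[0-9]+_", nm) | grepl("^final_", nm)
    model$trainable[frozen] <- FALSE
  }
  model
}

#' Save / load a model checkpoint (config embedded)
#' @param model a `unet3d`; `path` an .rds file path.
#' @return the path, or the model on load.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  m <- readRDS(path)
  stopifnot(inherits(m, "unet3d"))
  m
}

#' Convert per-voxel class probabilities to a hard label map
#' @param prob 4 x N matrix with a `vol_dim` attribute (as returned in
#'   `seg_probs`), or a plain 4 x N matrix plus explicit `dims`.
#' @param dims optional length-3 grid dimensions.
#' @return 3D integer array with labels 0..3.
#' @export
prob_to_labels <- function(prob, dims = NULL) {
  dims <- dims %||% attr(prob, "vol_dim")
  lab <- max.col(t(prob)) - 1L
  array(as.integer(lab), dim = dims)
}
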