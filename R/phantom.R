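#' Phantom cohort configuration
#'
#' Settings for the seeded synthetic brain-phantom generator. The phantom
#' emulates the statistical structure the multitask framework assumes:
#' a three-tissue 3D head (background shell, CSF rim and ventricles, WM core,
#' GM ribbon), GM atrophy increasing with a latent severity, a right-skewed
#' (Gamma-shaped) baseline ADAS-Cog11 marginal driven by that severity, an
#' exponential longitudinal decline, and an optional young-control cohort
#' with zero atrophy used for segmentation pretraining.
#'
#' Severity `s` is drawn from the density p(s) proportional to
#' (s / scale) * exp(-s / scale), i.e. a shape-2 Gamma with the given scale,
#' so the baseline cognition marginal is Gamma-shaped. Diagnosis is assigned
#' by severity bands: s < scale is CN, scale <= s < 3*scale is MCI, else AD.
#'
#' @param grid_size voxels per axis; must be 4 times a power of two so the
#'   encoder can pool down to a 4^3 bottleneck (16, 32, 64, ...).
#' @param n_subjects number of subjects.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param severity_scale scale (score points) of the latent severity density.
#' @param noise_sd_intensity additive image noise, intensity units.
#' @param adas_meas_sd measurement noise on baseline cognition, score points.
#' @param hotspot_fraction fraction of GM designated cognition-informative;
#'   this contiguous subregion is eroded in proportion to severity and its
#'   location is recorded so attribution methods can be checked against
#'   ground truth.
#' @param young_control logical; TRUE yields a zero-atrophy cohort of young
#'   subjects without cognition labels (segmentation-pretraining analogue).
#' @param visit_months follow-up months of the longitudinal series
#'   (month 0 must be first).
#' @param longit_noise_sd multiplicative lognormal noise (sd of log) on
#'   follow-up scores.
#' @param make_images logical; FALSE skips image synthesis (labels and
#'   tabular records only), used for large tabular-only simulations.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid_size = 32, n_subjects = 100, seed = 1,
                           severity_scale = 5, noise_sd_intensity = 0.05,
                           adas_meas_sd = 2, hotspot_fraction = 0.15,
                           young_control = FALSE,
                           visit_months = c(0, 6, 12, 18, 24, 36),
                           longit_noise_sd = 0.05, make_images = TRUE) {
  g <- as.integer(grid_size)
  if (g < 16) stop_config("grid_size must be >= 16")
  depth <- log2(g / 4)
  if (g %% 1 != 0 || depth %% 1 != 0 || depth < 1)
    stop_config("grid_size must be 4 * 2^depth (16, 32, 64, ...), got ", g)
  if (n_subjects < 1) stop_config("n_subjects must be >= 1")
  if (severity_scale <= 0) stop_config("severity_scale must be > 0")
  if (noise_sd_intensity < 0 || adas_meas_sd < 0 || longit_noise_sd < 0)
    stop_config("noise parameters must be >= 0")
  if (hotspot_fraction <= 0 || hotspot_fraction >= 1)
    stop_config("hotspot_fraction must be in (0, 1)")
  if (visit_months[1] != 0 || is.unsorted(visit_months, strictly = TRUE))
    stop_config("visit_months must start at 0 and increase strictly")
  structure(list(grid_size = g, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), severity_scale = severity_scale,
                 noise_sd_intensity = noise_sd_intensity,
                 adas_meas_sd = adas_meas_sd,
                 hotspot_fraction = hotspot_fraction,
                 young_control = isTRUE(young_control),
                 visit_months = as.numeric(visit_months),
                 longit_noise_sd = longit_noise_sd,
                 make_images = isTRUE(make_images)),
            class = "phantom_config")
}

# Geometry constants of the template head, expressed as fractions of the
# half-grid radius. The head is a mildly anisotropic ellipsoid; tissue
# shells are radial bands; ventricles are a central CSF ellipsoid.
.PHANTOM_GEOM <- list(
  axis_scale = c(0.95, 1.00, 0.90),
  r_head = 0.92, r_gm_outer = 0.84, gm_inner = 0.62,
  vent_radii = c(0.20, 0.10, 0.12),
  hotspot_dir = c(0.55, 0.30, -0.20), hotspot_rr = 0.73,
  mu = c(bg = 0.05, GM = 0.55, WM = 0.85, CSF = 0.25),
  pv_sigma = 0.6,
  # Inter-subject anatomical variability (disease cohorts): head size,
  # GM/WM boundary (cortical thickness) and GM/CSF boundary (sulcal CSF)
  # jitters. Calibrated so total tissue volumes are only a noisy severity
  # correlate -- volume-only models land in the weak regime reported for
  # demographics+volume regressors -- while the focal hotspot erosion stays
  # a clean, locally visible severity signal for the imaging model.
  head_jitter_sd = 0.02, gm_outer_jitter_sd = 0.02,
  thickness_jitter_sd = 0.035,
  # atrophy rates, voxels removed per severity point, as fractions:
  # hotspot fully eroded at s = 4 * severity_scale; global thinning rate
  # 0.5% of GM per point
  hotspot_full_at = 4, global_rate = 0.005,
  # longitudinal rate model: alpha = a0 + a1 * GM z-deficit + a2 * (age - mean)
  a0 = 0.005, a1 = 0.01, a2 = 0.002, sigma_alpha = 0.005,
  # rank correlation (Gaussian copula) between age and latent severity in
  # disease cohorts: demographics alone then predict cognition at the weak
  # but real level reported for demographics-only regressors, so the
  # tabular module contributes information genuinely complementary to the
  # imaging module. The severity marginal is untouched.
  age_severity_rho = 0.45
)

# Label codes: 0 background, 1 GM, 2 WM, 3 CSF.
.phantom_labels <- function(g, center, gm_inner, gm_outer = NULL,
                            head_scale = 1) {
  gg <- .PHANTOM_GEOM
  gm_outer <- gm_outer %||% gg$r_gm_outer
  ax <- seq_len(g)
  x <- rep(ax, times = g * g)
  y <- rep(rep(ax, each = g), times = g)
  z <- rep(ax, each = g * g)
  sx <- (x - center[1]) / gg$axis_scale[1]
  sy <- (y - center[2]) / gg$axis_scale[2]
  sz <- (z - center[3]) / gg$axis_scale[3]
  rr <- sqrt(sx^2 + sy^2 + sz^2) / (g / 2) / head_scale
  lab <- integer(g^3)
  lab[rr <= gg$r_head] <- 3L
  lab[rr <= gm_outer & rr > gm_inner] <- 1L
  lab[rr <= gm_inner] <- 2L
  vs <- head_scale * g / 2
  vr <- sqrt(((x - center[1]) / (gg$vent_radii[1] * vs))^2 +
             ((y - center[2]) / (gg$vent_radii[2] * vs))^2 +
             ((z - center[3]) / (gg$vent_radii[3] * vs))^2)
  lab[vr <= 1 & lab == 2L] <- 3L
  list(lab = lab, rr = rr, coords = cbind(x, y, z))
}

.phantom_hotspot_center <- function(g, center) {
  gg <- .PHANTOM_GEOM
  u <- gg$hotspot_dir / sqrt(sum(gg$hotspot_dir^2))
  center + u * gg$hotspot_rr * (g / 2) * gg$axis_scale
}

# Synthesise one subject's label map. Atrophy is implemented as deterministic
# voxel removal: the n_hot voxels of the hotspot closest to its centre and
# the n_glob outermost non-hotspot GM voxels become CSF, which makes the GM
# count a strictly decreasing, exactly reproducible function of severity.
.phantom_subject_labels <- function(g, center, gm_inner, severity, frac_hot,
                                    severity_scale, gm_outer = NULL,
                                    head_scale = 1) {
  gg <- .PHANTOM_GEOM
  geo <- .phantom_labels(g, center, gm_inner, gm_outer, head_scale)
  lab <- geo$lab
  gm_idx <- which(lab == 1L)
  hc <- .phantom_hotspot_center(g, center)
  d2 <- (geo$coords[gm_idx, 1] - hc[1])^2 + (geo$coords[gm_idx, 2] - hc[2])^2 +
        (geo$coords[gm_idx, 3] - hc[3])^2
  n_hot <- max(1L, round(frac_hot * length(gm_idx)))
  ord_hot <- order(d2)
  hot_idx <- gm_idx[ord_hot[seq_len(n_hot)]]
  hot_d2 <- d2[ord_hot[seq_len(n_hot)]]
  if (severity > 0) {
    k_hot <- n_hot / (gg$hotspot_full_at * severity_scale)
    n_erode <- min(n_hot, round(k_hot * severity))
    if (n_erode > 0) lab[hot_idx[order(hot_d2)[seq_len(n_erode)]]] <- 3L
    k_glob <- gg$global_rate * length(gm_idx)
    n_glob <- round(k_glob * severity)
    if (n_glob > 0) {
      rest <- setdiff(gm_idx, hot_idx)
      rest <- rest[order(geo$rr[rest], decreasing = TRUE)]
      lab[rest[seq_len(min(n_glob, length(rest)))]] <- 3L
    }
  }
  list(lab = array(lab, dim = c(g, g, g)), hotspot_idx = hot_idx,
       coords = geo$coords)
}

.phantom_image <- function(lab_arr, noise_sd) {
  gg <- .PHANTOM_GEOM
  g <- dim(lab_arr)[1]
  mu <- gg$mu[c(1, 2, 3, 4)][as.integer(lab_arr) + 1L]
  clean <- .cpp_gauss_smooth(as.numeric(mu), dim(lab_arr), gg$pv_sigma)
  img <- clean + rnorm(length(clean), 0, noise_sd)
  array(img, dim = dim(lab_arr))
}

#' Generate a synthetic phantom cohort
#'
#' Deterministic for a fixed configuration (seed included): two runs with the
#' same config produce bit-identical volumes and records. Each subject is the
#' template head with (for disease cohorts) a per-subject GM-ribbon thickness
#' jitter and sub-voxel centre shift, plus severity-driven atrophy; young
#' controls keep the exact template geometry up to an integer-voxel shift, so
#' their GM voxel count equals the undeformed template's.
#'
#' @param config a [phantom_config].
#' @return A `phantom_cohort` list with elements `volumes` (list of
#'   [volume3d] or NULL when `make_images = FALSE`), `labels` (list of 3D
#'   integer arrays: 0 background, 1 GM, 2 WM, 3 CSF), `records` (one row per
#'   subject: demographics, diagnosis, severity, baseline ADAS, true decline
#'   rate, GM voxel count), `adas_series` (long table subject_id, month,
#'   adas) and `ground_truth` (per-subject hotspot voxel indices, the cohort
#'   hotspot union bounding box, and the template GM count).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gg <- .PHANTOM_GEOM
  g <- config$grid_size
  n <- config$n_subjects
  with_seed(config$seed, {
    center0 <- rep((g + 1) / 2, 3)
    template <- .phantom_subject_labels(g, center0, gg$gm_inner, 0,
                                        config$hotspot_fraction,
                                        config$severity_scale)
    template_gm <- sum(template$lab == 1L)

    severity <- if (config$young_control) rep(0, n)
                else rgamma(n, shape = 2, scale = config$severity_scale)
    if (config$young_control) {
      age <- pmin(pmax(rnorm(n, 28, 3), 22), 37)
      shifts <- matrix(sample(-1:1, 3 * n, replace = TRUE), ncol = 3)
      gm_inner <- rep(gg$gm_inner, n)
      gm_outer <- rep(gg$r_gm_outer, n)
      head_scale <- rep(1, n)
    } else {
      z_s <- qnorm(rank(severity, ties.method = "random") / (n + 1))
      rho <- gg$age_severity_rho
      age_z <- rho * z_s + sqrt(1 - rho^2) * rnorm(n)
      age <- pmin(pmax(73 + 6 * age_z, 55), 91)
      shifts <- matrix(runif(3 * n, -1.5, 1.5), ncol = 3)
      gm_inner <- gg$gm_inner + rnorm(n, 0, gg$thickness_jitter_sd)
      gm_outer <- gg$r_gm_outer + rnorm(n, 0, gg$gm_outer_jitter_sd)
      head_scale <- 1 + rnorm(n, 0, gg$head_jitter_sd)
    }
    sex <- sample(c("F", "M"), n, replace = TRUE)
    education <- pmin(pmax(round(rnorm(n, 16, 2.5)), 4), 20)
    marital <- sample(c("married", "divorced", "other"), n, replace = TRUE,
                      prob = c(0.75, 0.09, 0.16))
    diagnosis <- ifelse(severity < config$severity_scale, "CN",
                 ifelse(severity < 3 * config$severity_scale, "MCI", "AD"))
    adas0 <- pmin(pmax(severity + rnorm(n, 0, config$adas_meas_sd), 0), 70)

    labels <- vector("list", n)
    volumes <- vector("list", n)
    hotspot_idx <- vector("list", n)
    gm_count <- integer(n)
    for (i in seq_len(n)) {
      sub <- .phantom_subject_labels(g, center0 + shifts[i, ], gm_inner[i],
                                     severity[i], config$hotspot_fraction,
                                     config$severity_scale, gm_outer[i],
                                     head_scale[i])
      labels[[i]] <- sub$lab
      hotspot_idx[[i]] <- sub$hotspot_idx
      gm_count[i] <- sum(sub$lab == 1L)
      if (config$make_images)
        volumes[[i]] <- volume3d(.phantom_image(sub$lab,
                                                config$noise_sd_intensity))
    }

    # longitudinal decline rate from GM deficit (z vs CN) and age
    if (config$young_control) {
      alpha_true <- rep(NA_real_, n)
      adas0[] <- NA_real_
    } else {
      cn <- diagnosis == "CN"
      mu_cn <- if (any(cn)) mean(gm_count[cn]) else mean(gm_count)
      sd_cn <- if (sum(cn) > 1 && sd(gm_count[cn]) > 0) sd(gm_count[cn])
               else max(sd(gm_count), 1)
      z_deficit <- (mu_cn - gm_count) / sd_cn
      alpha_true <- gg$a0 + gg$a1 * z_deficit + gg$a2 * (age - mean(age)) +
        rnorm(n, 0, gg$sigma_alpha)
    }

    subject_id <- sprintf("S%04d", seq_len(n))
    records <- data.frame(subject_id = subject_id, age = age, sex = sex,
                          education = education, marital = marital,
                          diagnosis = diagnosis, severity = severity,
                          adas0 = adas0, alpha_true = alpha_true,
                          gm_count = gm_count, stringsAsFactors = FALSE)

    adas_series <- NULL
    if (!config$young_control) {
      months <- config$visit_months
      rows <- lapply(seq_len(n), function(i) {
        val <- adas0[i] * exp(alpha_true[i] * months)
        noise <- exp(rnorm(length(months), 0, config$longit_noise_sd))
        noise[1] <- 1  # month 0 is the measured baseline itself
        data.frame(subject_id = subject_id[i], month = months,
                   adas = pmin(pmax(val * noise, 0), 70),
                   stringsAsFactors = FALSE)
      })
      adas_series <- do.call(rbind, rows)
    }

    hot_union <- sort(unique(unlist(hotspot_idx)))
    hc <- arrayInd(hot_union, .dim = c(g, g, g))
    bbox <- apply(hc, 2, range)
    structure(list(volumes = volumes, labels = labels, records = records,
                   adas_series = adas_series,
                   ground_truth = list(hotspot_idx = hotspot_idx,
                                       hotspot_union = hot_union,
                                       hotspot_bbox = bbox,
                                       template_gm_count = template_gm),
                   config = config),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> n =", nrow(x$records), "subjects, grid",
      x$config$grid_size, "^3,",
      if (x$config$young_control) "young controls (zero atrophy)"
      else paste0("diagnoses: ",
                  paste(names(table(x$records$diagnosis)),
                        table(x$records$diagnosis), collapse = ", ")), "\n")
  invisible(x)
}

#' Kolmogorov-Smirnov distance to the shape-2 Gamma reference
#'
#' Sup-norm distance between the empirical CDF of nonnegative scores and the
#' CDF of the Gamma distribution with density proportional to
#' (x / gamma) * exp(-x / gamma) (shape 2, scale `gamma`). Used to check
#' that the phantom's baseline cognition marginal has the intended
#' right-skewed shape.
#'
#' @param samples numeric vector of nonnegative scores (at least 10).
#' @param gamma scale parameter of the reference density.
#' @return the KS statistic in \[0, 1\].
#' @export
ks_distance_to_gamma <- function(samples, gamma) {
  if (length(samples) == 0) stop("empty sample")
  if (length(samples) < 10) stop("need at least 10 samples")
  if (gamma <= 0) stop("gamma must be positive")
  x <- sort(samples)
  n <- length(x)
  f <- pgamma(x, shape = 2, scale = gamma)
  max(max(seq_len(n) / n - f), max(f - (seq_len(n) - 1) / n))
}

#' Write a phantom cohort to disk
#'
#' One NIfTI image and one NIfTI label map per subject, a cohort CSV with one
#' row per subject-visit, and a JSON ground-truth sidecar (severity, true
#' decline rate, hotspot bounding box, seed).
#'
#' @param cohort a [generate_cohort] result (with images).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- cohort$records
  for (i in seq_len(nrow(rec))) {
    sid <- rec$subject_id[i]
    if (!is.null(cohort$volumes[[i]]))
      write_volume(cohort$volumes[[i]], file.path(dir, paste0(sid, "_T1.nii.gz")))
    write_volume(volume3d(cohort$labels[[i]] + 0),
                 file.path(dir, paste0(sid, "_labels.nii.gz")))
  }
  visits <- cohort$adas_series
  if (is.null(visits))
    visits <- data.frame(subject_id = rec$subject_id, month = 0,
                         adas = NA_real_)
  tab <- merge(visits, rec[c("subject_id", "age", "sex", "education",
                             "marital", "diagnosis")], by = "subject_id")
  tab <- tab[order(tab$subject_id, tab$month),
             c("subject_id", "month", "age", "sex", "education", "marital",
               "diagnosis", "adas")]
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         grid_size = cohort$config$grid_size,
         young_control = cohort$config$young_control,
         severity = setNames(as.list(rec$severity), rec$subject_id),
         alpha_true = setNames(as.list(rec$alpha_true), rec$subject_id),
         hotspot_bbox = cohort$ground_truth$hotspot_bbox,
         template_gm_count = cohort$ground_truth$template_gm_count),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort]
#' @param dir cohort directory.
#' @return a `phantom_cohort`-like list (without generator internals).
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) stop("no cohort.csv in ", dir, "; run the simulate ",
                              "step first")
  tab <- read.csv(csv, stringsAsFactors = FALSE)
  ids <- unique(tab$subject_id)
  volumes <- labels <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    img <- file.path(dir, paste0(ids[i], "_T1.nii.gz"))
    lb <- file.path(dir, paste0(ids[i], "_labels.nii.gz"))
    if (file.exists(img)) volumes[[i]] <- read_volume(img)
    if (file.exists(lb)) {
      l <- read_volume(lb)
      labels[[i]] <- array(as.integer(round(l$values)), dim = dim(l$values))
    }
  }
  rec <- unique(tab[c("subject_id", "age", "sex", "education", "marital",
                      "diagnosis")])
  base <- tab[tab$month == 0, c("subject_id", "adas")]
  names(base)[2] <- "adas0"
  rec <- merge(rec, base, by = "subject_id", all.x = TRUE)
  rec <- rec[match(ids, rec$subject_id), ]
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path,
                                                      simplifyVector = TRUE)
        else NULL
  list(volumes = volumes, labels = labels, records = rec,
       adas_series = tab[c("subject_id", "month", "adas")],
       ground_truth = gt)
}
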