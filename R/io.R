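#' 3D volume container
#'
#' A minimal container for a 3D intensity grid with voxel spacing and an
#' origin offset. Axis order is fixed (x, y, z) with x varying fastest, the
#' native column-major order of an R array.
#'
#' @param values 3D numeric array.
#' @param voxel_size numeric length-3, mm per axis (anisotropic allowed).
#' @param origin numeric length-3 offset in mm.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dimension(s)")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (!all(is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

as_volume_array <- function(v) {
  if (inherits(v, "volume3d")) v$values
  else if (is.array(v) && length(dim(v)) == 3L) v
  else stop("expected a volume3d or 3D array")
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around RNifti preserving voxel spacing. Only 3D images are
#' accepted; higher-dimensional NIfTI files are rejected.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume3d]; `write_volume` returns the
#'   path invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("expected a 3D image, got ", length(dm), " dimensions in ", path)
  vs <- RNifti::pixdim(img)[seq_len(3)]
  volume3d(array(as.numeric(img), dim = dm), voxel_size = vs)
}

#' @param v a [volume3d] (or 3D array, written with unit spacing).
#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  if (is.array(v)) v <- volume3d(v)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to a target grid
#'
#' Trilinear interpolation for intensities, nearest-neighbour for label maps
#' (which guarantees no new label values are invented). The voxel size is
#' rescaled so physical extent is preserved.
#'
#' @param v [volume3d] or 3D array.
#' @param target_size integer scalar or length-3 target grid.
#' @param method "trilinear" or "nearest".
#' @return same type as the input.
#' @export
resample_to_grid <- function(v, target_size, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  arr <- as_volume_array(v)
  src <- dim(arr)
  tgt <- as.integer(rep_len(target_size, 3L))
  if (any(tgt < 1L)) stop("target size must be positive")
  out <- .cpp_resample(as.numeric(arr), as.integer(src), tgt,
                       method == "nearest")
  out <- array(out, dim = tgt)
  if (method == "nearest") out <- array(as.integer(round(out)), dim = tgt)
  if (inherits(v, "volume3d"))
    volume3d(out, voxel_size = v$voxel_size * src / tgt, origin = v$origin)
  else out
}

#' Subject-level train / validation / test split plan
#'
#' Splits a cohort into a set-aside test fraction and k cross-validation
#' folds over the remainder, stratified by diagnosis and assigned strictly
#' per subject (never per scan or visit), so no subject identifier can cross
#' a partition boundary.
#'
#' @param cohort data.frame with at least `subject_id` and `diagnosis`
#'   columns; repeated rows per subject (visits) are allowed but must agree
#'   on demographics.
#' @param n_folds number of CV folds over the non-test portion (default 9).
#' @param test_frac set-aside test fraction (default 0.1).
#' @param seed RNG seed governing the (stratified) shuffle; the same seed
#'   yields the identical plan.
#' @return A `split_plan`: data.frame with columns `subject_id`, `role`
#'   ("train" or "test") and `fold` (NA for test subjects).
#' @export
make_splits <- function(cohort, n_folds = 9, test_frac = 0.1, seed = 42) {
  stopifnot(is.data.frame(cohort), "subject_id" %in% names(cohort))
  demo_cols <- intersect(c("age", "sex", "education", "marital", "diagnosis"),
                         names(cohort))
  subj <- unique(cohort[c("subject_id", demo_cols)])
  if (anyDuplicated(subj$subject_id))
    stop("duplicate subject_id rows with conflicting demographics")
  n <- nrow(subj)
  if (n < n_folds + 1) stop("need at least n_folds + 1 subjects")
  strata <- if ("diagnosis" %in% names(subj)) as.character(subj$diagnosis)
            else rep("all", n)
  n_test <- round(test_frac * n)
  plan <- with_seed(seed, {
    ord <- unlist(lapply(split(seq_len(n), strata), sample), use.names = FALSE)
    # largest-remainder allocation of the test quota across strata
    sizes <- table(strata)[unique(strata[ord])]
    quota <- n_test * as.numeric(sizes) / n
    base <- floor(quota)
    extra <- order(quota - base, decreasing = TRUE)
    add <- integer(length(sizes))
    need <- n_test - sum(base)
    if (need > 0) add[extra[seq_len(need)]] <- 1L
    test_per <- base + add
    role <- rep("train", n)
    fold <- rep(NA_integer_, n)
    pos <- 1L
    train_ord <- integer(0)
    for (si in seq_along(sizes)) {
      ids <- ord[pos:(pos + sizes[si] - 1L)]
      pos <- pos + as.integer(sizes[si])
      if (test_per[si] > 0) role[ids[seq_len(test_per[si])]] <- "test"
      train_ord <- c(train_ord, ids[setdiff(seq_along(ids),
                                            seq_len(test_per[si]))])
    }
    fold[train_ord] <- rep_len(seq_len(n_folds), length(train_ord))
    data.frame(subject_id = subj$subject_id, role = role, fold = fold,
               stringsAsFactors = FALSE)
  })
  structure(plan, n_folds = n_folds, seed = seed, test_frac = test_frac,
            class = c("split_plan", "data.frame"))
}

#' Validate partition disjointness of a split plan
#'
#' Checks that every subject appears exactly once, that test subjects carry
#' no fold, and that folds partition the non-test subjects. Used as the
#' automated leakage audit of the splitting stage.
#'
#' @param plan a [make_splits] plan.
#' @return TRUE invisibly; errors on any violation.
#' @export
validate_split_plan <- function(plan) {
  if (anyDuplicated(plan$subject_id))
    stop("leakage: subject appears in more than one partition")
  if (any(plan$role == "test" & !is.na(plan$fold)))
    stop("test subjects must not belong to a CV fold")
  if (any(plan$role == "train" & is.na(plan$fold)))
    stop("train subjects must belong to a CV fold")
  invisible(TRUE)
}

#' Partition subject ids for one CV fold
#'
#' @param plan a [make_splits] plan.
#' @param fold validation fold index, or NULL for the train/test view only.
#' @return list with `train`, `validation` and `test` character vectors.
#' @export
split_ids <- function(plan, fold = NULL) {
  test <- plan$subject_id[plan$role == "test"]
  if (is.null(fold)) {
    list(train = plan$subject_id[plan$role == "train"],
         validation = character(0), test = test)
  } else {
    if (!fold %in% seq_len(attr(plan, "n_folds"))) stop("invalid fold index")
    val <- plan$subject_id[plan$role == "train" & plan$fold == fold]
    tr <- plan$subject_id[plan$role == "train" & plan$fold != fold]
    list(train = tr, validation = val, test = test)
  }
}

#' Write / read split plans as JSON
#' @param plan a split plan; `path` a JSON file path.
#' @return the path (write) or the plan (read).
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(n_folds = attr(plan, "n_folds"),
                            seed = attr(plan, "seed"),
                            test_frac = attr(plan, "test_frac"),
                            assignment = as.data.frame(plan)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x$assignment, n_folds = x$n_folds, seed = x$seed,
            test_frac = x$test_frac, class = c("split_plan", "data.frame"))
}
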