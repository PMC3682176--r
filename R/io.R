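# File formats: NIfTI volumes, YAML ground truth / manifests, CSV + JSON
# results.

#' Write a cohort's volumes as NIfTI-1 files
#'
#' One gzipped NIfTI file per subject and time point, named
#' `<subject_id>_t1.nii.gz` / `<subject_id>_t2.nii.gz`.
#'
#' @param volumes a `cohort_volumes` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_volumes <- function(volumes, dir) {
  stopifnot(inherits(volumes, "cohort_volumes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(volumes$subject_ids)) {
    id <- volumes$subject_ids[i]
    for (tp in c("t1", "t2")) {
      img <- RNifti::asNifti(volumes[[tp]][, , , i])
      RNifti::pixdim(img) <- volumes$voxel_size
      RNifti::writeNifti(img, file.path(dir, paste0(id, "_", tp, ".nii.gz")))
    }
  }
  invisible(dir)
}

#' Read a cohort's volumes from NIfTI-1 files
#'
#' Expects the layout written by [write_volumes()]. Subjects are loaded in
#' the order of `subject_ids`; a missing file, a shape mismatch or a voxel
#' size mismatch is an error naming the subject.
#'
#' @param dir directory containing `<id>_t{1,2}.nii.gz` files.
#' @param subject_ids ordered subject ids to load (default: every id with
#'   a `_t1` file, numerically sorted).
#' @return a `cohort_volumes` object.
#' @export
read_volumes <- function(dir, subject_ids = NULL) {
  if (is.null(subject_ids)) {
    f <- list.files(dir, pattern = "_t1\\.nii(\\.gz)?$")
    subject_ids <- sort(as.integer(sub("_t1\\.nii(\\.gz)?$", "", f)))
  }
  if (length(subject_ids) == 0) abort("no volumes found")
  ref_dim <- NULL; ref_pix <- NULL
  load_one <- function(id, tp) {
    path <- file.path(dir, paste0(id, "_", tp, ".nii.gz"))
    if (!file.exists(path))
      path <- file.path(dir, paste0(id, "_", tp, ".nii"))
    if (!file.exists(path))
      abort(paste0("missing ", tp, " volume for subject ", id))
    img <- RNifti::readNifti(path)
    pix <- attr(img, "pixdim")[1:3]
    if (is.null(ref_dim)) {
      ref_dim <<- dim(img); ref_pix <<- pix
    } else {
      if (!identical(dim(img), ref_dim))
        abort(paste0("volume shape mismatch for subject ", id))
      if (any(abs(pix - ref_pix) > 1e-6))
        abort(paste0("voxel size / affine mismatch for subject ", id))
    }
    as.array(img)
  }
  n <- length(subject_ids)
  first <- load_one(subject_ids[1], "t1")
  t1 <- array(0, c(dim(first), n)); t1[, , , 1] <- first
  t2 <- array(0, c(dim(first), n)); t2[, , , 1] <- load_one(subject_ids[1], "t2")
  if (n > 1) for (i in 2:n) {
    t1[, , , i] <- load_one(subject_ids[i], "t1")
    t2[, , , i] <- load_one(subject_ids[i], "t2")
  }
  new_cohort_volumes(t1, t2, subject_ids, ref_pix)
}

#' Write a statistic or count array as NIfTI-1
#'
#' @param x 3-D array, or a `stat_map` (its z array is written).
#' @param file output path (`.nii.gz`).
#' @param voxel_size mm per voxel (taken from a `stat_map` if not given).
#' @return the path, invisibly.
#' @export
write_map <- function(x, file, voxel_size = NULL) {
  if (inherits(x, "stat_map")) {
    voxel_size <- x$voxel_size
    x <- x$z
  }
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Serialise a ground truth to YAML
#'
#' Masks are stored as 0-based voxel coordinate lists; [read_truth()]
#' restores the object exactly.
#'
#' @param truth a [ground_truth()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, file) {
  stopifnot(inherits(truth, "ground_truth"))
  ser <- truth
  ser$region_v <- apply(lin_to_coord(which(truth$region_v), truth$shape) - 1L,
                        1, identity, simplify = FALSE)
  ser$region_p <- apply(lin_to_coord(which(truth$region_p), truth$shape) - 1L,
                        1, identity, simplify = FALSE)
  yaml::write_yaml(lapply(ser, function(v) if (is.array(v)) as.numeric(v) else v),
                   file)
  invisible(file)
}

#' Read a ground truth from YAML
#'
#' @param file path written by [write_truth()].
#' @return a `ground_truth` object.
#' @export
read_truth <- function(file) {
  y <- yaml::read_yaml(file)
  shape <- as.integer(unlist(y$shape))
  unmask <- function(coords) {
    m <- array(FALSE, shape)
    xyz <- do.call(rbind, lapply(coords, as.integer)) + 1L
    m[coord_to_lin(xyz, shape)] <- TRUE
    m
  }
  ground_truth(
    shape = shape, voxel_size = unlist(y$voxel_size),
    center_v = unlist(y$center_v), center_p = unlist(y$center_p),
    region_v = unmask(y$region_v), region_p = unmask(y$region_p),
    slope_v = y$slope_v, slope_p = y$slope_p,
    age_slope = if (length(unlist(y$age_slope)) == 1) y$age_slope
                else array(unlist(y$age_slope), shape),
    noise_sd = y$noise_sd, smooth_fwhm = y$smooth_fwhm,
    baseline_mean = y$baseline_mean, baseline_sd = y$baseline_sd
  )
}

#' Write a cross-validation result to a run directory
#'
#' Writes `folds.csv` (the [fold_table()]), `summary.json` (per-measure
#' R-squared values and type-II rates), `manifest.yaml` (scheme,
#' configuration, seed, package version) and, for split-half results, a
#' selection-frequency NIfTI per measure.
#'
#' @param result a `cv_result`.
#' @param dir output directory.
#' @param voxel_size mm per voxel for the frequency maps.
#' @return `dir`, invisibly.
#' @export
write_cv_result <- function(result, dir, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(result, "cv_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(fold_table(result), file.path(dir, "folds.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(scheme = result$scheme, summary = result$summary),
    file.path(dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest <- c(list(scheme = result$scheme,
                     package_version = as.character(utils::packageVersion("longicv"))),
                unclass(result$config))
  manifest$forming_p <- as.list(manifest$forming_p)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (!is.null(result$selection_freq)) {
    for (m in names(result$selection_freq))
      write_map(result$selection_freq[[m]],
                file.path(dir, paste0("selection_freq_", m, ".nii.gz")),
                voxel_size = voxel_size)
  }
  invisible(dir)
}
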