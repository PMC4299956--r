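#' Read / write a volume as NIfTI-1
#'
#' Thin wrappers around RNifti returning plain 3D arrays, so intensity and
#' label volumes share a representation with the synthetic generator.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param volume Numeric or integer 3D array.
#' @return `read_volume` returns a 3D array.
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' Extract per-VOI mean uptake from a labeled volume
#'
#' Computes the arithmetic mean of the intensity volume over the voxels of
#' each labeled region. Background (label 0) is ignored. NaN voxels are
#' excluded from the mean; the number of exclusions is recorded. A region
#' whose voxels are all NaN, a mapped region with no voxels, or a label in
#' the volume that is missing from the map are errors.
#'
#' @param intensity_volume 3D numeric array.
#' @param label_volume 3D integer array of the same shape.
#' @param label_map Label map data frame (see [build_atlas()]).
#' @return A `voi_table` data frame: region_name, hemisphere, voxel_count,
#'   raw_mean, nv (NA until normalized), is_cerebellum, label,
#'   n_nan_excluded.
#' @export
extract_voi_means <- function(intensity_volume, label_volume, label_map) {
  if (!identical(dim(intensity_volume), dim(label_volume)))
    stopf("intensity and label volumes have different shapes")
  labs_present <- sort(unique(as.integer(label_volume)))
  labs_present <- labs_present[labs_present != 0L]
  unmapped <- setdiff(labs_present, label_map$label)
  if (length(unmapped))
    stopf("label(s) present in volume but missing from label map: %s",
          paste(unmapped, collapse = ", "))
  idx <- which(label_volume != 0L)
  by_lab <- split(intensity_volume[idx], as.integer(label_volume[idx]))
  out <- label_map[, c("region_name", "hemisphere", "is_cerebellum", "label")]
  out$voxel_count <- NA_integer_
  out$raw_mean <- NA_real_
  out$n_nan_excluded <- 0L
  for (k in seq_len(nrow(out))) {
    v <- by_lab[[as.character(out$label[k])]]
    if (is.null(v) || !length(v))
      stopf("region '%s' (%s) has no voxels in the label volume",
            out$region_name[k], out$hemisphere[k])
    nan <- is.na(v)
    if (all(nan))
      stopf("region '%s' (%s) contains only NaN voxels",
            out$region_name[k], out$hemisphere[k])
    out$n_nan_excluded[k] <- sum(nan)
    out$voxel_count[k] <- length(v)
    out$raw_mean[k] <- mean(v[!nan])
  }
  out$nv <- NA_real_
  class(out) <- c("voi_table", "data.frame")
  out[, c("region_name", "hemisphere", "voxel_count", "raw_mean", "nv",
          "is_cerebellum", "label", "n_nan_excluded")]
}

#' Normalize a VOI table to the cerebellar reference
#'
#' Divides every regional raw mean by the cerebellar reference, defined as
#' the voxel-count-weighted mean raw intensity over all cerebellar regions
#' (equal to the plain voxel mean over their pooled voxel set). Cerebellar
#' rows are retained, flagged, and normalize to a weighted aggregate of 1
#' by construction.
#'
#' @param table A `voi_table` from [extract_voi_means()].
#' @return The table with the `nv` column filled and attribute
#'   `cerebellar_reference` set.
#' @export
normalize_to_cerebellum <- function(table) {
  cb <- table$is_cerebellum & table$voxel_count >= 1L
  if (!any(cb)) stopf("no cerebellar reference region with voxels")
  ref <- sum(table$raw_mean[cb] * table$voxel_count[cb]) / sum(table$voxel_count[cb])
  if (!is.finite(ref) || ref <= 0)
    stopf("cerebellar reference is non-positive or undefined (%.4g)", ref)
  table$nv <- table$raw_mean / ref
  attr(table, "cerebellar_reference") <- ref
  table
}

#' Extract and normalize every subject of a simulated volume cohort
#'
#' Convenience wrapper producing a `feature_cohort` (per-subject VOI tables
#' plus metadata) from a `volume_cohort`, the form consumed by
#' [assemble_dataset()].
#'
#' @param vc A `volume_cohort` from [simulate_volume_cohort()].
#' @return A `feature_cohort`.
#' @export
extract_cohort <- function(vc) {
  stopifnot(inherits(vc, "volume_cohort"))
  tables <- lapply(vc$volumes, function(v)
    normalize_to_cerebellum(
      extract_voi_means(v, vc$atlas$labels, vc$atlas$label_map)))
  structure(list(tables = tables, metadata = vc$metadata),
            class = "feature_cohort")
}

#' Write per-subject VOI means to CSV
#'
#' Long format: subject_id, region_name, hemisphere, voxel_count, raw_mean,
#' nv.
#'
#' @param fc A `feature_cohort`.
#' @param path Output CSV path.
#' @export
write_voi_means <- function(fc, path) {
  rows <- do.call(rbind, lapply(names(fc$tables), function(sid) {
    t <- fc$tables[[sid]]
    cbind(subject_id = sid,
          t[, c("region_name", "hemisphere", "voxel_count", "raw_mean", "nv")])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
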