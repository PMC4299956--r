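#' AAL-style bilateral region table
#'
#' The 45 bilateral cortical and subcortical regions used for regional FDG
#' uptake quantification, together with the meta-VOI each belongs to (or
#' `NA` for regions outside the twelve anatomo-functional groupings).
#' Region names follow the Automated Anatomical Labeling nomenclature.
#'
#' @return A data frame with columns `region_name` and `meta_voi`.
#' @export
aal_region_table <- function() {
  m <- default_meta_voi_map()
  regions <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  meta <- rep(NA_character_, length(regions))
  for (mv in names(m)) meta[regions %in% m[[mv]]] <- mv
  data.frame(region_name = regions, meta_voi = meta, stringsAsFactors = FALSE)
}

#' Default meta-VOI map
#'
#' The twelve per-hemisphere groupings of anatomo-functionally related AAL
#' regions used to reduce the 45 bilateral VOIs to 12 bilateral meta-VOIs.
#'
#' @return Named list: meta-VOI name to character vector of constituent
#'   region names (per hemisphere).
#' @export
default_meta_voi_map <- function() {
  list(
    Occipital_Cortex = c("Calcarine", "Lingual", "Occipital_Inf",
                         "Occipital_Mid", "Occipital_Sup"),
    Thalamus_Striatum = c("Thalamus", "Putamen", "Pallidum", "Caudate"),
    Mesial_Temporal_Insula = c("ParaHippocampal", "Amygdala", "Hippocampus",
                               "Insula"),
    Orbitofrontal_Cortex = c("Frontal_Inf_Orb", "Frontal_Med_Orb",
                             "Frontal_Sup_Orb"),
    Frontal_Cortex = c("Frontal_Mid", "Frontal_Sup", "Frontal_Sup_Medial"),
    Cuneus_Fusiform_Precuneus = c("Cuneus", "Fusiform", "Precuneus"),
    Sensorimotor = c("Postcentral", "Precentral", "Supp_Motor_Area"),
    Parietal_Lobe = c("Parietal_Inf", "Parietal_Sup"),
    Anterior_Cingulate = "Cingulum_Ant",
    Posterior_Cingulate = "Cingulum_Post",
    Temporal_Lobe = c("Temporal_Inf", "Temporal_Mid", "Temporal_Sup"),
    Temporal_Pole = c("Temporal_Pole_Mid", "Temporal_Pole_Sup")
  )
}

#' Specify a phantom atlas
#'
#' Describes a labeled phantom volume: a grid, a set of bilateral VOIs with
#' target voxel counts, and at least one cerebellar reference region per
#' hemisphere. Left/right homologs always receive equal voxel counts and are
#' mirror-placed across the mid-sagittal plane.
#'
#' @param grid_shape Integer vector of length 3, voxels per axis. The first
#'   axis is left-right and must be even.
#' @param regions Data frame with columns `region_name` and (optionally)
#'   `meta_voi`; one row per bilateral VOI. Defaults to [aal_region_table()].
#' @param voxels_per_region Target voxel count for each bilateral VOI
#'   (per hemisphere); either a scalar or one value per region.
#' @param cerebellum_voxels Target voxel count of the cerebellar reference
#'   region in each hemisphere.
#' @return An object of class `atlas_spec`.
#' @export
atlas_spec <- function(grid_shape = c(32L, 32L, 32L),
                       regions = aal_region_table(),
                       voxels_per_region = 64L,
                       cerebellum_voxels = 256L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stopf("grid_shape must be three integers >= 2")
  if (grid_shape[1] %% 2L != 0L)
    stopf("first grid axis must be even (mid-sagittal mirror plane)")
  if (!all(c("region_name") %in% names(regions)))
    stopf("regions needs a region_name column")
  if (anyDuplicated(regions$region_name))
    stopf("duplicate region names in atlas spec")
  nv <- rep_len(as.integer(voxels_per_region), nrow(regions))
  if (any(nv < 1L) || cerebellum_voxels < 1L)
    stopf("voxel counts must be positive")
  layout <- data.frame(
    region_name = c(regions$region_name, "Cerebelum"),
    meta_voi = c(if ("meta_voi" %in% names(regions)) regions$meta_voi
                 else rep(NA_character_, nrow(regions)), NA_character_),
    target_voxels = c(nv, as.integer(cerebellum_voxels)),
    is_cerebellum = c(rep(FALSE, nrow(regions)), TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(grid_shape = grid_shape, layout = layout,
                 background_label = 0L),
            class = "atlas_spec")
}

#' Build a labeled phantom volume from an atlas specification
#'
#' Carves each region out of the left half-grid as a run of consecutive
#' voxels in raster order (axis-aligned slabs when counts are multiples of
#' the half-row length) and mirrors it across the mid-sagittal plane to
#' create the right homolog. Labels are consecutive positive integers in
#' layout order, left before right; background is 0.
#'
#' @param spec An [atlas_spec()].
#' @return A `labeled_volume`: list with `labels` (3D integer array) and
#'   `label_map` (data frame: label, region_name, hemisphere, meta_voi,
#'   is_cerebellum, voxel_count).
#' @export
build_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  g <- spec$grid_shape
  nxh <- g[1] %/% 2L
  capacity <- nxh * g[2] * g[3]
  lay <- spec$layout
  labels <- array(0L, dim = g)
  # left-half voxel order: x fastest, then y, then z
  cursor <- 0L
  map <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    n <- lay$target_voxels[i]
    if (cursor + n > capacity)
      stopf("atlas grid too small: cannot place region '%s' (%d voxels needed, %d free)",
            lay$region_name[i], n, capacity - cursor)
    off <- cursor + seq_len(n) - 1L
    x <- off %% nxh + 1L
    y <- (off %/% nxh) %% g[2] + 1L
    z <- off %/% (nxh * g[2]) + 1L
    lab_l <- 2L * i - 1L
    lab_r <- 2L * i
    labels[cbind(x, y, z)] <- lab_l
    labels[cbind(g[1] + 1L - x, y, z)] <- lab_r
    map[[i]] <- data.frame(
      label = c(lab_l, lab_r),
      region_name = lay$region_name[i],
      hemisphere = c("L", "R"),
      meta_voi = lay$meta_voi[i],
      is_cerebellum = lay$is_cerebellum[i],
      voxel_count = n,
      stringsAsFactors = FALSE
    )
    cursor <- cursor + n
  }
  structure(list(labels = labels, label_map = do.call(rbind, map)),
            class = "labeled_volume")
}

#' Write / read an atlas label map as TSV
#'
#' Columns: label_int, region_name, hemisphere (L/R/NA), meta_voi_name,
#' is_cerebellum (0/1).
#'
#' @param label_map Data frame as produced by [build_atlas()].
#' @param path File path.
#' @return `read_label_map` returns the label map data frame.
#' @export
write_label_map <- function(label_map, path) {
  out <- data.frame(
    label_int = label_map$label,
    region_name = label_map$region_name,
    hemisphere = ifelse(is.na(label_map$hemisphere), "NA", label_map$hemisphere),
    meta_voi_name = ifelse(is.na(label_map$meta_voi), "NA", label_map$meta_voi),
    is_cerebellum = as.integer(label_map$is_cerebellum),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  data.frame(
    label = as.integer(x$label_int),
    region_name = x$region_name,
    hemisphere = ifelse(x$hemisphere == "NA", NA_character_, x$hemisphere),
    meta_voi = ifelse(x$meta_voi_name == "NA", NA_character_, x$meta_voi_name),
    is_cerebellum = x$is_cerebellum == 1L,
    voxel_count = if ("voxel_count" %in% names(x)) x$voxel_count else NA_integer_,
    stringsAsFactors = FALSE
  )
}
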