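#' Merge a VOI table to meta-VOI resolution
#'
#' Each meta-VOI value is the voxel-count-weighted mean of its constituent
#' normalized values (identical to the voxel mean over the merged volume);
#' voxel counts add. Merging is done per hemisphere. Cerebellar rows are
#' carried through unchanged.
#'
#' @param table A `voi_table` with `nv` filled.
#' @param map Named list, meta-VOI name to constituent region names
#'   (default [default_meta_voi_map()]).
#' @return A `voi_table` at meta-VOI resolution.
#' @export
merge_meta_vois <- function(table, map = default_meta_voi_map()) {
  rows <- list()
  for (mv in names(map)) {
    for (h in c("L", "R")) {
      sel <- table$region_name %in% map[[mv]] & table$hemisphere == h &
        !table$is_cerebellum
      missing <- setdiff(map[[mv]], table$region_name[table$hemisphere == h])
      if (length(missing))
        stopf("meta-VOI '%s' (%s): missing constituent region(s): %s",
              mv, h, paste(missing, collapse = ", "))
      w <- table$voxel_count[sel]
      rows[[paste(mv, h)]] <- data.frame(
        region_name = mv, hemisphere = h, voxel_count = sum(w),
        raw_mean = sum(table$raw_mean[sel] * w) / sum(w),
        nv = sum(table$nv[sel] * w) / sum(w),
        is_cerebellum = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  cb <- table[table$is_cerebellum,
              c("region_name", "hemisphere", "voxel_count", "raw_mean", "nv",
                "is_cerebellum")]
  out <- rbind(do.call(rbind, rows), cb)
  rownames(out) <- NULL
  class(out) <- c("voi_table", "data.frame")
  out
}

#' Inter-hemispheric asymmetry index
#'
#' `asy = |nv_left - nv_right| / (nv_left + nv_right)`, the absolute
#' normalized left-right difference of a bilateral VOI. Dimensionless,
#' symmetric in its arguments, scale-invariant, and bounded by [0, 1] for
#' positive inputs.
#'
#' @param nv_left,nv_right Normalized uptake of the left / right homolog
#'   (vectorized).
#' @return Asymmetry value(s).
#' @export
asymmetry_index <- function(nv_left, nv_right) {
  s <- nv_left + nv_right
  if (any(!is.finite(s)) || any(s <= 0))
    stopf("asymmetry index needs a positive left+right sum")
  abs(nv_left - nv_right) / s
}

#' Assemble a subjects-by-features dataset
#'
#' Builds the feature matrix for one dataset variant from per-subject VOI
#' tables:
#' * `"90R"` — normalized values of the 45 bilateral regions (90 features);
#' * `"24R"` — normalized values of the 12 bilateral meta-VOIs (24);
#' * `"90R+45A"` — 90R plus one asymmetry index per bilateral pair (135);
#' * `"24R+12A"` — 24R plus meta-VOI asymmetries (36);
#' * `"custom"` — an explicit list of feature names drawn from the region
#'   or meta-VOI space (regional/meta values named `<name>_L` / `<name>_R`,
#'   asymmetries `asy_<name>`).
#'
#' Cerebellar reference regions never appear as features. Meta-VOI
#' asymmetries are computed from the merged left/right meta values.
#'
#' @param fc A `feature_cohort` (from [simulate_feature_cohort()] or
#'   [extract_cohort()]).
#' @param variant One of `"90R"`, `"24R"`, `"90R+45A"`, `"24R+12A"`,
#'   `"custom"`.
#' @param meta_map Meta-VOI map for the meta variants.
#' @param features For `variant = "custom"`: character vector of feature
#'   names, resolved against the meta-VOI space first, then the region
#'   space.
#' @return A `feature_dataset`: list with `x` (numeric matrix subjects x
#'   features), `group` (factor control/patient), `gender`, `age`,
#'   `subject_id`, `variant`.
#' @export
assemble_dataset <- function(fc, variant = c("90R", "24R", "90R+45A",
                                             "24R+12A", "custom"),
                             meta_map = default_meta_voi_map(),
                             features = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(fc, "feature_cohort"))
  md <- fc$metadata
  build <- function(tab, level) {
    t <- if (level == "meta") merge_meta_vois(tab, meta_map) else tab
    t <- t[!t$is_cerebellum, ]
    t <- t[order(match(t$region_name, unique(t$region_name)), t$hemisphere), ]
    vals <- t$nv
    names(vals) <- paste0(t$region_name, "_", t$hemisphere)
    asy <- vapply(unique(t$region_name), function(r) {
      l <- t$nv[t$region_name == r & t$hemisphere == "L"]
      r_ <- t$nv[t$region_name == r & t$hemisphere == "R"]
      if (length(l) != 1L || length(r_) != 1L)
        stopf("region '%s' is not bilateral in this table", r)
      asymmetry_index(l, r_)
    }, 0)
    names(asy) <- paste0("asy_", unique(t$region_name))
    c(vals, asy)
  }
  level <- switch(variant, "24R" = , "24R+12A" = "meta", "region")
  if (variant == "custom" && is.null(features))
    stopf("variant 'custom' needs an explicit feature list")
  rows <- lapply(fc$tables, function(tab) {
    if (variant == "custom") {
      # the meta-VOI pool is only available when the table carries the
      # map's constituents; custom selections from pure region tables work
      meta_all <- tryCatch(build(tab, "meta"), error = function(e) NULL)
      reg_all <- build(tab, "region")
      pool <- c(meta_all, reg_all[setdiff(names(reg_all), names(meta_all))])
      missing <- setdiff(features, names(pool))
      if (length(missing))
        stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
      pool[features]
    } else {
      all <- build(tab, level)
      keep <- switch(variant,
        "90R" = , "24R" = !startsWith(names(all), "asy_"),
        rep(TRUE, length(all)))
      all[keep]
    }
  })
  nm <- names(rows[[1]])
  bad <- which(vapply(rows, function(r) !identical(names(r), nm), TRUE))
  if (length(bad))
    stopf("subject '%s' has a different region set", md$subject_id[bad[1]])
  x <- do.call(rbind, rows)
  rownames(x) <- md$subject_id
  if (anyNA(x)) stopf("assembled dataset contains missing values")
  structure(list(x = x, group = factor(md$group, c("control", "patient")),
                 gender = md$gender, age = md$age,
                 subject_id = md$subject_id, variant = variant),
            class = "feature_dataset")
}

#' Fit the control-only gender model
#'
#' Fits a linear model of normalized value on region, gender, age and the
#' region-by-gender interaction over control subjects only (long format,
#' one row per subject-by-region value; asymmetry features are excluded).
#' Returns per-region gender offsets (female minus male cell means),
#' pooled control means, and screening p-values for the omnibus
#' region-by-gender interaction and the age term.
#'
#' @param dataset A `feature_dataset` containing control subjects (patients,
#'   if present, are ignored).
#' @return A `gender_model`: list with `offsets`, `pooled_means`,
#'   `p_gender_interaction`, `p_age`, `features`.
#' @export
fit_gender_model <- function(dataset) {
  stopifnot(inherits(dataset, "feature_dataset"))
  ctrl <- dataset$group == "control"
  if (sum(ctrl) < 4L) stopf("need at least 4 control subjects")
  feats <- colnames(dataset$x)[!startsWith(colnames(dataset$x), "asy_")]
  if (!length(feats)) stopf("no regional (non-asymmetry) features to model")
  g <- factor(dataset$gender[ctrl], c("F", "M"))
  if (nlevels(droplevels(g)) < 2L)
    stopf("controls contain a single gender; gender model is unidentifiable")
  x <- dataset$x[ctrl, feats, drop = FALSE]
  long <- data.frame(
    value = as.vector(x),
    region = factor(rep(feats, each = nrow(x)), feats),
    gender = rep(g, length(feats)),
    age = rep(dataset$age[ctrl], length(feats))
  )
  fit <- stats::lm(value ~ region * gender + age, data = long)
  an <- stats::anova(fit)
  offsets <- vapply(feats, function(f) {
    v <- long$value[long$region == f]
    gg <- long$gender[long$region == f]
    mean(v[gg == "F"]) - mean(v[gg == "M"])
  }, 0)
  pooled <- colMeans(x)
  structure(list(
    offsets = offsets, pooled_means = pooled,
    gender_means = list(F = pooled + offsets * mean(g == "M"),
                        M = pooled - offsets * mean(g == "F")),
    p_gender_interaction = an["region:gender", "Pr(>F)"],
    p_age = an["age", "Pr(>F)"],
    features = feats, n_controls = sum(ctrl)
  ), class = "gender_model")
}

#' Apply the additive gender correction
#'
#' Aligns each gender to the pooled control mean per region: from every
#' subject's value the control-estimated deviation of their gender from the
#' pooled control mean is subtracted. Applied identically to controls and
#' patients; age and asymmetry features are left untouched. The dataset is
#' marked as corrected, and re-applying a correction to an already
#' corrected dataset is a no-op, so the operation is idempotent for a
#' fixed fitted model. Within each gender stratum, control-versus-patient
#' differences are preserved exactly (a constant is subtracted from every
#' subject of a gender).
#'
#' @param dataset A `feature_dataset`.
#' @param model A `gender_model` fitted on the same (non-asymmetry) feature
#'   space.
#' @return The corrected `feature_dataset`.
#' @export
apply_gender_correction <- function(dataset, model) {
  stopifnot(inherits(dataset, "feature_dataset"),
            inherits(model, "gender_model"))
  if (isTRUE(dataset$gender_corrected)) return(dataset)
  feats <- colnames(dataset$x)[!startsWith(colnames(dataset$x), "asy_")]
  if (!setequal(feats, model$features))
    stopf("feature space mismatch between dataset and gender model")
  x <- dataset$x
  for (g in c("F", "M")) {
    dev <- model$gender_means[[g]][feats] - model$pooled_means[feats]
    sel <- dataset$gender == g
    x[sel, feats] <- sweep(x[sel, feats, drop = FALSE], 2, dev, "-")
  }
  dataset$x <- x
  dataset$gender_corrected <- TRUE
  dataset
}

#' Subset a feature dataset to named features
#'
#' @param dataset A `feature_dataset`.
#' @param features Character vector of feature names to keep, in order.
#' @return The reduced `feature_dataset` with variant `"selected"`.
#' @export
select_features <- function(dataset, features) {
  missing <- setdiff(features, colnames(dataset$x))
  if (length(missing))
    stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
  dataset$x <- dataset$x[, features, drop = FALSE]
  dataset$variant <- "selected"
  dataset
}

#' Read / write a meta-VOI map as YAML
#'
#' The YAML maps each meta-VOI name to the list of its constituent region
#' names (per hemisphere). The default map shipped with the package
#' (`system.file("extdata", "meta_voi_map.yaml", package = "voiclass")`)
#' encodes the twelve standard groupings of [default_meta_voi_map()].
#'
#' @param map Named list, meta-VOI name to constituent region names.
#' @param path File path.
#' @return `read_meta_voi_map` returns the named list.
#' @export
write_meta_voi_map <- function(map, path) {
  yaml::write_yaml(lapply(map, as.list), path)
  invisible(path)
}

#' @rdname write_meta_voi_map
#' @export
read_meta_voi_map <- function(path) {
  m <- lapply(yaml::read_yaml(path), function(x) as.character(unlist(x)))
  dup <- unlist(m)[duplicated(unlist(m))]
  if (length(dup))
    stopf("region(s) assigned to more than one meta-VOI: %s",
          paste(unique(dup), collapse = ", "))
  m
}

#' Write a feature dataset to CSV
#'
#' Columns: subject_id, group, gender, age, then one column per feature.
#'
#' @param dataset A `feature_dataset`.
#' @param path Output path.
#' @export
write_features <- function(dataset, path) {
  out <- data.frame(subject_id = dataset$subject_id,
                    group = as.character(dataset$group),
                    gender = dataset$gender, age = dataset$age,
                    dataset$x, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
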