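#' Feature preset: the published best-discriminating subset
#'
#' The named 6-meta-VOI + 6-asymmetry feature set reported as the best
#' backward-selection result on the original cohort (left mesial
#' temporal/insula, left frontal, left sensorimotor, right parietal, left
#' anterior and posterior cingulate values, plus occipital,
#' striato-thalamic, mesial temporal, orbitofrontal, frontal and
#' cuneus/fusiform/precuneus asymmetries). Shipped as a preset for
#' reproduction-style runs; on synthetic cohorts the selection is re-run
#' instead.
#'
#' @return Character vector of 12 feature names in the meta-VOI space.
#' @export
preset_6r6a_features <- function() {
  c("Mesial_Temporal_Insula_L", "Frontal_Cortex_L", "Sensorimotor_L",
    "Parietal_Lobe_R", "Anterior_Cingulate_L", "Posterior_Cingulate_L",
    "asy_Occipital_Cortex", "asy_Thalamus_Striatum",
    "asy_Mesial_Temporal_Insula", "asy_Orbitofrontal_Cortex",
    "asy_Frontal_Cortex", "asy_Cuneus_Fusiform_Precuneus")
}

#' Pipeline run configuration
#'
#' @param cohort A [cohort_spec()]; its seed is overridden by `seed`.
#' @param variants Dataset variants to evaluate. `"6R+6A"` means: run
#'   stepwise backward elimination on the gender-corrected 24R+12A dataset
#'   and evaluate the selected subset.
#' @param selection_mode `"paper"` (selection on full-sample LOO criterion,
#'   then LOO metrics on the selected set — optimistic, as commonly
#'   reported) or `"nested"` (selection repeated inside every outer fold).
#' @param selection_criterion,selection_min_size,n_perm Passed to
#'   [backward_select()].
#' @param hyperparams An [svm_hyperparams()].
#' @param bootstrap_B Bootstrap replicates for AUC intervals.
#' @param rate_ci_method `"wald"` or `"clopper_pearson"`.
#' @param include_tsum Run the voxel t-sum comparator and paired AUC
#'   comparisons against it.
#' @param tsum Settings for the comparator: `grid_shape`,
#'   `voxels_per_region`, `cerebellum_voxels`, `smoothing_fwhm` (voxel
#'   units of the phantom grid), `n_reference` (control database size),
#'   `n_null` (held-out controls for threshold calibration).
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @return A `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       variants = c("90R", "24R", "90R+45A", "24R+12A",
                                    "6R+6A"),
                       selection_mode = c("paper", "nested"),
                       selection_criterion = "loo_auc",
                       selection_min_size = 6L,
                       n_perm = 10L,
                       hyperparams = svm_hyperparams(),
                       bootstrap_B = 1000L,
                       rate_ci_method = "wald",
                       include_tsum = TRUE,
                       tsum = list(grid_shape = c(16L, 16L, 16L),
                                   voxels_per_region = 8L,
                                   cerebellum_voxels = 32L,
                                   smoothing_fwhm = 2,
                                   n_reference = 25L,
                                   n_null = 40L),
                       seed = 1L) {
  if (!length(variants)) stopf("at least one variant is required")
  structure(list(cohort = cohort, variants = variants,
                 selection_mode = match.arg(selection_mode),
                 selection_criterion = selection_criterion,
                 selection_min_size = selection_min_size, n_perm = n_perm,
                 hyperparams = hyperparams, bootstrap_B = bootstrap_B,
                 rate_ci_method = rate_ci_method,
                 include_tsum = include_tsum, tsum = tsum,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Demo configuration: reduced sizes, same effect structure
#'
#' A quick-running configuration for demonstrations and determinism
#' checks: the generative effect structure is the default one, group sizes
#' and resampling counts are reduced.
#'
#' @param seed Master seed.
#' @param n_controls,n_patients Reduced group sizes.
#' @param effect_scale Multiplier on the default hypometabolism and
#'   asymmetry maps (0 gives a null cohort).
#' @return A `run_config`.
#' @export
demo_run_config <- function(seed = 1L, n_controls = 44L, n_patients = 32L,
                            effect_scale = 1) {
  run_config(
    cohort = cohort_spec(
      n_controls = n_controls, n_patients = n_patients,
      hypometabolism = default_hypometabolism() * effect_scale,
      asymmetry_extra = default_asymmetry_extra() * effect_scale,
      seed = seed),
    n_perm = 5L, bootstrap_B = 200L,
    tsum = list(grid_shape = c(12L, 12L, 12L), voxels_per_region = 4L,
                cerebellum_voxels = 16L, smoothing_fwhm = 1.5,
                n_reference = 15L, n_null = 20L),
    seed = seed)
}

normalize_volume_to_cerebellum <- function(volume, atlas) {
  cb_labels <- atlas$label_map$label[atlas$label_map$is_cerebellum]
  ref <- mean(volume[atlas$labels %in% cb_labels])
  if (!is.finite(ref) || ref <= 0) stopf("non-positive cerebellar reference")
  volume / ref
}

run_tsum_arm <- function(config) {
  ts <- config$tsum
  cohort <- config$cohort
  spec <- atlas_spec(grid_shape = ts$grid_shape,
                     voxels_per_region = ts$voxels_per_region,
                     cerebellum_voxels = ts$cerebellum_voxels)
  atlas <- build_atlas(spec)
  # scale voxel noise so the region-mean noise budget matches the feature path
  vox_cohort <- cohort
  vox_cohort$voxel_noise_sd <- cohort$voxel_noise_sd *
    sqrt(ts$voxels_per_region / cohort$voxels_per_region)
  class(vox_cohort) <- "cohort_spec"
  vc <- simulate_volume_cohort(atlas, vox_cohort)
  # independent control database + held-out nulls for threshold calibration
  ref_args <- unclass(vox_cohort)
  ref_args$n_controls <- ts$n_reference + ts$n_null
  ref_args$n_patients <- 4L
  ref_args$seed <- subject_seed(config$seed, 9001L)
  ref_args <- ref_args[intersect(names(ref_args), names(formals(cohort_spec)))]
  ref_cohort <- do.call(cohort_spec, ref_args)
  rc <- simulate_volume_cohort(atlas, ref_cohort)
  ref_ctrl <- which(rc$metadata$group == "control")
  norm <- function(v) normalize_volume_to_cerebellum(v, atlas)
  db_idx <- ref_ctrl[seq_len(ts$n_reference)]
  null_idx <- ref_ctrl[ts$n_reference + seq_len(ts$n_null)]
  reference <- fit_control_reference(
    lapply(rc$volumes[db_idx], function(v)
      gaussian_smooth(norm(v), ts$smoothing_fwhm)),
    rc$metadata$age[db_idx], min_controls = min(10L, ts$n_reference))
  lm_hypo <- atlas$label_map$region_name %in% names(cohort$hypometabolism)
  mask <- array(FALSE, dim(atlas$labels))
  mask[atlas$labels %in% atlas$label_map$label[lm_hypo]] <- TRUE
  score_one <- function(v, age) {
    tm <- t_map(norm(v), age, reference, smoothing_fwhm = ts$smoothing_fwhm)
    tsum_score(tm, tsum_config(mask, abnormality_threshold = 1,
                               voxel_t_floor = 0))$score
  }
  null_scores <- mapply(score_one, rc$volumes[null_idx],
                        rc$metadata$age[null_idx])
  threshold <- calibrate_tsum_threshold(null_scores)
  scores <- mapply(score_one, vc$volumes, vc$metadata$age)
  list(scores = unname(scores), metadata = vc$metadata,
       threshold = threshold, mask_voxels = sum(mask),
       null_scores = unname(null_scores))
}

report_from_scores <- function(scores, labels, config, seed,
                               threshold = "optimal") {
  rep <- diagnostic_report(scores, labels, threshold = threshold,
                           rate_ci_method = config$rate_ci_method,
                           B = config$bootstrap_B, seed = seed)
  ci3 <- function(x) list(est = unname(x[1]), lo = unname(x[2]),
                          hi = unname(x[3]))
  list(confusion = rep$confusion[c("TP", "FN", "FP", "TN")],
       threshold = rep$threshold,
       accuracy = ci3(rep$accuracy), sensitivity = ci3(rep$sensitivity),
       specificity = ci3(rep$specificity), lr_plus = ci3(rep$lr_plus),
       lr_minus = ci3(rep$lr_minus), odds_ratio = ci3(rep$odds_ratio),
       auc = ci3(rep$auc))
}

#' Run the end-to-end study on a synthetic cohort
#'
#' Simulates (or ingests) the cohort, builds each requested dataset
#' variant with gender correction estimated on controls, produces
#' leave-one-out SVM decision scores (with backward feature elimination
#' for the `"6R+6A"` variant), evaluates every diagnostic accuracy
#' statistic per variant, optionally runs the voxel t-sum comparator on a
#' matched phantom cohort and compares each variant's AUC to it with the
#' paired z-test, and writes `report.json`, per-variant score CSVs and a
#' human-readable `summary.md` into `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param feature_cohort Optionally, an existing `feature_cohort` to use
#'   instead of simulating one (its metadata must match the cohort spec if
#'   the t-sum arm is enabled).
#' @return The run report (list), invisibly written as JSON.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         feature_cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  cohort$seed <- as.integer(subject_seed(config$seed, 1L))
  class(cohort) <- "cohort_spec"
  config$cohort <- cohort
  fc <- feature_cohort %||% simulate_feature_cohort(cohort)
  labels <- fc$metadata$group == "patient"

  ds90 <- assemble_dataset(fc, "90R")
  ds24 <- assemble_dataset(fc, "24R")
  gm_region <- fit_gender_model(ds90)
  gm_meta <- fit_gender_model(ds24)
  corrected <- list(
    "90R" = apply_gender_correction(ds90, gm_region),
    "24R" = apply_gender_correction(ds24, gm_meta),
    "90R+45A" = apply_gender_correction(assemble_dataset(fc, "90R+45A"),
                                        gm_region),
    "24R+12A" = apply_gender_correction(assemble_dataset(fc, "24R+12A"),
                                        gm_meta))

  variant_out <- list()
  score_sets <- list()
  for (v in config$variants) {
    if (v == "6R+6A") {
      base <- corrected[["24R+12A"]]
      if (config$selection_mode == "nested") {
        res <- loo_with_selection(base, config$selection_criterion,
                                  config$selection_min_size,
                                  config$hyperparams, n_perm = config$n_perm,
                                  seed = subject_seed(config$seed, 31L))
        selected <- sort(unique(unlist(attr(res, "selected_per_fold"))))
        trace <- NULL
      } else {
        bs <- backward_select(base, config$selection_criterion,
                              config$selection_min_size, config$hyperparams,
                              n_perm = config$n_perm,
                              seed = subject_seed(config$seed, 31L))
        selected <- bs$selected
        trace <- bs$trace
        res <- loo_scores(select_features(base, selected), config$hyperparams)
      }
      extra <- list(selected_features = selected,
                    selection_mode = config$selection_mode)
      if (!is.null(trace)) extra$selection_trace <- trace
    } else {
      if (!v %in% names(corrected)) stopf("unknown variant '%s'", v)
      res <- loo_scores(corrected[[v]], config$hyperparams)
      extra <- NULL
    }
    score_sets[[v]] <- res
    variant_out[[v]] <- c(
      report_from_scores(res$decision_score, labels, config,
                         seed = subject_seed(config$seed, 101L)),
      list(n_features = if (v == "6R+6A") length(extra$selected_features)
           else ncol(corrected[[v]]$x)),
      extra)
  }

  comparisons <- list()
  tsum_out <- NULL
  if (isTRUE(config$include_tsum)) {
    arm <- run_tsum_arm(config)
    tsum_out <- c(report_from_scores(arm$scores, labels, config,
                                     seed = subject_seed(config$seed, 102L),
                                     threshold = arm$threshold),
                  list(calibrated_threshold = arm$threshold,
                       mask_voxels = arm$mask_voxels))
    for (v in names(score_sets)) {
      cmp <- paired_auc_z(score_sets[[v]]$decision_score, arm$scores, labels)
      comparisons[[paste0(v, "_vs_tsum")]] <-
        list(auc_a = cmp$auc_a, auc_b = cmp$auc_b, se_diff = cmp$se_diff,
             z = cmp$z, p = cmp$p)
    }
  }

  report <- list(
    seed = config$seed,
    n_controls = cohort$n_controls, n_patients = cohort$n_patients,
    gender_model = list(
      region = list(p_gender_interaction = gm_region$p_gender_interaction,
                    p_age = gm_region$p_age),
      meta = list(p_gender_interaction = gm_meta$p_gender_interaction,
                  p_age = gm_meta$p_age)),
    variants = variant_out,
    tsum = tsum_out,
    comparisons = comparisons)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    for (v in names(score_sets)) {
      sc <- as.data.frame(score_sets[[v]])
      # full precision so cached scores reproduce threshold ties exactly
      sc$decision_score <- sprintf("%.17g", sc$decision_score)
      utils::write.csv(sc,
                       file.path(out_dir, paste0("scores_",
                                                 gsub("[+]", "plus", v),
                                                 ".csv")),
                       row.names = FALSE)
    }
    writeLines(format_summary_table(report), file.path(out_dir, "summary.md"))
  }
  invisible(report)
}

format_summary_table <- function(report) {
  cols <- c(names(report$variants),
            if (!is.null(report$tsum)) "tsum")
  get <- function(col) {
    if (col == "tsum") report$tsum else report$variants[[col]]
  }
  fmt <- function(x) sprintf("%.2f (%.2f-%.2f)", x$est, x$lo, x$hi)
  rows <- c("accuracy", "sensitivity", "specificity", "lr_plus", "lr_minus",
            "odds_ratio", "auc")
  lines <- c(paste(c("| measure", cols, ""), collapse = " | "),
             paste(c("|", rep("---|", length(cols) + 1)), collapse = ""))
  for (r in rows) {
    cells <- vapply(cols, function(cl) fmt(get(cl)[[r]]), "")
    lines <- c(lines, paste(c(paste0("| ", r), cells, ""), collapse = " | "))
  }
  c(sprintf("# Classification summary (n = %d controls, %d patients, seed %d)",
            report$n_controls, report$n_patients, report$seed),
    "", lines)
}
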