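#' Default per-region baseline uptake pattern
#'
#' Baseline mean uptake per region in cerebellum-relative units (the
#' cerebellar reference is fixed at 1). Cortical and subcortical gray-matter
#' regions sit between roughly 1.0 and 1.3 times cerebellum, with a fixed
#' deterministic spread across regions so that the regional profile is not
#' flat.
#'
#' @param region_names Character vector of region names (cerebellum added if
#'   absent).
#' @return Named numeric vector of baseline means, including `Cerebelum`.
#' @export
default_baseline_uptake <- function(region_names = aal_region_table()$region_name) {
  region_names <- setdiff(region_names, "Cerebelum")
  i <- seq_along(region_names)
  b <- 1.05 + 0.25 * ((i * 7L) %% 11L) / 10
  names(b) <- region_names
  c(b, Cerebelum = 1.0)
}

#' Default patient hypometabolism pattern
#'
#' Fractional reductions of regional uptake in patients relative to
#' controls, concentrated in the precuneus, posterior cingulate,
#' temporo-parietal and frontal cortices — the canonical pattern of
#' prodromal Alzheimer-type hypometabolism. Magnitudes are synthetic-model
#' defaults chosen to produce discrimination difficulty comparable to a
#' real MCI-converter cohort; they are not measured values.
#'
#' @return Named numeric vector, region name to fractional reduction.
#' @export
default_hypometabolism <- function() {
  c(Precuneus = 0.12, Cingulum_Post = 0.13, Parietal_Inf = 0.10,
    Parietal_Sup = 0.09, Angular = 0.08, SupraMarginal = 0.07,
    Temporal_Mid = 0.07, Temporal_Inf = 0.06, Temporal_Sup = 0.05,
    Hippocampus = 0.06, ParaHippocampal = 0.06, Amygdala = 0.05,
    Insula = 0.04, Frontal_Mid = 0.05, Frontal_Sup = 0.05,
    Frontal_Sup_Medial = 0.05, Cingulum_Ant = 0.04, Cuneus = 0.04,
    Fusiform = 0.05)
}

#' Default left-predominant extra reduction in patients
#'
#' Additional fractional reduction applied to the left homolog only, giving
#' patients a left-predominant inter-hemispheric asymmetry in mesial
#' temporal, frontal, sensorimotor and cingulate regions, plus milder
#' asymmetries in occipital, striato-thalamic, orbitofrontal and
#' cuneus/fusiform/precuneus territories.
#'
#' @return Named numeric vector, region name to extra left-sided reduction.
#' @export
default_asymmetry_extra <- function() {
  c(ParaHippocampal = 0.04, Hippocampus = 0.04, Amygdala = 0.03,
    Insula = 0.03, Frontal_Mid = 0.03, Frontal_Sup = 0.03,
    Frontal_Sup_Medial = 0.03, Postcentral = 0.03, Precentral = 0.03,
    Supp_Motor_Area = 0.03, Cingulum_Ant = 0.03, Cingulum_Post = 0.04,
    Parietal_Inf = 0.02, Parietal_Sup = 0.02,
    Calcarine = 0.02, Lingual = 0.02, Occipital_Mid = 0.02,
    Thalamus = 0.02, Putamen = 0.02, Caudate = 0.02,
    Frontal_Med_Orb = 0.02, Frontal_Sup_Orb = 0.02, Frontal_Inf_Orb = 0.02,
    Cuneus = 0.02, Fusiform = 0.02, Precuneus = 0.02)
}

#' Default female-vs-male regional offsets
#'
#' Additive offsets (cerebellum-relative units) applied to female subjects,
#' emulating the region-by-gender interaction observed in control FDG data.
#'
#' @return Named numeric vector, region name to additive offset.
#' @export
default_gender_offset <- function() {
  c(Cingulum_Ant = 0.08, Frontal_Mid = 0.06, Frontal_Sup = 0.06,
    Frontal_Sup_Medial = 0.04, Occipital_Mid = -0.06, Calcarine = -0.04,
    Thalamus = 0.04, Temporal_Mid = 0.04, Precuneus = 0.04)
}

#' Specify a synthetic cohort
#'
#' All parameters of the synthetic generative model for a two-group
#' (control / MCI-converter) FDG-PET cohort. Defaults reproduce the study
#' conditions: 109 controls (57 women, 52 men, ages 52-83) and 62 patients
#' (34 women, 28 men, ages 54-86), an AD-like hypometabolic pattern with
#' left-predominant asymmetry, gender-dependent regional offsets, a
#' log-normal subject-level global scale (injected-dose analog), and
#' additive Gaussian voxel noise.
#'
#' The voxel value model is
#' `scale * (baseline * (1 - hypo) * (1 - asym_if_left) + gender_offset) + noise`
#' for patients (controls have zero hypo/asym); cerebellar regions never
#' receive hypometabolism or asymmetry effects.
#'
#' @param n_controls,n_patients Group sizes.
#' @param baseline_uptake Named per-region positive baseline means, must
#'   include `Cerebelum`.
#' @param global_scale_sd SD of the log of the subject-level multiplicative
#'   global scale.
#' @param gender_offset Named signed additive offsets applied to females.
#' @param hypometabolism Named fractional reductions in patients, in [0,1).
#' @param asymmetry_extra Named extra fractional reductions applied to the
#'   left homolog only, in patients, in [0,1).
#' @param voxel_noise_sd SD of additive Gaussian voxel noise.
#' @param region_noise_sd SD of additive noise on normalized region values
#'   for the direct feature path; default `voxel_noise_sd / sqrt(voxels_per_region)`
#'   scaled by the cerebellar baseline, matching the voxel path's region-mean
#'   noise budget.
#' @param voxels_per_region Nominal voxels per VOI used by the feature path.
#' @param age_range_controls,age_range_patients Year bounds.
#' @param gender_split Fraction of women per group,
#'   `c(control = , patient = )`.
#' @param seed Integer master seed; each subject derives its own stream.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 109L, n_patients = 62L,
                        baseline_uptake = default_baseline_uptake(),
                        global_scale_sd = 0.15,
                        gender_offset = default_gender_offset(),
                        hypometabolism = default_hypometabolism(),
                        asymmetry_extra = default_asymmetry_extra(),
                        voxel_noise_sd = 1.8,
                        region_noise_sd = NULL,
                        voxels_per_region = 64L,
                        age_range_controls = c(52, 83),
                        age_range_patients = c(54, 86),
                        gender_split = c(control = 57 / 109, patient = 34 / 62),
                        seed = 1L) {
  if (any(baseline_uptake <= 0)) stopf("all baseline means must be > 0")
  if (!"Cerebelum" %in% names(baseline_uptake))
    stopf("baseline_uptake must include a 'Cerebelum' entry")
  for (nm in c("hypometabolism", "asymmetry_extra")) {
    v <- get(nm)
    if (length(v) && (any(v < 0) || any(v >= 1)))
      stopf("%s fractions must lie in [0, 1)", nm)
  }
  if (global_scale_sd < 0 || voxel_noise_sd < 0)
    stopf("spread parameters must be non-negative")
  n_f <- round(c(n_controls, n_patients) * gender_split[c("control", "patient")])
  if (any(n_f < 2) || any(c(n_controls, n_patients) - n_f < 2))
    stopf("need at least 2 subjects per gender in each group")
  b_cb <- unname(baseline_uptake["Cerebelum"])
  if (is.null(region_noise_sd))
    region_noise_sd <- voxel_noise_sd / sqrt(voxels_per_region) / b_cb
  structure(list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    baseline_uptake = baseline_uptake, global_scale_sd = global_scale_sd,
    gender_offset = gender_offset, hypometabolism = hypometabolism,
    asymmetry_extra = asymmetry_extra, voxel_noise_sd = voxel_noise_sd,
    region_noise_sd = region_noise_sd,
    voxels_per_region = as.integer(voxels_per_region),
    age_range_controls = age_range_controls,
    age_range_patients = age_range_patients,
    gender_split = gender_split, seed = as.integer(seed)
  ), class = "cohort_spec")
}

cohort_metadata <- function(cohort) {
  n <- cohort$n_controls + cohort$n_patients
  group <- rep(c("control", "patient"), c(cohort$n_controls, cohort$n_patients))
  nf_c <- round(cohort$n_controls * cohort$gender_split[["control"]])
  nf_p <- round(cohort$n_patients * cohort$gender_split[["patient"]])
  gender <- c(rep(c("F", "M"), c(nf_c, cohort$n_controls - nf_c)),
              rep(c("F", "M"), c(nf_p, cohort$n_patients - nf_p)))
  seeds <- vapply(seq_len(n), function(i) subject_seed(cohort$seed, i), 1L)
  age <- numeric(n)
  rng <- lapply(seq_len(n), function(i) {
    rr <- if (group[i] == "control") cohort$age_range_controls else cohort$age_range_patients
    with_seed(seeds[i], {
      a <- stats::runif(1, rr[1], rr[2])
      g <- exp(stats::rnorm(1, 0, cohort$global_scale_sd))
      c(a, g)
    })
  })
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, gender = gender,
    age = round(vapply(rng, `[`, 0, 1), 1),
    global_scale = vapply(rng, `[`, 0, 2),
    seed = seeds,
    stringsAsFactors = FALSE
  )
}

# Expected (noise-free) region mean for one subject, before global scaling.
region_model_mean <- function(cohort, region, hemisphere, is_cerebellum,
                              group, gender) {
  b <- cohort$baseline_uptake[[region]]
  h <- if (group == "patient" && !is_cerebellum)
    cohort$hypometabolism[region] else NA
  a <- if (group == "patient" && !is_cerebellum && identical(hemisphere, "L"))
    cohort$asymmetry_extra[region] else NA
  d <- if (gender == "F") cohort$gender_offset[region] else NA
  h <- if (is.na(h)) 0 else unname(h)
  a <- if (is.na(a)) 0 else unname(a)
  d <- if (is.na(d)) 0 else unname(d)
  b * (1 - h) * (1 - a) + d
}

check_effect_regions <- function(cohort, atlas_regions, cereb_regions) {
  for (nm in c("hypometabolism", "asymmetry_extra", "gender_offset")) {
    bad <- setdiff(names(cohort[[nm]]), atlas_regions)
    if (length(bad))
      stopf("%s names region(s) absent from the atlas: %s", nm,
            paste(bad, collapse = ", "))
  }
  bad <- intersect(c(names(cohort$hypometabolism), names(cohort$asymmetry_extra)),
                   cereb_regions)
  if (length(bad))
    stopf("cerebellar reference regions cannot carry disease effects: %s",
          paste(unique(bad), collapse = ", "))
}

#' Simulate a cohort of labeled phantom volumes
#'
#' Draws one intensity volume per subject on the atlas grid according to the
#' generative model of [cohort_spec()]. Each subject uses its own RNG stream
#' derived from the master seed and the subject index, so results do not
#' depend on generation order.
#'
#' @param atlas A `labeled_volume` from [build_atlas()].
#' @param cohort A [cohort_spec()].
#' @return A `volume_cohort`: list with `volumes` (named list of 3D arrays),
#'   `metadata` (subject data frame) and `atlas`.
#' @export
simulate_volume_cohort <- function(atlas, cohort) {
  stopifnot(inherits(atlas, "labeled_volume"), inherits(cohort, "cohort_spec"))
  lm <- atlas$label_map
  missing_b <- setdiff(lm$region_name, names(cohort$baseline_uptake))
  if (length(missing_b))
    stopf("baseline_uptake missing region(s): %s", paste(missing_b, collapse = ", "))
  check_effect_regions(cohort, unique(lm$region_name),
                       unique(lm$region_name[lm$is_cerebellum]))
  md <- cohort_metadata(cohort)
  voxel_idx <- lapply(lm$label, function(l) which(atlas$labels == l))
  vols <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    vol <- array(0, dim = dim(atlas$labels))
    with_seed(md$seed[i], {
      stats::runif(1); stats::rnorm(1)  # age and scale draws, fixed in metadata
      g <- md$global_scale[i]
      for (k in seq_len(nrow(lm))) {
        m <- region_model_mean(cohort, lm$region_name[k], lm$hemisphere[k],
                               lm$is_cerebellum[k], md$group[i], md$gender[i])
        nvox <- length(voxel_idx[[k]])
        noise <- if (cohort$voxel_noise_sd > 0)
          stats::rnorm(nvox, 0, cohort$voxel_noise_sd) else 0
        vol[voxel_idx[[k]]] <- g * m + noise
      }
    })
    vols[[i]] <- vol
  }
  names(vols) <- md$subject_id
  structure(list(volumes = vols, metadata = md, atlas = atlas),
            class = "volume_cohort")
}

#' Simulate cerebellum-normalized VOI tables directly
#'
#' Fast path that skips the voxel layer: emits per-subject, per-region
#' normalized values drawn from the same generative model with region-level
#' Gaussian noise. With zero noise it agrees region-by-region with
#' extracting and normalizing simulated volumes.
#'
#' @param cohort A [cohort_spec()].
#' @param region_names Bilateral region names to emit (default: every
#'   non-cerebellar region in `baseline_uptake`).
#' @return A `feature_cohort`: list with `tables` (named list of VOI data
#'   frames with columns region_name, hemisphere, voxel_count, nv,
#'   is_cerebellum) and `metadata`.
#' @export
simulate_feature_cohort <- function(cohort, region_names = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (is.null(region_names))
    region_names <- setdiff(names(cohort$baseline_uptake), "Cerebelum")
  missing_b <- setdiff(region_names, names(cohort$baseline_uptake))
  if (length(missing_b))
    stopf("baseline_uptake missing region(s): %s", paste(missing_b, collapse = ", "))
  check_effect_regions(cohort, c(region_names, "Cerebelum"), "Cerebelum")
  b_cb <- unname(cohort$baseline_uptake["Cerebelum"])
  md <- cohort_metadata(cohort)
  grid <- data.frame(
    region_name = c(rep(region_names, each = 2L), "Cerebelum", "Cerebelum"),
    hemisphere = c(rep(c("L", "R"), length(region_names)), "L", "R"),
    is_cerebellum = c(rep(FALSE, 2L * length(region_names)), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  grid$voxel_count <- ifelse(grid$is_cerebellum, 4L, 1L) * cohort$voxels_per_region
  tables <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    mu <- vapply(seq_len(nrow(grid)), function(k)
      region_model_mean(cohort, grid$region_name[k], grid$hemisphere[k],
                        grid$is_cerebellum[k], md$group[i], md$gender[i]),
      0) / b_cb
    nv <- with_seed(md$seed[i], {
      stats::runif(1); stats::rnorm(1)  # keep stream aligned with volume path
      mu + if (cohort$region_noise_sd > 0)
        stats::rnorm(length(mu), 0, cohort$region_noise_sd) else 0
    })
    tab <- grid
    tab$raw_mean <- NA_real_
    tab$nv <- nv
    tables[[i]] <- tab
  }
  names(tables) <- md$subject_id
  structure(list(tables = tables, metadata = md), class = "feature_cohort")
}

#' Write / read a cohort specification as YAML
#' @param cohort A [cohort_spec()].
#' @param path File path.
#' @return `read_cohort_spec` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(cohort, path) {
  x <- unclass(cohort)
  # named numeric vectors must become YAML maps, not bare sequences
  for (nm in c("baseline_uptake", "gender_offset", "hypometabolism",
               "asymmetry_extra", "gender_split"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("baseline_uptake", "gender_offset", "hypometabolism",
               "asymmetry_extra", "gender_split")) {
    v <- unlist(x[[nm]])
    x[nm] <- list(if (is.null(v)) numeric() else v)
  }
  for (nm in c("age_range_controls", "age_range_patients"))
    x[[nm]] <- unlist(x[[nm]])
  do.call(cohort_spec, x[intersect(names(x), names(formals(cohort_spec)))])
}
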