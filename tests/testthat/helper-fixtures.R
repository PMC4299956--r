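# Small fixtures shared across test files; everything is generated in code.

tiny_atlas_spec <- function(n_regions = 2, grid = c(8L, 8L, 8L),
                            vox = 8L, cereb = 16L) {
  atlas_spec(grid_shape = grid,
             regions = data.frame(region_name = LETTERS[seq_len(n_regions)],
                                  meta_voi = NA_character_),
             voxels_per_region = vox, cerebellum_voxels = cereb)
}

tiny_cohort <- function(n_controls = 6L, n_patients = 6L,
                        hypo = c(A = 0.15), asym = numeric(),
                        offset = numeric(), noise = 0,
                        scale_sd = 0, region_noise = NULL, seed = 1L,
                        baseline = c(A = 1.2, B = 1.1, Cerebelum = 1)) {
  cohort_spec(n_controls = n_controls, n_patients = n_patients,
              baseline_uptake = baseline,
              hypometabolism = hypo, asymmetry_extra = asym,
              gender_offset = offset, voxel_noise_sd = noise,
              region_noise_sd = region_noise,
              global_scale_sd = scale_sd,
              gender_split = c(control = 0.5, patient = 0.5), seed = seed)
}

# two Gaussian clusters with a configurable number of informative features
gaussian_dataset <- function(n_per_class = 20L, d = 10L, n_signal = 1L,
                             effect = 3, seed = 1L) {
  n <- 2L * n_per_class
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  grp <- rep(c("control", "patient"), each = n_per_class)
  x[grp == "patient", seq_len(n_signal)] <-
    x[grp == "patient", seq_len(n_signal)] + effect
  structure(list(x = x, group = factor(grp, c("control", "patient")),
                 gender = rep(c("F", "M"), n / 2),
                 age = rep(60, n),
                 subject_id = sprintf("T%03d", seq_len(n)),
                 variant = "custom"),
            class = "feature_dataset")
}

region_mean_from_volume <- function(vol, atlas, region, hemi) {
  lm <- atlas$label_map
  lab <- lm$label[lm$region_name == region & lm$hemisphere == hemi]
  mean(vol[atlas$labels == lab])
}
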