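make_voi_table <- function(regions, nv, vox = 100L) {
  n <- length(regions)
  data.frame(region_name = rep(regions, each = 2),
             hemisphere = rep(c("L", "R"), n),
             voxel_count = rep_len(vox, 2 * n),
             raw_mean = rep(nv, each = 2) * 2,
             nv = rep(nv, each = 2),
             is_cerebellum = FALSE,
             stringsAsFactors = FALSE)
}

test_that("meta-VOI merging is the voxel-count-weighted mean", {
  t <- data.frame(region_name = c("A", "B", "A", "B"),
                  hemisphere = c("L", "L", "R", "R"),
                  voxel_count = c(100L, 300L, 100L, 300L),
                  raw_mean = c(0.9, 1.1, 0.9, 1.1),
                  nv = c(0.9, 1.1, 0.9, 1.1),
                  is_cerebellum = FALSE, stringsAsFactors = FALSE)
  m <- merge_meta_vois(t, list(M = c("A", "B")))
  expect_equal(m$nv[m$hemisphere == "L"], 1.05)
  expect_equal(m$voxel_count[m$hemisphere == "L"], 400L)

  t$voxel_count <- rep(50L, 4)
  t$nv <- c(0.8, 1.0, 0.8, 1.0)
  expect_equal(merge_meta_vois(t, list(M = c("A", "B")))$nv[1], 0.9)

  single <- merge_meta_vois(t, list(OnlyA = "A"))
  expect_equal(single$nv[single$hemisphere == "L"], 0.8)

  expect_error(merge_meta_vois(t, list(M = c("A", "Zed"))), "Zed")
})

test_that("asymmetry index follows its defining formula and symmetries", {
  expect_equal(asymmetry_index(1, 1), 0)
  expect_equal(asymmetry_index(0.8, 1.0), 0.1111111, tolerance = 1e-6)
  set.seed(3)
  l <- runif(50, 0.1, 2); r <- runif(50, 0.1, 2)
  expect_equal(asymmetry_index(l, r), asymmetry_index(r, l))
  expect_equal(asymmetry_index(3 * l, 3 * r), asymmetry_index(l, r),
               tolerance = 1e-12)
  expect_true(all(asymmetry_index(l, r) >= 0 & asymmetry_index(l, r) <= 1))
  expect_error(asymmetry_index(0, 0), "positive")
})

test_that("meta merging commutes with extraction on noise-free volumes", {
  spec <- atlas_spec(grid_shape = c(12L, 12L, 12L),
                     regions = data.frame(region_name = c("A", "B", "C"),
                                          meta_voi = c("M", "M", NA)),
                     voxels_per_region = c(8L, 24L, 8L), cerebellum_voxels = 16L)
  at <- build_atlas(spec)
  co <- cohort_spec(n_controls = 4, n_patients = 4,
                    baseline_uptake = c(A = 1.3, B = 0.9, C = 1.1, Cerebelum = 1),
                    hypometabolism = c(A = 0.2), asymmetry_extra = numeric(),
                    gender_offset = numeric(), voxel_noise_sd = 0,
                    global_scale_sd = 0.1,
                    gender_split = c(control = 0.5, patient = 0.5), seed = 4)
  vc <- simulate_volume_cohort(at, co)
  tab <- normalize_to_cerebellum(
    extract_voi_means(vc$volumes[[5]], at$labels, at$label_map))
  merged <- merge_meta_vois(tab, list(M = c("A", "B")))
  # oracle: extract from a label volume where A and B share one label
  labels2 <- at$labels
  lmA <- at$label_map
  for (h in c("L", "R")) {
    labA <- lmA$label[lmA$region_name == "A" & lmA$hemisphere == h]
    labB <- lmA$label[lmA$region_name == "B" & lmA$hemisphere == h]
    labels2[labels2 == labB] <- labA
  }
  lm2 <- lmA[lmA$region_name != "B", ]
  lm2$region_name[lm2$region_name == "A"] <- "M"
  direct <- normalize_to_cerebellum(
    extract_voi_means(vc$volumes[[5]], labels2, lm2))
  for (h in c("L", "R"))
    expect_equal(merged$nv[merged$region_name == "M" & merged$hemisphere == h],
                 direct$nv[direct$region_name == "M" & direct$hemisphere == h],
                 tolerance = 1e-12)
})

test_that("dataset variants have the documented shapes and names", {
  co <- cohort_spec(n_controls = 5, n_patients = 5, seed = 2)
  fc <- simulate_feature_cohort(co)
  expect_identical(dim(assemble_dataset(fc, "90R")$x), c(10L, 90L))
  expect_identical(dim(assemble_dataset(fc, "24R")$x), c(10L, 24L))
  expect_identical(dim(assemble_dataset(fc, "90R+45A")$x), c(10L, 135L))
  d36 <- assemble_dataset(fc, "24R+12A")
  expect_identical(dim(d36$x), c(10L, 36L))
  expect_false(any(grepl("Cerebelum", colnames(d36$x))))
  custom <- assemble_dataset(fc, "custom", features = preset_6r6a_features())
  expect_identical(colnames(custom$x), preset_6r6a_features())
  expect_identical(ncol(custom$x), 12L)
  expect_error(assemble_dataset(fc, "custom", features = "NotAFeature"),
               "NotAFeature")
})

test_that("gender model recovers a known offset and flags the interaction", {
  delta <- 0.08
  co <- cohort_spec(n_controls = 400, n_patients = 4,
                    baseline_uptake = c(A = 1.2, B = 1.1, C = 1.0, Cerebelum = 1),
                    hypometabolism = numeric(), asymmetry_extra = numeric(),
                    gender_offset = c(A = delta), voxel_noise_sd = 0,
                    region_noise_sd = 0.05, global_scale_sd = 0,
                    gender_split = c(control = 0.5, patient = 0.5), seed = 12)
  fc <- simulate_feature_cohort(co, c("A", "B", "C"))
  ds <- assemble_dataset(fc, "custom",
                         features = c("A_L", "A_R", "B_L", "B_R", "C_L", "C_R"))
  gm <- fit_gender_model(ds)
  se <- 0.05 * sqrt(1 / 200 + 1 / 200)
  expect_lt(abs(gm$offsets[["A_L"]] - delta), 3 * se)
  expect_lt(abs(gm$offsets[["B_L"]]), 3 * se)
  expect_lt(gm$p_gender_interaction, 0.01)
  expect_gt(gm$p_age, 0.01)  # generator has no age slope
})

test_that("gender correction equalizes genders, preserves group differences, and is idempotent", {
  co <- cohort_spec(n_controls = 60, n_patients = 40, seed = 21)
  fc <- simulate_feature_cohort(co)
  ds <- assemble_dataset(fc, "24R")
  gm <- fit_gender_model(ds)
  cor1 <- apply_gender_correction(ds, gm)
  cor2 <- apply_gender_correction(cor1, gm)
  expect_equal(cor1$x, cor2$x, tolerance = 1e-12)
  # within each gender stratum the control-vs-patient difference is exact
  for (gg in c("F", "M")) {
    sel <- ds$gender == gg
    pat <- ds$group == "patient" & sel
    ctl <- ds$group == "control" & sel
    expect_equal(colMeans(ds$x[pat, ]) - colMeans(ds$x[ctl, ]),
                 colMeans(cor1$x[pat, ]) - colMeans(cor1$x[ctl, ]),
                 tolerance = 1e-10)
  }
  # control gender means align after correction
  ctrl <- ds$group == "control"
  g <- ds$gender[ctrl]
  before <- colMeans(ds$x[ctrl, ][g == "F", ]) - colMeans(ds$x[ctrl, ][g == "M", ])
  after <- colMeans(cor1$x[ctrl, ][g == "F", ]) - colMeans(cor1$x[ctrl, ][g == "M", ])
  expect_lt(max(abs(after)), 1e-10)
  expect_gt(max(abs(before)), 0.01)

  zero <- gm
  zero$offsets[] <- 0
  zero$gender_means <- list(F = zero$pooled_means, M = zero$pooled_means)
  expect_equal(apply_gender_correction(ds, zero)$x, ds$x)

  ds2 <- assemble_dataset(fc, "90R")
  expect_error(apply_gender_correction(ds2, gm), "mismatch")
})

test_that("the shipped meta-VOI map file matches the in-code default", {
  path <- system.file("extdata", "meta_voi_map.yaml", package = "voiclass")
  expect_true(nzchar(path))
  expect_identical(read_meta_voi_map(path), default_meta_voi_map())
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_meta_voi_map(default_meta_voi_map(), tmp)
  expect_identical(read_meta_voi_map(tmp), default_meta_voi_map())
})

test_that("single-gender controls are rejected", {
  ds <- gaussian_dataset(n_per_class = 6)
  ds$gender <- rep("F", length(ds$gender))
  expect_error(fit_gender_model(ds), "single gender")
})
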