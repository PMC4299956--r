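#' Separable Gaussian smoothing of a volume
#'
#' Isotropic Gaussian filter applied as three 1D convolutions with a kernel
#' truncated at three standard deviations and renormalized at the edges.
#' `fwhm = 0` is the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm Full width at half maximum, in voxel-size units.
#' @param voxel_size Edge length of a voxel in the same units as `fwhm`
#'   (default 1).
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm, voxel_size = 1) {
  if (fwhm <= 0) return(volume)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  v <- volume
  # convolve along each axis in turn; aperm keeps the axis order straight
  for (ax in 1:3) {
    v <- aperm(apply(v, setdiff(1:3, ax), function(line) {
      n <- length(line)
      out <- numeric(n)
      for (i in seq_len(n)) {
        j <- max(1L, i - r):min(n, i + r)
        w <- k[j - i + r + 1L]
        out[i] <- sum(line[j] * w) / sum(w)
      }
      out
    }), append(2:3, 1, after = ax - 1))
  }
  v
}

#' Fit the voxel-wise control reference with age adjustment
#'
#' Per-voxel ordinary least squares of intensity on age over a database of
#' control volumes (globally normalized beforehand, e.g. to the cerebellar
#' reference). Residual standard deviations are floored at a low quantile
#' of their own voxel-wise distribution to prevent t-value blow-ups at
#' near-noiseless voxels. A zero-variance age vector drops the slope with a
#' warning (mean/SD model).
#'
#' @param control_volumes List of 3D arrays on a common grid.
#' @param ages Numeric vector of control ages.
#' @param sd_floor_quantile Quantile of the voxel-wise residual-SD
#'   distribution used as the floor (default 0.1).
#' @param min_controls Minimum database size (default 10).
#' @return A `control_reference`: intercept, slope, residual SD arrays plus
#'   age statistics and degrees of freedom.
#' @export
fit_control_reference <- function(control_volumes, ages,
                                  sd_floor_quantile = 0.1,
                                  min_controls = 10L) {
  n <- length(control_volumes)
  if (n < min_controls)
    stopf("control database needs at least %d volumes (got %d)", min_controls, n)
  if (length(ages) != n) stopf("one age per control volume required")
  dims <- dim(control_volumes[[1]])
  if (!all(vapply(control_volumes, function(v) identical(dim(v), dims), TRUE)))
    stopf("control volumes must share a grid")
  y <- matrix(unlist(control_volumes, use.names = FALSE), ncol = n)
  age_mean <- mean(ages)
  ac <- ages - age_mean
  sxx <- sum(ac^2)
  degenerate <- sxx <= .Machine$double.eps * n
  if (degenerate) {
    warning("age vector has zero variance; using a mean/SD reference model",
            call. = FALSE)
    slope <- numeric(nrow(y))
    intercept <- rowMeans(y)
    df <- n - 1L
    resid <- y - intercept
  } else {
    slope <- (y %*% ac) / sxx
    intercept <- rowMeans(y)
    df <- n - 2L
    resid <- y - intercept - slope %*% t(ac)
  }
  rsd <- sqrt(rowSums(resid^2) / df)
  floor_val <- stats::quantile(rsd, sd_floor_quantile, names = FALSE)
  rsd_floored <- pmax(rsd, floor_val)
  structure(list(
    intercept = array(intercept, dims),
    slope = array(as.numeric(slope), dims),
    residual_sd = array(rsd_floored, dims),
    sd_floor = floor_val, df = df, n = n,
    age_mean = age_mean, sxx = if (degenerate) NA_real_ else sxx,
    grid = dims
  ), class = "control_reference")
}

#' Voxel-wise t-map of a subject against the control reference
#'
#' After smoothing the subject volume, computes at each voxel
#' `t = (expected(age) - observed) / (residual_sd * sqrt(1 + leverage))`,
#' where `expected` is the age-adjusted control prediction and the leverage
#' is `1/n + (age - mean_age)^2 / Sxx`. Positive t means the subject is
#' below the control expectation (hypometabolism).
#'
#' @param subject_volume 3D array on the reference grid.
#' @param subject_age Subject age in years.
#' @param reference A `control_reference`.
#' @param smoothing_fwhm Gaussian FWHM applied to the subject volume first
#'   (default 8 voxel units; 0 disables).
#' @return 3D array of t-values.
#' @export
t_map <- function(subject_volume, subject_age, reference,
                  smoothing_fwhm = 8) {
  stopifnot(inherits(reference, "control_reference"))
  if (!identical(dim(subject_volume), reference$grid))
    stopf("subject volume grid does not match the reference")
  obs <- gaussian_smooth(subject_volume, smoothing_fwhm)
  ac <- subject_age - reference$age_mean
  expected <- reference$intercept + reference$slope * ac
  lev <- 1 / reference$n +
    if (is.na(reference$sxx)) 0 else ac^2 / reference$sxx
  (expected - obs) / (reference$residual_sd * sqrt(1 + lev))
}

#' t-sum configuration
#'
#' @param ad_mask Binary/logical 3D array marking the AD-pattern voxels.
#' @param abnormality_threshold Score above which a scan is called abnormal
#'   (default 11089, the conventional fixed threshold; for synthetic
#'   cohorts calibrate from the simulated null instead, see
#'   [calibrate_tsum_threshold()]).
#' @param smoothing_fwhm Gaussian FWHM for [t_map()] (default 8).
#' @param voxel_t_floor t-values at or below this floor contribute nothing
#'   to the score (default 0: all positive t-values are summed).
#' @return A `tsum_config`.
#' @export
tsum_config <- function(ad_mask, abnormality_threshold = 11089,
                        smoothing_fwhm = 8, voxel_t_floor = 0) {
  if (abnormality_threshold <= 0) stopf("abnormality threshold must be > 0")
  if (voxel_t_floor < 0) stopf("voxel_t_floor must be non-negative")
  structure(list(ad_mask = ad_mask != 0,
                 abnormality_threshold = abnormality_threshold,
                 smoothing_fwhm = smoothing_fwhm,
                 voxel_t_floor = voxel_t_floor),
            class = "tsum_config")
}

#' t-sum abnormality score
#'
#' Sum of t-values exceeding the configured floor over the AD-pattern
#' mask; the scan is flagged abnormal when the score exceeds the
#' abnormality threshold.
#'
#' @param t_volume 3D array of t-values from [t_map()].
#' @param config A [tsum_config()].
#' @return List with `score` and `abnormal`.
#' @export
tsum_score <- function(t_volume, config) {
  stopifnot(inherits(config, "tsum_config"))
  if (!identical(dim(t_volume), dim(config$ad_mask)))
    stopf("mask and volume grids differ")
  if (!any(config$ad_mask)) stopf("empty AD mask")
  t_in <- t_volume[config$ad_mask]
  score <- sum(t_in[t_in > config$voxel_t_floor])
  list(score = score, abnormal = score > config$abnormality_threshold)
}

#' Calibrate the abnormality threshold from a null score sample
#'
#' The synthetic analog of the fixed commercial threshold: the given
#' quantile (default 95th percentile) of t-sum scores observed in held-out
#' controls.
#'
#' @param null_scores Numeric vector of control t-sum scores.
#' @param q Quantile (default 0.95).
#' @return Threshold value.
#' @export
calibrate_tsum_threshold <- function(null_scores, q = 0.95) {
  stats::quantile(null_scores, q, names = FALSE)
}
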