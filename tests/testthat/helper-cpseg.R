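# compact phantom used throughout the tests: same structure as the
# default spec on a smaller grid so single fits run in well under a second
small_phantom_spec <- function(cp_blob_radius_mm = 3.5, ...) {
  phantom_spec(grid_shape = c(48, 48, 48),
               ventricle_semiaxes = c(8, 16, 7),
               ventricle_separation = 11,
               ilv_semiaxes = c(4, 6, 3), ilv_offset = c(3, -13, -5),
               cp_blob_count = 2L,
               cp_blob_radius_mm = cp_blob_radius_mm, ...)
}

# two-group cohort at the published ALS/HC volume summaries, covariates
# shared across groups (independent of group membership)
two_group_spec <- function(seed) {
  cohort_spec(n_per_group = c(ALS = 155L, HC = 105L),
              cpv_mean = c(ALS = 2930.7, HC = 2454.5),
              cpv_sd = c(ALS = 724.8, HC = 781.3),
              age_mean = 57.2, age_sd = 8.9, sex_prop_male = 0.57,
              education_mean = 9.6, education_sd = 3.7,
              duration_mean = c(ALS = 13.6, HC = NA),
              duration_sd = c(ALS = 7.9, HC = NA),
              bulbar_onset_prop = c(ALS = 0.25, HC = NA),
              hars_mean = 6, hars_sd = 4, hdrs_mean = 6, hdrs_sd = 4,
              n_qalb = 115L, hc_group = "HC", seed = seed)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# direct-summation SUSAN oracle: O(n^2) over masked voxels, small grids only
susan_oracle <- function(image, mask, sigma, t, radius_factor = 3) {
  idx <- which(mask, arr.ind = TRUE)
  vals <- image$data[mask]
  vs <- image$voxel_size
  out <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    d2 <- colSums((t(idx) - idx[i, ])^2 * vs^2)
    sel <- d2 > 0 & d2 <= (radius_factor * sigma)^2
    if (!any(sel)) {
      out[i] <- vals[i]
      next
    }
    w <- exp(-d2[sel] / (2 * sigma^2) - (vals[sel] - vals[i])^2 / t^2)
    out[i] <- if (sum(w) > 0) sum(w * vals[sel]) / sum(w) else vals[i]
  }
  out
}

# patient-row partial correlations of CP volume with ALSFRS-R and Qalb
cohort_partials <- function(coh, hc_group = "HC") {
  pt <- coh$group != hc_group
  covm <- data.frame(age = coh$age[pt],
                     sex = as.numeric(coh$sex[pt] == "M"),
                     tiv = coh$tiv[pt])
  c(alsfrs = partial_correlation(coh$cp_volume[pt], coh$alsfrs_r[pt],
                                 covm)$r,
    qalb = partial_correlation(coh$cp_volume[pt], coh$qalb[pt], covm)$r)
}
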