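#' Specification for a simulated clinical cohort
#'
#' Describes a cohort of ALS patients and healthy controls with
#' per-group sample sizes and summary statistics for choroid-plexus
#' volume, demographics and clinical scores, plus target partial
#' correlations (given age, sex and total intracranial volume) between
#' CP volume and the ALSFRS-R score and the albumin quotient among the
#' patient rows.  The defaults reproduce the published three-group
#' cohort structure (12 genetic ALS, 143 sporadic ALS, 105 controls).
#'
#' Per-group parameters are named vectors over `names(n_per_group)`;
#' scalars are recycled.  Every group whose name differs from `hc_group`
#' is treated as a patient group: only those rows receive disease
#' duration, onset site, ALSFRS-R and albumin values.
#'
#' @param n_per_group Named integer vector of group sizes (each >= 2).
#' @param cpv_mean,cpv_sd Per-group CP volume mean and SD in mm^3.
#' @param age_mean,age_sd Per-group age summaries in years.
#' @param sex_prop_male Per-group proportion of males.
#' @param education_mean,education_sd Per-group education (years).
#' @param duration_mean,duration_sd Disease duration (months), patient
#'   groups only.
#' @param bulbar_onset_prop Proportion of bulbar-onset patients.
#' @param hars_mean,hars_sd,hdrs_mean,hdrs_sd Anxiety/depression scores.
#' @param alsfrs_mean,alsfrs_sd ALSFRS-R summaries pooled over patients.
#' @param qalb_mean,qalb_sd Albumin-quotient summaries (mg/g) pooled over
#'   the patients with albumin data.
#' @param serum_albumin_mean,serum_albumin_sd Serum albumin (g/L).
#' @param tiv_mean,tiv_sd Total intracranial volume (mm^3), truncated
#'   positive.
#' @param target_partial_r_alsfrs,target_partial_r_qalb Target population
#'   partial correlations (|r| < 1) of CP volume with ALSFRS-R and Qalb
#'   given age, sex and TIV, among patient rows.
#' @param n_qalb Number of patient rows carrying albumin data (the rest
#'   get `NA`, matching incomplete lumbar-puncture coverage).
#' @param hc_group Name of the healthy-control group.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(genetic_ALS = 12L,
                                        sporadic_ALS = 143L, HC = 105L),
                        cpv_mean = c(genetic_ALS = 3161.8,
                                     sporadic_ALS = 2911.3, HC = 2454.5),
                        cpv_sd = c(genetic_ALS = 735.1,
                                   sporadic_ALS = 735.1, HC = 781.3),
                        age_mean = c(genetic_ALS = 44.5,
                                     sporadic_ALS = 58.2, HC = 57.3),
                        age_sd = c(genetic_ALS = 10.3,
                                   sporadic_ALS = 8.7, HC = 7.9),
                        sex_prop_male = c(genetic_ALS = 9 / 12,
                                          sporadic_ALS = 85 / 143,
                                          HC = 55 / 105),
                        education_mean = c(genetic_ALS = 8.3,
                                           sporadic_ALS = 9.5, HC = 9.9),
                        education_sd = c(genetic_ALS = 3.3,
                                         sporadic_ALS = 4.0, HC = 3.2),
                        duration_mean = c(genetic_ALS = 14.5,
                                          sporadic_ALS = 13.6, HC = NA),
                        duration_sd = c(genetic_ALS = 9.7,
                                        sporadic_ALS = 6.0, HC = NA),
                        bulbar_onset_prop = c(genetic_ALS = 4 / 12,
                                              sporadic_ALS = 34 / 143,
                                              HC = NA),
                        hars_mean = c(genetic_ALS = 8.7,
                                      sporadic_ALS = 8.7, HC = 4.0),
                        hars_sd = c(genetic_ALS = 5.8,
                                    sporadic_ALS = 5.1, HC = 3.9),
                        hdrs_mean = c(genetic_ALS = 10.1,
                                      sporadic_ALS = 10.5, HC = 3.4),
                        hdrs_sd = c(genetic_ALS = 5.9,
                                    sporadic_ALS = 4.9, HC = 4.2),
                        alsfrs_mean = 40.3, alsfrs_sd = 3.7,
                        qalb_mean = 5.9, qalb_sd = 2.8,
                        serum_albumin_mean = 40, serum_albumin_sd = 4,
                        tiv_mean = 1.45e6, tiv_sd = 1.5e5,
                        target_partial_r_alsfrs = -0.226,
                        target_partial_r_qalb = 0.479,
                        n_qalb = 115L,
                        hc_group = "HC",
                        seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(groups == ""))
    stop("`n_per_group` must be a named vector", call. = FALSE)
  n_per_group <- vapply(n_per_group, as.integer, integer(1))
  if (any(n_per_group < 2L))
    stop("every group needs size >= 2", call. = FALSE)
  expand <- function(x) {
    if (length(x) == 1L) x <- rep(x, length(groups))
    if (is.null(names(x))) names(x) <- groups
    x[groups]
  }
  sds <- c(expand(cpv_sd), expand(age_sd), alsfrs_sd, qalb_sd, tiv_sd)
  if (any(sds[!is.na(sds)] <= 0))
    stop("all SDs must be > 0", call. = FALSE)
  for (r in c(target_partial_r_alsfrs, target_partial_r_qalb))
    if (!is.finite(r) || abs(r) >= 1)
      stop("calibration error: target partial correlation must satisfy ",
           "|r| < 1 (the residual-noise floor leaves no attainable ",
           "solution otherwise)", call. = FALSE)
  if (!hc_group %in% groups)
    stop("`hc_group` must be one of the group names", call. = FALSE)
  structure(list(
    groups = groups, n_per_group = n_per_group,
    cpv_mean = expand(cpv_mean), cpv_sd = expand(cpv_sd),
    age_mean = expand(age_mean), age_sd = expand(age_sd),
    sex_prop_male = expand(sex_prop_male),
    education_mean = expand(education_mean),
    education_sd = expand(education_sd),
    duration_mean = expand(duration_mean),
    duration_sd = expand(duration_sd),
    bulbar_onset_prop = expand(bulbar_onset_prop),
    hars_mean = expand(hars_mean), hars_sd = expand(hars_sd),
    hdrs_mean = expand(hdrs_mean), hdrs_sd = expand(hdrs_sd),
    alsfrs_mean = alsfrs_mean, alsfrs_sd = alsfrs_sd,
    qalb_mean = qalb_mean, qalb_sd = qalb_sd,
    serum_albumin_mean = serum_albumin_mean,
    serum_albumin_sd = serum_albumin_sd,
    tiv_mean = tiv_mean, tiv_sd = tiv_sd,
    target_partial_r_alsfrs = target_partial_r_alsfrs,
    target_partial_r_qalb = target_partial_r_qalb,
    n_qalb = as.integer(n_qalb), hc_group = hc_group, seed = seed),
    class = "cohort_spec")
}

# Normal draws truncated below by rejection (bounds here sit >= ~3 SD from
# the mean, so rejection is cheap)
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  out <- rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- out <= lower
    if (!any(bad)) return(out)
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower + sd * 1e-6)
}

#' Simulate a clinical cohort table
#'
#' Draws per-subject records per the [cohort_spec()]: demographics,
#' TIV and CP volume from per-group Gaussians (TIV and CP volume
#' truncated positive), and — for patient rows — disease duration, onset
#' site, ALSFRS-R and the albumin quotient.  ALSFRS-R and Qalb come from
#' a latent linear model on the covariate-standardized CP volume,
#' \eqn{y = \mu_y + \sigma_y (r z_x + \sqrt{1-r^2}\,\epsilon)}, whose
#' noise scale is solved in closed form so that the population partial
#' correlation with CP volume given age, sex and TIV (all generated
#' independently of CP volume) equals the spec target.  Control rows
#' carry `NA` for all patient-only variables; only `n_qalb` patient rows
#' carry albumin data.  A fixed seed reproduces the table exactly.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of class `cohort_table`, one row per subject:
#'   `id`, `group`, `age`, `sex`, `education`, `duration`, `onset_site`,
#'   `alsfrs_r`, `bpr`, `hars`, `hdrs`, `csf_albumin`, `serum_albumin`,
#'   `qalb`, `tiv`, `cp_volume`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' aggregate(cp_volume ~ group, coh, mean)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- lapply(spec$groups, function(g) {
      n <- spec$n_per_group[[g]]
      is_pt <- g != spec$hc_group
      data.frame(
        id = character(n), group = g,
        age = rnorm_trunc(n, spec$age_mean[[g]], spec$age_sd[[g]], 18),
        sex = ifelse(runif(n) < spec$sex_prop_male[[g]], "M", "F"),
        education = pmax(0, rnorm(n, spec$education_mean[[g]],
                                  spec$education_sd[[g]])),
        duration = if (is_pt)
          rnorm_trunc(n, spec$duration_mean[[g]], spec$duration_sd[[g]], 1)
          else NA_real_,
        onset_site = if (is_pt)
          ifelse(runif(n) < spec$bulbar_onset_prop[[g]], "bulbar",
                 "spinal") else NA_character_,
        alsfrs_r = NA_real_, bpr = NA_real_,
        hars = pmax(0, rnorm(n, spec$hars_mean[[g]], spec$hars_sd[[g]])),
        hdrs = pmax(0, rnorm(n, spec$hdrs_mean[[g]], spec$hdrs_sd[[g]])),
        csf_albumin = NA_real_, serum_albumin = NA_real_,
        qalb = NA_real_,
        tiv = rnorm_trunc(n, spec$tiv_mean, spec$tiv_sd, 0),
        cp_volume = rnorm_trunc(n, spec$cpv_mean[[g]], spec$cpv_sd[[g]],
                                0),
        stringsAsFactors = FALSE)
    })
    coh <- do.call(rbind, rows)
    coh$id <- sprintf("S%04d", seq_len(nrow(coh)))

    pt <- coh$group != spec$hc_group
    n_pt <- sum(pt)
    if (n_pt >= 2L) {
      # latent linear model: standardize CP volume over the pooled
      # patient rows, mix with independent Gaussian noise at the exact
      # weight that yields the target population partial correlation
      z <- scale(coh$cp_volume[pt])[, 1]
      draw_y <- function(r, mu, s) {
        mu + s * (r * z + sqrt(1 - r^2) * rnorm(n_pt))
      }
      coh$alsfrs_r[pt] <- pmin(48, pmax(0, draw_y(
        spec$target_partial_r_alsfrs, spec$alsfrs_mean, spec$alsfrs_sd)))
      coh$bpr[pt] <- bpr(coh$alsfrs_r[pt], coh$duration[pt])
      q <- pmax(0.1, draw_y(spec$target_partial_r_qalb, spec$qalb_mean,
                            spec$qalb_sd))
      has_alb <- sample(which(pt), min(spec$n_qalb, n_pt))
      sera <- rnorm_trunc(length(has_alb), spec$serum_albumin_mean,
                          spec$serum_albumin_sd, 10)
      coh$serum_albumin[has_alb] <- sera
      coh$qalb[has_alb] <- q[match(has_alb, which(pt))]
      coh$csf_albumin[has_alb] <- coh$qalb[has_alb] * sera
    }
    class(coh) <- c("cohort_table", "data.frame")
    coh
  })
}
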