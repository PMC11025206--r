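#' CSF/serum albumin quotient (Qalb)
#'
#' Index of blood-CSF-barrier permeability: CSF albumin (mg/L) divided by
#' serum albumin (g/L), numerically in mg/g.  Higher values indicate a
#' more permeable barrier.
#'
#' @param csf_albumin CSF albumin concentration in mg/L (> 0).
#' @param serum_albumin Serum albumin concentration in g/L (> 0).
#' @return Qalb in mg/g; vectorized.
#' @export
#' @examples
#' qalb(236, 40)  # 5.9 mg/g
qalb <- function(csf_albumin, serum_albumin) {
  if (any(!is.finite(csf_albumin)) || any(!is.finite(serum_albumin)) ||
      any(csf_albumin <= 0) || any(serum_albumin <= 0))
    stop("albumin concentrations must be finite and positive",
         call. = FALSE)
  csf_albumin / serum_albumin
}

#' Baseline progression rate (BPR)
#'
#' Functional decline per month since symptom onset:
#' `(48 - ALSFRS-R) / duration`, in points per month, where 48 is the
#' maximum (fully functional) ALSFRS-R score and duration is the disease
#' duration in months.
#'
#' @param alsfrs_r ALSFRS-R score in \[0, 48\].
#' @param duration_months Disease duration in months (> 0).
#' @return Progression rate in points/month; vectorized.
#' @export
#' @examples
#' bpr(36, 12)  # 1 point lost per month
bpr <- function(alsfrs_r, duration_months) {
  if (any(!is.finite(alsfrs_r)) || any(alsfrs_r < 0) || any(alsfrs_r > 48))
    stop("`alsfrs_r` must lie in [0, 48]", call. = FALSE)
  if (any(!is.finite(duration_months)) || any(duration_months <= 0))
    stop("`duration_months` must be positive", call. = FALSE)
  (48 - alsfrs_r) / duration_months
}
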