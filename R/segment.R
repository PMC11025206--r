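#' Initial ventricular-system mask from an anatomical label map
#'
#' Union of the six FreeSurfer 'aseg' structures that bound the
#' lateral-ventricle choroid plexus: left and right lateral ventricle,
#' inferior lateral ventricle and choroid plexus.  All six codes must be
#' present in the label map's code table (their voxel counts may be
#' zero), and the union must be non-empty for the pipeline to proceed.
#'
#' @param labels A [label_map()].
#' @return Logical array of the same shape, with attribute `n_voxels`.
#' @export
build_initial_mask <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  wanted <- labels$codes[names(aseg_codes())]
  mask <- array(labels$data %in% wanted, dim = dim(labels$data))
  n <- sum(mask)
  if (n == 0L)
    stop("initial mask is empty: no voxels carry any of the six ",
         "ventricular-system labels", call. = FALSE)
  attr(mask, "n_voxels") <- n
  mask
}

#' Stage-1 clustering: split the initial mask into CSF and CP+wall
#'
#' Fits a 2-component Gaussian mixture to the image intensities inside
#' the initial mask and hard-assigns every mask voxel.  The component
#' with the larger mean is the "high" class (choroid plexus plus
#' ventricle wall); the other is the "low" class (CSF).  If the fitted
#' means are exactly equal the tie is broken toward the component with
#' the larger variance, then the lower index.  The two output masks
#' partition the input mask.
#'
#' @param image A [volume_image()].
#' @param mask Logical array, the initial mask.
#' @param control A [gmm_control()].
#' @return List with `low_mask`, `high_mask` (logical arrays) and `fit`
#'   (the [fit_gmm()] result).
#' @export
stage1_cluster <- function(image, mask, control = gmm_control()) {
  stopifnot(inherits(image, "volume_image"))
  if (!identical(dim(mask), dim(image$data)))
    stop("mask shape does not match the image grid", call. = FALSE)
  if (!any(mask)) stop("stage-1 mask is empty", call. = FALSE)
  vals <- image$data[mask]
  fit <- fit_gmm(vals, 2L, control)
  assign <- gmm_assign(fit)
  hi <- select_high_component(fit$means, fit$variances)
  high <- array(FALSE, dim = dim(mask))
  low <- array(FALSE, dim = dim(mask))
  where <- which(mask)
  high[where[assign == hi]] <- TRUE
  low[where[assign != hi]] <- TRUE
  list(low_mask = low, high_mask = high, fit = fit)
}

#' Stage-2 clustering: isolate the choroid plexus from smoothed values
#'
#' Fits a 3-component Gaussian mixture to the smoothed intensities on the
#' stage-1 high (CP + wall) domain and returns the voxels hard-assigned
#' to the component with the highest mean as the final choroid-plexus
#' mask (equal means fall back to the larger-variance, then lower-index
#' tie rule).
#'
#' @param smoothed Numeric vector of smoothed intensities, one per `TRUE`
#'   voxel of `domain_mask` in array order (as returned by
#'   [susan_smooth()]).
#' @param domain_mask Logical array, the stage-1 high mask (>= 30 voxels).
#' @param control A [gmm_control()].
#' @return List with `cp_mask` (logical array) and `fit`.
#' @export
stage2_cluster <- function(smoothed, domain_mask, control = gmm_control()) {
  n <- sum(domain_mask)
  if (n < 30L)
    stop("stage-2 domain has ", n, " voxels; need at least 30",
         call. = FALSE)
  if (length(smoothed) != n)
    stop("length of `smoothed` does not match the domain mask",
         call. = FALSE)
  fit <- fit_gmm(smoothed, 3L, control)
  assign <- gmm_assign(fit)
  hi <- select_high_component(fit$means, fit$variances)
  cp <- array(FALSE, dim = dim(domain_mask))
  where <- which(domain_mask)
  cp[where[assign == hi]] <- TRUE
  list(cp_mask = cp, fit = fit)
}

#' Apply a reproducible manual-edit list to a mask
#'
#' Stands in for expert manual correction of the automatic segmentation:
#' a documented, replayable list of voxels to remove and add.  Removals
#' are applied first, then additions, so a voxel listed in both ends up
#' present.  Applying the same edit list twice is a no-op the second
#' time.
#'
#' @param mask Logical array.
#' @param edits List with optional elements `remove` and `add`, each an
#'   n x 3 matrix (or data frame) of 1-based voxel indices.
#' @return The edited logical array.
#' @export
apply_manual_edits <- function(mask, edits) {
  if (is.null(edits) || (is.null(edits$remove) && is.null(edits$add)))
    return(mask)
  dims <- dim(mask)
  as_idx <- function(x, what) {
    if (is.null(x) || NROW(x) == 0L) return(NULL)
    x <- as.matrix(x)
    storage.mode(x) <- "integer"
    if (ncol(x) != 3L)
      stop("edit `", what, "` must have 3 index columns", call. = FALSE)
    bad <- x < 1L | x > matrix(dims, nrow(x), 3L, byrow = TRUE)
    if (any(bad))
      stop("edit `", what, "` contains voxel indices outside the grid",
           call. = FALSE)
    x
  }
  rem <- as_idx(edits$remove, "remove")
  add <- as_idx(edits$add, "add")
  if (!is.null(rem)) mask[rem] <- FALSE
  if (!is.null(add)) mask[add] <- TRUE
  mask
}

#' Volume of a voxel mask in cubic millimetres
#'
#' @param mask Logical array.
#' @param voxel_size Voxel edge lengths in mm (scalar or length 3).
#' @return Voxel count times voxel volume, in mm^3.
#' @export
#' @examples
#' compute_volume(array(TRUE, c(10, 10, 10)), 1)  # 1000 mm^3
compute_volume <- function(mask, voxel_size) {
  if (!is.logical(mask)) stop("`mask` must be logical", call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  sum(mask) * prod(voxel_size)
}

#' Configuration for the choroid-plexus segmentation pipeline
#'
#' @param sigma_mm SUSAN spatial standard deviation in mm (default 1 mm).
#' @param brightness_threshold SUSAN intensity similarity scale; `NULL`
#'   uses the `0.1 * (P95 - P5)` rule on the smoothing domain.
#' @param radius_factor SUSAN kernel truncation radius in units of sigma.
#' @param gmm A [gmm_control()] shared by both clustering stages.
#' @param min_component_size Minimum connected-component voxel count kept
#'   in the final mask; 0 (the default) disables size filtering.
#' @param seed Seed recorded in the provenance and forwarded to the GMM
#'   control when it has none (only relevant for random initialization).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(sigma_mm = 1, brightness_threshold = NULL,
                                radius_factor = 3, gmm = gmm_control(),
                                min_component_size = 0L, seed = NULL) {
  if (sigma_mm <= 0) stop("`sigma_mm` must be > 0", call. = FALSE)
  structure(list(sigma_mm = sigma_mm,
                 brightness_threshold = brightness_threshold,
                 radius_factor = radius_factor, gmm = gmm,
                 min_component_size = as.integer(min_component_size),
                 seed = seed),
            class = "segmentation_config")
}

# drop 6-connected components smaller than min_size voxels
filter_small_components <- function(mask, min_size) {
  if (min_size <= 1L || !any(mask)) return(mask)
  dims <- dim(mask)
  lab <- array(0L, dim = dims)
  nxt <- 0L
  where <- which(mask)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (v in where) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      ai <- arrayInd(cur, dims)
      nb <- offs + matrix(ai, 6L, 3L, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      flat <- nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] *
        (nb[, 3] - 1L)
      flat <- flat[mask[flat] & lab[flat] == 0L]
      lab[flat] <- nxt
      queue <- c(queue, flat)
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  array(lab %in% keep, dim = dims)
}

#' Segment the choroid plexus from an image and label map
#'
#' Runs the full two-stage pipeline: (1) initial mask as the union of the
#' six ventricular-system labels; (2) 2-component Gaussian-mixture
#' clustering of the mask intensities into CSF (low mean) versus choroid
#' plexus + ventricle wall (high mean); (3) SUSAN smoothing of the
#' high-intensity class (default sigma 1 mm); (4) 3-component
#' Gaussian-mixture clustering of the smoothed values, keeping the
#' highest-mean component as the choroid plexus; (5) optional manual-edit
#' replay and optional minimum-size filtering; (6) voxel volumetry.
#' The first failing stage aborts with a stage-tagged error.
#'
#' @param image A [volume_image()].
#' @param labels A [label_map()] aligned with the image.
#' @param config A [segmentation_config()].
#' @param edits Optional manual-edit list for [apply_manual_edits()].
#' @return An object of class `segmentation_result` with the per-stage
#'   masks, the smoothed intensities, both mixture fits, the final mask,
#'   `cp_volume_mm3`, and a `provenance` record (config, seed, per-stage
#'   voxel counts).
#' @export
segment_cp <- function(image, labels, config = segmentation_config(),
                       edits = NULL) {
  stopifnot(inherits(image, "volume_image"), inherits(labels, "label_map"))
  check_aligned(image, labels)
  gctl <- config$gmm
  if (is.null(gctl$seed)) gctl$seed <- config$seed

  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop("[", tag, "] ", conditionMessage(e), call. = FALSE))
  }

  initial <- stage("initial_mask", build_initial_mask(labels))
  s1 <- stage("stage1_gmm", stage1_cluster(image, initial, gctl))
  smoothed <- stage("susan", susan_smooth(
    image, s1$high_mask, sigma_mm = config$sigma_mm,
    brightness_threshold = config$brightness_threshold,
    radius_factor = config$radius_factor))
  s2 <- stage("stage2_gmm", stage2_cluster(smoothed, s1$high_mask, gctl))
  cp <- s2$cp_mask
  if (!is.null(edits))
    cp <- stage("manual_edits", apply_manual_edits(cp, edits))
  if (config$min_component_size > 0L)
    cp <- filter_small_components(cp, config$min_component_size)

  vol <- compute_volume(cp, image$voxel_size)
  prov <- list(
    config = config,
    seed = config$seed,
    brightness_threshold = attr(smoothed, "brightness_threshold"),
    n_initial = sum(initial), n_high = sum(s1$high_mask),
    n_cp = sum(cp),
    stage1_means = s1$fit$means, stage2_means = s2$fit$means)
  structure(list(initial_mask = initial, stage1_high_mask = s1$high_mask,
                 stage1_low_mask = s1$low_mask,
                 smoothed_intensities = as.numeric(smoothed),
                 final_cp_mask = cp, cp_volume_mm3 = vol,
                 stage1_fit = s1$fit, stage2_fit = s2$fit,
                 provenance = prov),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  p <- x$provenance
  cat("<segmentation_result>\n")
  cat(sprintf("  initial mask : %8d voxels\n", p$n_initial))
  cat(sprintf("  CP + wall    : %8d voxels (stage-1 means %s)\n",
              p$n_high, paste(signif(sort(p$stage1_means), 4),
                              collapse = ", ")))
  cat(sprintf("  choroid plexus: %7d voxels (stage-2 means %s)\n",
              p$n_cp, paste(signif(sort(p$stage2_means), 4),
                            collapse = ", ")))
  cat(sprintf("  CP volume    : %.1f mm^3\n", x$cp_volume_mm3))
  invisible(x)
}
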