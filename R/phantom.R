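#' Specification for a synthetic ventricular phantom
#'
#' Describes a 3-D head phantom that emulates the T1-weighted appearance of
#' the ventricular system: dark CSF inside two ellipsoidal lateral
#' ventricles (plus a small inferior/temporal-horn ellipsoid per side), an
#' intermediate-intensity partial-volume rim along each ventricle wall,
#' and bright choroid-plexus blobs floating in the CSF, over a uniform
#' background, with additive Gaussian noise.  The geometry is fully
#' deterministic given the spec; the noise field is the only stochastic
#' element and is controlled by `seed`.
#'
#' The default intensity ordering (CSF < wall < choroid plexus) is what a
#' T1 image shows and is required for the highest-mean-cluster rule of the
#' segmentation to be meaningful; the constructor enforces it.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size Voxel edge length(s) in mm (isotropic scalar or
#'   length 3).
#' @param ventricle_semiaxes Length-3 semiaxes in mm of each lateral
#'   ventricle ellipsoid (x = left-right, y = anterior-posterior,
#'   z = inferior-superior).
#' @param ventricle_separation Distance in mm from the midline to each
#'   ventricle centre along x.
#' @param ilv_semiaxes Semiaxes in mm of the inferior-lateral-ventricle
#'   ellipsoid on each side.
#' @param ilv_offset Offset in mm of the inferior-lateral-ventricle centre
#'   from its lateral-ventricle centre (the x component is mirrored on the
#'   left side).
#' @param wall_thickness Thickness in mm of the partial-volume rim just
#'   inside each ellipsoid surface.
#' @param cp_blob_count Number of spherical choroid-plexus blobs per
#'   lateral ventricle, spaced evenly along its long (y) axis.
#' @param cp_blob_radius_mm Blob radius in mm.
#' @param intensity_means Named numeric vector with entries `background`,
#'   `csf`, `wall`, `cp` (arbitrary T1-like units); must satisfy
#'   csf < wall < cp.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed RNG seed for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(48, 48, 48), noise_sd = 0)
#' ph <- generate_phantom(spec)
#' sum(ph$truth) * prod(ph$image$voxel_size)  # true CP volume in mm^3
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         voxel_size = 1,
                         ventricle_semiaxes = c(10, 24, 9),
                         ventricle_separation = 14,
                         ilv_semiaxes = c(5, 8, 4),
                         ilv_offset = c(4, -20, -8),
                         wall_thickness = 2,
                         cp_blob_count = 3L,
                         cp_blob_radius_mm = 4,
                         intensity_means = c(background = 100, csf = 30,
                                             wall = 70, cp = 110),
                         noise_sd = 5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  geom <- c(voxel_size, ventricle_semiaxes, ventricle_separation,
            ilv_semiaxes, wall_thickness, cp_blob_radius_mm)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric parameters must be positive and finite",
         call. = FALSE)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("`grid_shape` must be 3 integers >= 8", call. = FALSE)
  need <- c("background", "csf", "wall", "cp")
  if (!all(need %in% names(intensity_means)))
    stop("`intensity_means` must name background, csf, wall, cp",
         call. = FALSE)
  im <- intensity_means[need]
  if (!(im[["csf"]] < im[["wall"]] && im[["wall"]] < im[["cp"]]))
    stop("intensity means must satisfy csf < wall < cp", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cp_blob_count < 1L) stop("`cp_blob_count` must be >= 1", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 ventricle_semiaxes = ventricle_semiaxes,
                 ventricle_separation = ventricle_separation,
                 ilv_semiaxes = ilv_semiaxes, ilv_offset = ilv_offset,
                 wall_thickness = wall_thickness,
                 cp_blob_count = as.integer(cp_blob_count),
                 cp_blob_radius_mm = cp_blob_radius_mm,
                 intensity_means = im, noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

# squared normalized ellipsoid coordinate ("<= 1" means inside), built from
# per-axis coordinate vectors to avoid materializing a coordinate grid
ellipsoid_q <- function(xs, ys, zs, centre, semi) {
  qx <- ((xs - centre[1]) / semi[1])^2
  qy <- ((ys - centre[2]) / semi[2])^2
  qz <- ((zs - centre[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+")
}

sphere_mask <- function(xs, ys, zs, centre, r) {
  dx <- (xs - centre[1])^2
  dy <- (ys - centre[2])^2
  dz <- (zs - centre[3])^2
  outer(outer(dx, dy, "+"), dz, "+") <= r^2
}

#' Generate a ventricular phantom with known choroid-plexus ground truth
#'
#' Renders the geometry described by a [phantom_spec()]: a label map using
#' the FreeSurfer 'aseg' codes (so real `aparc+aseg` output is drop-in
#' compatible), a noisy T1-like intensity volume, and the exact boolean
#' choroid-plexus mask.  Blob centres are placed deterministically along
#' each ventricle's long axis; a blob that would not fit entirely inside
#' its ventricle ellipsoid raises a geometry error rather than being
#' silently truncated.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `cp_phantom` with elements `image`
#'   ([volume_image]), `labels` ([label_map]), `truth` (logical array, the
#'   ground-truth choroid-plexus mask) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape
  vs <- spec$voxel_size
  # voxel-centre world coordinates, grid centred on the origin
  xs <- (seq_len(n[1]) - (n[1] + 1) / 2) * vs[1]
  ys <- (seq_len(n[2]) - (n[2] + 1) / 2) * vs[2]
  zs <- (seq_len(n[3]) - (n[3] + 1) / 2) * vs[3]

  semi <- spec$ventricle_semiaxes
  wall <- spec$wall_thickness
  if (any(semi <= wall))
    stop("wall_thickness must be smaller than every ventricle semiaxis",
         call. = FALSE)
  inner_semi <- semi - wall

  labels <- array(0L, dim = n)
  csf <- array(FALSE, dim = n)
  rim <- array(FALSE, dim = n)
  truth <- array(FALSE, dim = n)
  codes <- aseg_codes()

  for (side in c("right", "left")) {
    sgn <- if (side == "right") 1 else -1
    centre <- c(sgn * spec$ventricle_separation, 0, 0)
    q_out <- ellipsoid_q(xs, ys, zs, centre, semi)
    q_in <- ellipsoid_q(xs, ys, zs, centre, inner_semi)
    lv_all <- q_out <= 1
    lv_rim <- lv_all & q_in > 1
    lv_code <- codes[[paste0("lateral_ventricle_", side)]]
    labels[lv_all] <- lv_code

    # temporal-horn ellipsoid, same rim rule, lower priority than the
    # main body where they meet
    ic <- centre + c(sgn * spec$ilv_offset[1], spec$ilv_offset[2],
                     spec$ilv_offset[3])
    iq_out <- ellipsoid_q(xs, ys, zs, ic, spec$ilv_semiaxes)
    iq_in <- ellipsoid_q(xs, ys, zs, ic,
                         pmax(spec$ilv_semiaxes - wall,
                              0.25 * spec$ilv_semiaxes))
    ilv_all <- iq_out <= 1 & !lv_all
    ilv_rim <- ilv_all & iq_in > 1
    labels[ilv_all] <- codes[[paste0("inf_lateral_ventricle_", side)]]

    csf <- csf | (lv_all & !lv_rim) | (ilv_all & !ilv_rim)
    rim <- rim | lv_rim | ilv_rim

    # deterministic blob centres spaced along the ventricle long axis
    r <- spec$cp_blob_radius_mm
    k <- spec$cp_blob_count
    fr <- if (k == 1L) 0 else seq(-0.5, 0.5, length.out = k)
    shrunk <- semi - r
    if (any(shrunk <= 0))
      stop("blob radius ", r, " mm does not fit inside ventricle semiaxes (",
           paste(semi, collapse = ", "), " mm)", call. = FALSE)
    cp_code <- codes[[paste0("choroid_plexus_", side)]]
    for (f in fr) {
      bc <- centre + c(0, f * semi[2], 0)
      if (sum(((bc - centre) / shrunk)^2) > 1)
        stop("blob at offset ", signif(f * semi[2], 3),
             " mm along the ventricle axis cannot be fully contained; ",
             "reduce cp_blob_radius_mm or cp_blob_count", call. = FALSE)
      b <- sphere_mask(xs, ys, zs, bc, r)
      truth <- truth | b
      labels[b] <- cp_code
    }
  }

  im <- spec$intensity_means
  vol <- array(im[["background"]], dim = n)
  vol[csf] <- im[["csf"]]
  vol[rim] <- im[["wall"]]
  vol[truth] <- im[["cp"]]
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       array(rnorm(prod(n), sd = spec$noise_sd), dim = n))
    vol <- vol + noise
  }

  structure(list(image = volume_image(vol, voxel_size = vs),
                 labels = label_map(labels, voxel_size = vs),
                 truth = truth, spec = spec),
            class = "cp_phantom")
}

#' @export
print.cp_phantom <- function(x, ...) {
  cat("<cp_phantom> ", paste(dim(x$image$data), collapse = " x "),
      " voxels; true CP volume ",
      signif(sum(x$truth) * prod(x$image$voxel_size), 6), " mm^3\n",
      sep = "")
  invisible(x)
}
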