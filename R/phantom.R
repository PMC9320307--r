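#' Synthetic PET/CT phantom specification
#'
#' Describes a paired synthetic slice: a CT-like 512 x 512 anatomy image (an
#' elliptical body on a dark air background, with brighter lesion disks) and
#' a PET-like uptake image in which strong uptake appears as LOW gray values
#' (lesions are dark disks on a high-gray body; air, with no uptake, renders
#' white). The PET grid is related to the CT grid by a known affine
#' misalignment, the ground-truth lesion masks are exact disks in CT
#' coordinates, and landmark pairs consistent with the misalignment are
#' emitted for registration. Every stage of the pipeline is thereby testable
#' without patient data.
#'
#' Geometry defaults emulate a thoracic slice: a 512 x 512 CT raster, a
#' 168 x 168 PET raster, one 8-pixel-radius lesion, a small shear-free affine
#' misalignment of a few pixels, and mild Gaussian intensity noise.
#'
#' @param ct_size integer `c(width, height)` of the CT raster.
#' @param pet_size integer `c(width, height)` of the PET raster.
#' @param lesions list of lesions, each a list with `center` (`c(x, y)` in CT
#'   coordinates), `radius` (pixels, >= 2) and `pet_intensity` (low gray
#'   value, must be below `pet_bg / 2` so the doubled-threshold growth
#'   criterion separates lesion from body).
#' @param body_ellipse list with `center`, `semi_axes` (pixels) and
#'   `ct_intensity`.
#' @param background numeric `c(ct_bg, pet_bg)`: CT air value (dark) and PET
#'   body value (high gray).
#' @param misalign [affine_params()] applied to the (enlarged) PET grid, i.e.
#'   the transform carrying enlarged-PET coordinates into CT coordinates that
#'   registration must recover.
#' @param noise_sigma Gaussian intensity noise standard deviation (gray
#'   levels); noisy values are truncated to `[0, 255]`.
#' @param rng_seed integer seed; generation is fully deterministic given it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(ct_size = c(512L, 512L),
                         pet_size = c(168L, 168L),
                         lesions = list(list(center = c(330, 260), radius = 8,
                                             pet_intensity = 60)),
                         body_ellipse = list(center = c(256, 256),
                                             semi_axes = c(180, 130),
                                             ct_intensity = 120),
                         background = c(ct_bg = 20, pet_bg = 200),
                         misalign = affine_params(1.01, 0.004, -0.003, 0.99,
                                                  3, -2),
                         noise_sigma = 2,
                         rng_seed = 1L) {
  ct_bg <- background[[1]]; pet_bg <- background[[2]]
  ec <- body_ellipse$center; ea <- body_ellipse$semi_axes
  for (les in lesions) {
    if (les$radius < 2)
      pc_stop("lesion radius must be >= 2 pixels", "validation_error")
    if (les$pet_intensity >= pet_bg / 2)
      pc_stop("lesion pet_intensity must be below pet_bg / 2", "validation_error")
    u <- (les$center[1] - ec[1]) / max(ea[1] - les$radius, 1)
    v <- (les$center[2] - ec[2]) / max(ea[2] - les$radius, 1)
    if (u * u + v * v > 1)
      pc_stop("lesion (including its radius) must lie inside the body ellipse",
              "validation_error")
  }
  if (noise_sigma < 0)
    pc_stop("noise_sigma must be non-negative", "validation_error")
  structure(list(ct_size = as.integer(ct_size), pet_size = as.integer(pet_size),
                 lesions = lesions, body_ellipse = body_ellipse,
                 background = c(ct_bg = ct_bg, pet_bg = pet_bg),
                 misalign = misalign, noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# CT lesions render this much brighter than the surrounding tissue
CT_LESION_DELTA <- 40
# PET air (no uptake) renders white under the inverted-uptake convention
PET_AIR_VALUE <- 255

# vectorized scene evaluators at continuous CT-space coordinates
phantom_ct_scene <- function(spec, u, v) {
  ec <- spec$body_ellipse$center; ea <- spec$body_ellipse$semi_axes
  val <- rep(spec$background[["ct_bg"]], length(u))
  body <- ((u - ec[1]) / ea[1])^2 + ((v - ec[2]) / ea[2])^2 <= 1
  val[body] <- spec$body_ellipse$ct_intensity
  for (les in spec$lesions) {
    inles <- (u - les$center[1])^2 + (v - les$center[2])^2 <= les$radius^2
    val[inles] <- min(spec$body_ellipse$ct_intensity + CT_LESION_DELTA, 255)
  }
  val
}

phantom_pet_scene <- function(spec, u, v) {
  ec <- spec$body_ellipse$center; ea <- spec$body_ellipse$semi_axes
  val <- rep(PET_AIR_VALUE, length(u))
  body <- ((u - ec[1]) / ea[1])^2 + ((v - ec[2]) / ea[2])^2 <= 1
  val[body] <- spec$background[["pet_bg"]]
  for (les in spec$lesions) {
    inles <- (u - les$center[1])^2 + (v - les$center[2])^2 <= les$radius^2
    val[inles] <- les$pet_intensity
  }
  val
}

#' Generate a paired synthetic PET/CT slice
#'
#' Renders the CT image, the misaligned low-resolution PET image, the exact
#' per-lesion ground-truth masks in CT coordinates and landmark control
#' points consistent with the misalignment.
#'
#' The PET pixel at `(x, y)` samples the continuous uptake scene at
#' `misalign(S(x, y))`, where `S` is the align-corners scale from the PET
#' raster to the CT raster: the phantom's PET is exactly what a scanner
#' misaligned by `spec$misalign` (expressed in enlarged-PET coordinates)
#' would record. Landmarks are placed at the body-ellipse extrema and center
#' in CT space; their source coordinates are the inverse-mapped positions on
#' the enlarged PET, so fitting the landmarks recovers `spec$misalign`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `pet` and `ct` ([gray_image()]s), `truth` (list of
#'   `n x 2` integer matrices, one exact disk mask per lesion, CT
#'   coordinates), `points` (a [control_points()] set) and `spec`.
#' @export
make_phantom_pair <- function(spec = phantom_spec()) {
  set.seed(spec$rng_seed)
  cw <- spec$ct_size[1]; ch <- spec$ct_size[2]
  pw <- spec$pet_size[1]; ph <- spec$pet_size[2]

  ug <- matrix(0:(cw - 1), ch, cw, byrow = TRUE)
  vg <- matrix(0:(ch - 1), ch, cw)
  ct <- matrix(phantom_ct_scene(spec, as.vector(ug), as.vector(vg)), ch, cw)

  # PET grid -> enlarged-PET grid (align corners) -> CT space via misalign
  sx <- if (pw > 1) (cw - 1) / (pw - 1) else 1
  sy <- if (ph > 1) (ch - 1) / (ph - 1) else 1
  qx <- matrix((0:(pw - 1)) * sx, ph, pw, byrow = TRUE)
  qy <- matrix((0:(ph - 1)) * sy, ph, pw)
  mp <- spec$misalign
  ux <- mp[["a"]] * qx + mp[["b"]] * qy + mp[["h"]]
  uy <- mp[["c"]] * qx + mp[["d"]] * qy + mp[["k"]]
  pet <- matrix(phantom_pet_scene(spec, as.vector(ux), as.vector(uy)), ph, pw)

  if (spec$noise_sigma > 0) {
    ct <- clip01(ct + stats::rnorm(length(ct), 0, spec$noise_sigma))
    pet <- clip01(pet + stats::rnorm(length(pet), 0, spec$noise_sigma))
  }

  truth <- lapply(seq_along(spec$lesions), function(i) truth_mask(spec, i))

  ec <- spec$body_ellipse$center; ea <- spec$body_ellipse$semi_axes
  targets <- rbind(c(ec[1] - ea[1], ec[2]), c(ec[1] + ea[1], ec[2]),
                   c(ec[1], ec[2] - ea[2]), c(ec[1], ec[2] + ea[2]),
                   c(ec[1], ec[2]))
  sources <- affine_apply(affine_invert(mp), targets)
  points <- control_points(sources, targets)

  list(pet = gray_image(pet, "PET", "phantom-pet"),
       ct = gray_image(ct, "CT", "phantom-ct"),
       truth = truth, points = points, spec = spec)
}

# exact ground-truth disk mask of lesion i, n x 2 matrix of CT pixel coords
truth_mask <- function(spec, i) {
  les <- spec$lesions[[i]]
  r <- les$radius; cx <- les$center[1]; cy <- les$center[2]
  xs <- max(0, floor(cx - r)):min(spec$ct_size[1] - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(spec$ct_size[2] - 1, ceiling(cy + r))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' Ground-truth lesion mask area
#'
#' Pixel count of the exact disk mask of one lesion (pixels whose center lies
#' within `radius` of the lesion center).
#'
#' @param spec a [phantom_spec()].
#' @param lesion_index 1-based lesion index.
#' @return integer pixel count.
#' @export
truth_mask_area <- function(spec, lesion_index) {
  if (lesion_index < 1 || lesion_index > length(spec$lesions))
    pc_stop(sprintf("lesion index %s out of range", lesion_index), "bounds_error")
  nrow(truth_mask(spec, lesion_index))
}
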