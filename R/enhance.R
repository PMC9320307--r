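#' Enhancement configuration
#'
#' Settings for the PET enlargement/enhancement stage: the target raster size
#' (CT size, default 512 x 512) and the lower gray threshold `PETmin` of the
#' piecewise transform. `pet_min = "auto"` estimates the threshold per image
#' as the nearest-rank 1st percentile of the intensity distribution, which
#' suppresses only the darkest background tail.
#'
#' @param target_size integer `c(width, height)`, default `c(512, 512)`.
#' @param pet_min numeric threshold in `[0, 255)`, or `"auto"`.
#' @return an object of class `enhance_config`.
#' @export
enhance_config <- function(target_size = c(512L, 512L), pet_min = "auto") {
  if (length(target_size) != 2L || any(target_size < 1))
    pc_stop("target_size must be c(width, height) with positive entries",
            "validation_error")
  if (!identical(pet_min, "auto")) {
    stopifnot_scalar_num(pet_min, "pet_min")
    if (pet_min < 0 || pet_min >= 255)
      pc_stop("pet_min must lie in [0, 255)", "validation_error")
  }
  structure(list(target_size = as.integer(target_size), pet_min = pet_min),
            class = "enhance_config")
}

#' Enlarge an image by bilinear interpolation
#'
#' Align-corners bilinear upscaling: output corner pixels coincide with source
#' corner pixels, every other output pixel is the bilinear interpolant of the
#' four surrounding source pixels. Values never leave the source range;
#' upscaling to the source size is the identity.
#'
#' @param img a [gray_image()].
#' @param target_size integer `c(width, height)`, each >= the source dimension.
#' @return a [gray_image()] of exactly `target_size`.
#' @export
upscale_bilinear <- function(img, target_size) {
  m <- as.matrix(img)
  sw <- ncol(m); sh <- nrow(m)
  tw <- as.integer(target_size[1]); th <- as.integer(target_size[2])
  if (tw < sw || th < sh)
    pc_stop("target size must be >= source size in both dimensions",
            "validation_error")
  out <- interp_matrix(sh, th) %*% m %*% t(interp_matrix(sw, tw))
  rng <- range(m)
  out <- clip01(out, rng[1], rng[2])
  gray_image(out, attr(img, "modality"), attr(img, "source_id"))
}

# dst x src row-interpolation operator under align-corners mapping
interp_matrix <- function(src, dst) {
  R <- matrix(0, dst, src)
  if (src == 1L) {
    R[, 1] <- 1
    return(R)
  }
  pos <- if (dst == 1L) 0 else (0:(dst - 1)) * (src - 1) / (dst - 1)
  i0 <- pmin(floor(pos), src - 2)
  w <- pos - i0
  R[cbind(seq_len(dst), i0 + 1)] <- 1 - w
  R[cbind(seq_len(dst), i0 + 2)] <- R[cbind(seq_len(dst), i0 + 2)] + w
  R
}

#' Automatic lower gray threshold
#'
#' Returns the nearest-rank 1st percentile of the pixel intensities, used as
#' `PETmin` when the enhancement configuration says `"auto"`.
#'
#' @param img a [gray_image()].
#' @return a single intensity value.
#' @export
auto_pet_min <- function(img) {
  v <- sort(as.vector(as.matrix(img)))
  v[max(1L, ceiling(0.01 * length(v)))]
}

#' Piecewise grayscale enhancement
#'
#' The segmented gray transform that stretches the informative low range of an
#' inverted-uptake PET image: intensities below `pet_min` map to 0 and the
#' remaining range `[pet_min, 255]` is stretched linearly onto `[0, 255]`:
#' `G = 255 / (255 - PETmin) * (F - PETmin)` for `F >= PETmin`, else 0.
#' The output is kept as float and clipped to `[0, 255]`; the map is monotone
#' non-decreasing with `G(PETmin) = 0` and `G(255) = 255`.
#'
#' @param img a [gray_image()].
#' @param pet_min threshold in `[0, 255)`.
#' @return a [gray_image()] of the same size.
#' @export
piecewise_enhance <- function(img, pet_min) {
  stopifnot_scalar_num(pet_min, "pet_min")
  if (pet_min < 0 || pet_min >= 255)
    pc_stop("pet_min must lie in [0, 255); 255 would divide by zero",
            "validation_error")
  m <- as.matrix(img)
  g <- 255 / (255 - pet_min) * (m - pet_min)
  g[m < pet_min] <- 0
  gray_image(clip01(g), attr(img, "modality"), attr(img, "source_id"))
}

#' Enlarge and enhance a PET image
#'
#' Composition of [upscale_bilinear()] to the configured target size (the CT
#' raster, 512 x 512 by default) and [piecewise_enhance()], with `PETmin`
#' resolved by [auto_pet_min()] when the configuration says `"auto"`.
#'
#' @param img a PET [gray_image()].
#' @param cfg an [enhance_config()].
#' @return the enhanced [gray_image()] at `cfg$target_size`.
#' @export
enhance_pet <- function(img, cfg = enhance_config()) {
  up <- upscale_bilinear(img, cfg$target_size)
  pm <- if (identical(cfg$pet_min, "auto")) auto_pet_min(up) else cfg$pet_min
  if (pm >= 255) pm <- 254  # degenerate all-bright image; keep the map defined
  piecewise_enhance(up, pm)
}
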