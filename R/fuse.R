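#' Fusion weights
#'
#' PET/CT blending percentages applied to the wavelet coefficients. The two
#' percentages must sum to 100. The study default is 40% PET / 60% CT, the
#' ratio at which the fused slice keeps CT anatomical detail while the uptake
#' pattern stays visible.
#'
#' @param pet_pct percentage applied to PET coefficients, in `[0, 100]`.
#' @param ct_pct percentage applied to CT coefficients, in `[0, 100]`.
#' @return an object of class `fusion_weights`.
#' @export
fusion_weights <- function(pet_pct = 40, ct_pct = 60) {
  stopifnot_scalar_num(pet_pct, "pet_pct")
  stopifnot_scalar_num(ct_pct, "ct_pct")
  if (pet_pct < 0 || ct_pct < 0 || abs(pet_pct + ct_pct - 100) > 1e-9)
    pc_stop("fusion weights must be non-negative and sum to 100",
            "validation_error")
  structure(list(pet_pct = pet_pct, ct_pct = ct_pct), class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("<fusion_weights PET %g%% : CT %g%%>\n", x$pet_pct, x$ct_pct))
  invisible(x)
}

#' Blend two wavelet pyramids
#'
#' Every coefficient of the fused pyramid (approximation and all detail
#' bands) is the weighted combination
#' `pet_pct/100 * PET + ct_pct/100 * CT`. When `cfg$soft_threshold > 0` the
#' detail coefficients are first shrunk toward zero by
#' `sign(x) * max(|x| - t, 0)` (soft thresholding), a light denoising step.
#'
#' @param pet_coeffs,ct_coeffs `wavelet_pyramid` objects of identical shape
#'   (see [dwt_decompose()]).
#' @param w a [fusion_weights()] object.
#' @param cfg the [wavelet_config()] used for the decompositions.
#' @return the fused `wavelet_pyramid`.
#' @export
combine_coeffs <- function(pet_coeffs, ct_coeffs, w = fusion_weights(),
                           cfg = wavelet_config()) {
  if (length(pet_coeffs$details) != length(ct_coeffs$details) ||
      !identical(dim(pet_coeffs$approx), dim(ct_coeffs$approx)) ||
      !identical(lapply(pet_coeffs$details, lapply, dim),
                 lapply(ct_coeffs$details, lapply, dim)))
    pc_stop("coefficient pyramids have mismatched shapes", "validation_error")
  wp <- w$pet_pct / 100; wc <- w$ct_pct / 100
  shrink <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  out <- pet_coeffs
  out$approx <- wp * pet_coeffs$approx + wc * ct_coeffs$approx
  for (lev in seq_along(out$details)) {
    for (band in c("horizontal", "vertical", "diagonal")) {
      p <- pet_coeffs$details[[lev]][[band]]
      c_ <- ct_coeffs$details[[lev]][[band]]
      if (cfg$soft_threshold > 0) {
        p <- shrink(p, cfg$soft_threshold)
        c_ <- shrink(c_, cfg$soft_threshold)
      }
      out$details[[lev]][[band]] <- wp * p + wc * c_
    }
  }
  out
}

#' Fuse registered PET and CT slices in the wavelet domain
#'
#' Decomposes both same-size images with [dwt_decompose()], blends the
#' coefficient pyramids with [combine_coeffs()] and inverts the transform.
#' The result is clipped to `[0, 255]`. With the threshold off the operation
#' is linear, so fusing an image with itself (or using weights 100:0 / 0:100)
#' returns the input to numerical precision.
#'
#' @param pet registered, enhanced PET [gray_image()].
#' @param ct CT [gray_image()] of the same size.
#' @param w a [fusion_weights()] object.
#' @param cfg a [wavelet_config()].
#' @return the fused [gray_image()] (modality `"FUSED"`).
#' @export
fuse_images <- function(pet, ct, w = fusion_weights(), cfg = wavelet_config()) {
  if (!identical(dim(pet), dim(ct)))
    pc_stop("PET and CT must have the same size for fusion", "validation_error")
  pyr <- combine_coeffs(dwt_decompose(pet, cfg), dwt_decompose(ct, cfg), w, cfg)
  fused <- clip01(dwt_reconstruct(pyr))
  gray_image(fused, "FUSED",
             paste0(attr(pet, "source_id"), "+", attr(ct, "source_id")))
}

#' 256-entry pseudocolor lookup table
#'
#' A fixed piecewise-linear ramp through black, blue, cyan, green, yellow,
#' red and white, used to colorize fused slices for display so that strong
#' uptake regions stand out. Display-only: segmentation never reads RGB.
#'
#' @return integer `256 x 3` matrix (R, G, B in 0..255), row `i` holding the
#'   color of gray level `i - 1`.
#' @export
pseudocolor_lut <- function() {
  anchors_gray <- c(0, 42.5, 85, 127.5, 170, 212.5, 255)
  anchors_rgb <- rbind(c(0, 0, 0),        # black
                       c(0, 0, 255),      # blue
                       c(0, 255, 255),    # cyan
                       c(0, 255, 0),      # green
                       c(255, 255, 0),    # yellow
                       c(255, 0, 0),      # red
                       c(255, 255, 255))  # white
  g <- 0:255
  lut <- sapply(1:3, function(ch)
    round_half_up(stats::approx(anchors_gray, anchors_rgb[, ch], xout = g)$y))
  storage.mode(lut) <- "integer"
  colnames(lut) <- c("r", "g", "b")
  lut
}

#' Pseudocolor rendering of a grayscale image
#'
#' Rounds each pixel to its 8-bit gray level and maps it through the fixed
#' [pseudocolor_lut()]. Deterministic: equal gray in, equal color out.
#'
#' @param img a [gray_image()].
#' @return numeric array `height x width x 3` with values in 0..255.
#' @export
pseudocolor <- function(img) {
  m <- round_half_up(clip01(as.matrix(img)))
  lut <- pseudocolor_lut()
  out <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(lut[m + 1L, ch], nrow(m), ncol(m))
  out
}
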