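#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities (rows = image rows,
#' columns = image columns) carrying a modality tag and a free-text source
#' identifier. Intensities are kept as floating point in `[0, 255]` throughout
#' the pipeline and quantized to 8-bit only on export. All coordinates in the
#' package are 0-based with `x` the column index, `y` the row index and the
#' origin at the top-left pixel.
#'
#' @param pixels numeric matrix of intensities; `nrow` is the image height,
#'   `ncol` the width.
#' @param modality one of `"PET"`, `"CT"`, `"FUSED"`.
#' @param source_id free-text identifier (file name, phantom tag, ...).
#' @return an object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0, 4, 6), "CT", "demo")
#' image_size(img)  # width 6, height 4
#' @export
gray_image <- function(pixels, modality = c("PET", "CT", "FUSED"), source_id = "") {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    pc_stop("pixels must be a numeric matrix", "validation_error")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    pc_stop("image must have width >= 1 and height >= 1", "validation_error")
  structure(pixels,
            modality = modality,
            source_id = source_id,
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %s %dx%d (w x h), source '%s'>\n",
              attr(x, "modality"), ncol(x), nrow(x), attr(x, "source_id")))
  rng <- range(x)
  cat(sprintf("  intensity range [%.6g, %.6g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @rdname gray_image
#' @param img a `gray_image`.
#' @return `image_size()`: integer vector `c(width, height)`.
#' @export
image_size <- function(img) c(width = ncol(img), height = nrow(img))

#' @rdname gray_image
#' @export
image_modality <- function(img) attr(img, "modality")

# strip class/attrs, keep the bare intensity matrix
#' @export
as.matrix.gray_image <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' @export
plot.gray_image <- function(x, ...) {
  m <- as.matrix(x)
  # transpose/flip so the top-left pixel plots top-left
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  axes = FALSE, asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

# pixel lookup at 0-based (x, y); internal
px_at <- function(img, x, y) img[cbind(y + 1L, x + 1L)]

same_modality <- function(img, modality) identical(attr(img, "modality"), modality)
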