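#' Read a grayscale slice image
#'
#' Reads a single-frame grayscale image from PNG, TIFF or DICOM. The format is
#' detected from the file's magic bytes, not its extension. PNG/TIFF values
#' pass through unchanged on the `[0, 255]` scale; DICOM stored values are
#' rescaled to `[0, 255]` by linear min-max scaling of the slice (rounded half
#' up), since scanner windowing metadata is not interpreted.
#'
#' @param path path to the image file.
#' @param modality modality tag recorded on the returned image.
#' @return a [gray_image()].
#' @export
read_gray_image <- function(path, modality = c("PET", "CT", "FUSED")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    pc_stop(sprintf("cannot read image file '%s'", path), "io_error")
  head <- readBin(path, "raw", n = 132L)
  if (length(head) >= 8 &&
      identical(as.integer(head[1:4]), c(137L, 80L, 78L, 71L))) {
    m <- read_png_gray(path)
  } else if (length(head) >= 4 &&
             (identical(rawToChar(head[1:2]), "II") ||
              identical(rawToChar(head[1:2]), "MM"))) {
    m <- read_tiff_gray(path)
  } else if (length(head) >= 132 && identical(rawToChar(head[129:132]), "DICM")) {
    m <- read_dicom_gray(path)
  } else {
    pc_stop(sprintf("unrecognized image format in '%s'", path), "io_error")
  }
  gray_image(m, modality, source_id = basename(path))
}

read_png_gray <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] > 1L)
      pc_stop("color or multi-channel PNG input is not supported",
              "unsupported_format_error")
    v <- v[, , 1L]
  }
  round(v * 255, 6)
}

read_tiff_gray <- function(path) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] > 1L)
      pc_stop("color or multi-channel TIFF input is not supported",
              "unsupported_format_error")
    v <- v[, , 1L]
  }
  round(v * 255, 6)
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are clipped to `[0, 255]` and rounded half up to integers; a
#' read back with [read_gray_image()] returns identical pixel values.
#'
#' @param img a [gray_image()].
#' @param path output path (PNG).
#' @export
write_gray_image <- function(img, path) {
  if (!dir.exists(dirname(path)))
    pc_stop(sprintf("cannot write '%s': directory does not exist", path), "io_error")
  q <- round_half_up(clip01(as.matrix(img)))
  png::writePNG(q / 255, path)
  invisible(path)
}

# write an RGB overlay (values 0..255 integers) as PNG
#' @rdname write_gray_image
#' @param rgb numeric array `height x width x 3` with values in `[0, 255]`.
#' @export
write_rgb_image <- function(rgb, path) {
  if (!dir.exists(dirname(path)))
    pc_stop(sprintf("cannot write '%s': directory does not exist", path), "io_error")
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  png::writePNG(round_half_up(clip01(rgb)) / 255, path)
  invisible(path)
}

## ---- minimal single-frame DICOM reader -------------------------------------
## Supports uncompressed explicit/implicit VR little endian, grayscale,
## 8- or 16-bit, single frame. Just enough of the tag dictionary for pixel
## geometry; everything else is skipped structurally.

dcm_u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
dcm_u32 <- function(raw, off) {
  as.numeric(as.integer(raw[off + 1L])) +
    256 * as.integer(raw[off + 2L]) +
    65536 * as.integer(raw[off + 3L]) +
    16777216 * as.integer(raw[off + 4L])
}

read_dicom_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || !identical(rawToChar(raw[129:132]), "DICM"))
    pc_stop(sprintf("'%s' is not a DICOM file", path), "io_error")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  off <- 132L                 # 0-based offset just past "DICM"
  n <- length(raw)
  tags <- list()
  transfer_syntax <- "1.2.840.10008.1.2.1"
  explicit <- TRUE            # meta group is always explicit little endian
  meta_done <- FALSE
  while (off + 8 <= n) {
    group <- dcm_u16(raw, off); elem <- dcm_u16(raw, off + 2L)
    if (!meta_done && group != 2L) {
      meta_done <- TRUE
      explicit <- !identical(transfer_syntax, "1.2.840.10008.1.2")
      if (!transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        pc_stop("compressed or unsupported DICOM transfer syntax",
                "unsupported_format_error")
    }
    use_explicit <- explicit || group == 2L
    if (use_explicit) {
      vr <- rawToChar(raw[(off + 5L):(off + 6L)])
      if (vr %in% long_vrs) {
        len <- dcm_u32(raw, off + 8L); hdr <- 12L
      } else {
        len <- dcm_u16(raw, off + 6L); hdr <- 8L
      }
    } else {
      len <- dcm_u32(raw, off + 4L); hdr <- 8L
    }
    if (len == 4294967295) # undefined length (encapsulated data)
      pc_stop("encapsulated DICOM pixel data is not supported",
              "unsupported_format_error")
    val_off <- off + hdr
    if (val_off + len > n)
      pc_stop(sprintf("truncated DICOM element at offset %d in '%s'", off, path),
              "io_error")
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0002,0010", "0028,0008")) {
      vraw <- raw[seq(val_off + 1L, length.out = len)]
      tags[[key]] <- trimws(rawToChar(vraw[vraw != as.raw(0)]))
      if (key == "0002,0010") transfer_syntax <- tags[[key]]
    } else if (key %in% c("0028,0010", "0028,0011", "0028,0002",
                          "0028,0100", "0028,0103")) {
      tags[[key]] <- dcm_u16(raw, val_off)
    } else if (key == "7fe0,0010") {
      tags[[key]] <- raw[seq(val_off + 1L, length.out = len)]
    }
    off <- val_off + as.integer(len)
  }
  rows <- tags[["0028,0010"]]; cols <- tags[["0028,0011"]]
  bits <- tags[["0028,0100"]]; pix <- tags[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(bits) || is.null(pix))
    pc_stop(sprintf("DICOM file '%s' lacks image pixel tags", path), "io_error")
  if (!is.null(tags[["0028,0002"]]) && tags[["0028,0002"]] != 1L)
    pc_stop("color (multi-sample) DICOM input is not supported",
            "unsupported_format_error")
  nframes <- suppressWarnings(as.integer(tags[["0028,0008"]]))
  if (length(nframes) == 1L && !is.na(nframes) && nframes != 1L)
    pc_stop("multi-frame DICOM input is not supported", "unsupported_format_error")
  npix <- rows * cols
  if (bits == 8L) {
    if (length(pix) < npix)
      pc_stop("DICOM pixel data shorter than Rows x Columns", "io_error")
    v <- as.integer(pix[seq_len(npix)])
  } else if (bits == 16L) {
    if (length(pix) < 2L * npix)
      pc_stop("DICOM pixel data shorter than Rows x Columns", "io_error")
    signed <- !is.null(tags[["0028,0103"]]) && tags[["0028,0103"]] == 1L
    v <- readBin(pix, "integer", n = npix, size = 2L, signed = signed,
                 endian = "little")
    if (!signed) v <- ifelse(v < 0, v + 65536, v)  # readBin size-2 unsigned quirk
  } else {
    pc_stop(sprintf("unsupported DICOM BitsAllocated = %d", bits),
            "unsupported_format_error")
  }
  m <- matrix(as.numeric(v), nrow = rows, ncol = cols, byrow = TRUE)
  rng <- range(m)
  if (rng[2] > rng[1]) {
    round_half_up((m - rng[1]) / (rng[2] - rng[1]) * 255)
  } else {
    m * 0
  }
}

## ---- control points ---------------------------------------------------------

#' Landmark control-point pairs
#'
#' Ordered pairs of corresponding pixel coordinates on the moving (PET) and
#' fixed (CT) image, used by [fit_affine()]. At least three non-collinear
#' source points are required for the six-parameter affine fit to be unique.
#'
#' @param source numeric `n x 2` matrix of `(x, y)` points on the moving image.
#' @param target numeric `n x 2` matrix of `(x, y)` points on the fixed image.
#' @return an object of class `control_points`.
#' @export
control_points <- function(source, target) {
  source <- as_point_matrix(source, "source")
  target <- as_point_matrix(target, "target")
  if (nrow(source) != nrow(target))
    pc_stop("source and target must have the same number of points",
            "validation_error")
  if (nrow(source) < 3L)
    pc_stop("at least 3 control-point pairs are required", "validation_error")
  if (points_collinear(source))
    pc_stop("source control points are collinear; the affine fit is degenerate",
            "validation_error")
  structure(list(source = source, target = target, n = nrow(source)),
            class = "control_points")
}

as_point_matrix <- function(p, what) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L || anyNA(p) || !all(is.finite(p)))
    pc_stop(sprintf("%s points must be a finite n x 2 matrix", what),
            "validation_error")
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

points_collinear <- function(p) {
  cp <- sweep(p, 2, colMeans(p))
  s <- svd(cp, nu = 0, nv = 0)$d
  s[2] <= 1e-9 * max(s[1], 1)
}

#' @export
print.control_points <- function(x, ...) {
  cat(sprintf("<control_points: %d landmark pairs>\n", x$n))
  print(cbind(x$source, stats::setNames(as.data.frame(x$target), c("x'", "y'"))))
  invisible(x)
}

#' Read control points from CSV
#'
#' The file must have a header `x,y,x_prime,y_prime` and one row per landmark
#' pair: `(x, y)` on the moving PET image, `(x_prime, y_prime)` on the fixed
#' CT image.
#'
#' @param path CSV file path.
#' @return a [control_points()] object.
#' @export
read_control_points <- function(path) {
  if (!file.exists(path))
    pc_stop(sprintf("cannot read control-point file '%s'", path), "io_error")
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("x", "y", "x_prime", "y_prime")
  if (!identical(names(df), required))
    pc_stop(sprintf("control-point file '%s' must have header %s", path,
                    paste(required, collapse = ",")), "parse_error")
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, required))
  bad <- which(apply(is.na(num), 1L, any))
  if (length(bad))
    pc_stop(sprintf("malformed control-point row %d in '%s'", bad[1], path),
            "parse_error")
  control_points(num[, c("x", "y"), drop = FALSE],
                 num[, c("x_prime", "y_prime"), drop = FALSE])
}

#' @rdname read_control_points
#' @param points a [control_points()] object.
#' @export
write_control_points <- function(points, path) {
  df <- data.frame(x = points$source[, 1], y = points$source[, 2],
                   x_prime = points$target[, 1], y_prime = points$target[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- label records and JSON export ------------------------------------------

#' Lesion label record
#'
#' One annotated lesion: its seed, boundary polygon, bounding box, free-text
#' label and SUV class, tied to an image identifier. Coordinates are 0-based
#' `(x = column, y = row)`.
#'
#' @param image_id text identifier of the annotated image.
#' @param lesion_id integer lesion number (>= 1) within the image.
#' @param polygon `n x 2` matrix of ordered boundary vertices (n >= 1).
#' @param bbox numeric `c(x_min, y_min, x_max, y_max)`.
#' @param seed numeric `c(x, y)` refined seed position.
#' @param label_text free text attached by the annotator.
#' @param suv_class one of `"malignant"`, `"critical"`, `"benign"`, `"unknown"`.
#' @param image_size optional `c(width, height)`; when given, all coordinates
#'   are checked against the image bounds.
#' @return an object of class `label_record`.
#' @export
label_record <- function(image_id, lesion_id, polygon, bbox, seed,
                         label_text = "", suv_class = "unknown",
                         image_size = NULL) {
  rec <- structure(list(image_id = as.character(image_id),
                        lesion_id = as.integer(lesion_id),
                        polygon = as_point_matrix(polygon, "polygon"),
                        bbox = as.numeric(bbox),
                        seed = as.numeric(seed),
                        label_text = as.character(label_text),
                        suv_class = as.character(suv_class)),
                   class = "label_record")
  validate_label_record(rec, image_size)
  rec
}

validate_label_record <- function(rec, image_size = NULL) {
  id <- sprintf("record image_id='%s' lesion_id=%s", rec$image_id, rec$lesion_id)
  if (is.na(rec$lesion_id) || rec$lesion_id < 1L)
    pc_stop(sprintf("%s: lesion_id must be >= 1", id), "validation_error")
  if (!rec$suv_class %in% c("malignant", "critical", "benign", "unknown"))
    pc_stop(sprintf("%s: invalid suv_class '%s'", id, rec$suv_class),
            "validation_error")
  b <- rec$bbox
  if (length(b) != 4L || b[1] > b[3] || b[2] > b[4])
    pc_stop(sprintf("%s: bbox must satisfy x_min <= x_max and y_min <= y_max", id),
            "validation_error")
  if (nrow(rec$polygon) < 1L)
    pc_stop(sprintf("%s: polygon needs at least one vertex", id), "validation_error")
  px <- rec$polygon[, 1]; py <- rec$polygon[, 2]
  if (any(px < b[1] | px > b[3] | py < b[2] | py > b[4]))
    pc_stop(sprintf("%s: polygon vertex outside bbox", id), "validation_error")
  if (!is.null(image_size)) {
    w <- image_size[1]; h <- image_size[2]
    all_x <- c(px, b[c(1, 3)], rec$seed[1])
    all_y <- c(py, b[c(2, 4)], rec$seed[2])
    if (any(all_x < 0 | all_x > w - 1 | all_y < 0 | all_y > h - 1))
      pc_stop(sprintf("%s: coordinates outside image bounds", id),
              "validation_error")
  }
  invisible(rec)
}

#' Export lesion label records as JSON
#'
#' Writes the package's annotation schema:
#' `{"images": [{"image_id", "lesions": [{"lesion_id", "seed", "polygon",
#' "bbox", "label_text", "suv_class"}]}]}` with 0-based `(x, y)` coordinates.
#' Records are grouped by `image_id` in order of first appearance.
#'
#' @param records list of [label_record()] objects (may be empty).
#' @param path output JSON path.
#' @export
export_labels <- function(records, path) {
  for (rec in records) {
    if (!inherits(rec, "label_record"))
      pc_stop("export_labels() expects a list of label_record objects",
              "validation_error")
    validate_label_record(rec)
  }
  ids <- vapply(records, function(r) r$image_id, character(1))
  images <- lapply(unique(ids), function(id) {
    lesions <- lapply(records[ids == id], function(r) {
      list(lesion_id = r$lesion_id,
           seed = r$seed,
           polygon = unname(r$polygon),
           bbox = r$bbox,
           label_text = r$label_text,
           suv_class = r$suv_class)
    })
    list(image_id = id, lesions = lesions)
  })
  doc <- list(images = images)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_labels
#' @return `read_labels()`: the list of [label_record()] objects stored in the
#'   file.
#' @export
read_labels <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (im in doc$images) {
    for (les in im$lesions) {
      poly <- do.call(rbind, lapply(les$polygon, as.numeric))
      out[[length(out) + 1L]] <-
        label_record(im$image_id, les$lesion_id, poly,
                     as.numeric(les$bbox), as.numeric(les$seed),
                     les$label_text, les$suv_class)
    }
  }
  out
}
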