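#' Six-parameter affine transform
#'
#' The planar affine map `x' = a*x + b*y + h`, `y' = c*x + d*y + k` used to
#' carry moving-image (PET) coordinates into fixed-image (CT) coordinates.
#' `a, b, c, d` are the dimensionless linear coefficients and `h, k` the
#' translation in pixels.
#'
#' @param a,b,c,d linear coefficients.
#' @param h,k translation components (pixels).
#' @return an object of class `affine_params` (named numeric vector).
#' @examples
#' identity_affine()
#' affine_apply(affine_params(1, 0, 0, 1, 3, -2), cbind(0:2, 0:2))
#' @export
affine_params <- function(a, b, c, d, h, k) {
  p <- c(a = a, b = b, c = c, d = d, h = h, k = k)
  if (!all(is.finite(p)))
    pc_stop("affine parameters must all be finite", "validation_error")
  structure(p, class = "affine_params")
}

#' @rdname affine_params
#' @export
identity_affine <- function() affine_params(1, 0, 0, 1, 0, 0)

#' @export
print.affine_params <- function(x, ...) {
  cat("<affine_params>\n")
  cat(sprintf("  [ %10.6f %10.6f ] [x]   [ %10.6f ]\n", x["a"], x["b"], x["h"]))
  cat(sprintf("  [ %10.6f %10.6f ] [y] + [ %10.6f ]\n", x["c"], x["d"], x["k"]))
  cat(sprintf("  det(linear part) = %.8g\n", affine_det(x)))
  invisible(x)
}

affine_det <- function(p) p[["a"]] * p[["d"]] - p[["b"]] * p[["c"]]

#' @rdname affine_params
#' @param params an `affine_params` object.
#' @param pts numeric `n x 2` matrix of `(x, y)` points.
#' @return `affine_apply()`: the mapped `n x 2` point matrix.
#' @export
affine_apply <- function(params, pts) {
  pts <- as_point_matrix(pts, "input")
  cbind(x = params[["a"]] * pts[, 1] + params[["b"]] * pts[, 2] + params[["h"]],
        y = params[["c"]] * pts[, 1] + params[["d"]] * pts[, 2] + params[["k"]])
}

#' @rdname affine_params
#' @return `affine_invert()`: the inverse transform.
#' @export
affine_invert <- function(params) {
  dt <- affine_det(params)
  if (abs(dt) < 1e-12)
    pc_stop("affine linear part is singular; transform is not invertible",
            "degenerate_geometry_error")
  a <- params[["d"]] / dt; b <- -params[["b"]] / dt
  c <- -params[["c"]] / dt; d <- params[["a"]] / dt
  affine_params(a, b, c, d,
                h = -(a * params[["h"]] + b * params[["k"]]),
                k = -(c * params[["h"]] + d * params[["k"]]))
}

#' @rdname affine_params
#' @param first,second transforms; the composition applies `first`, then
#'   `second`.
#' @export
affine_compose <- function(second, first) {
  a <- second[["a"]] * first[["a"]] + second[["b"]] * first[["c"]]
  b <- second[["a"]] * first[["b"]] + second[["b"]] * first[["d"]]
  c <- second[["c"]] * first[["a"]] + second[["d"]] * first[["c"]]
  d <- second[["c"]] * first[["b"]] + second[["d"]] * first[["d"]]
  h <- second[["a"]] * first[["h"]] + second[["b"]] * first[["k"]] + second[["h"]]
  k <- second[["c"]] * first[["h"]] + second[["d"]] * first[["k"]] + second[["k"]]
  affine_params(a, b, c, d, h, k)
}

#' Fit the PET-to-CT affine by least squares on landmark pairs
#'
#' Estimates the six parameters minimizing the sum of squared landmark
#' residuals `C(a,b,c,d,h,k) = sum(rx_i^2) + sum(ry_i^2)` with
#' `rx_i = a*x_i + b*y_i + h - x'_i` and `ry_i = c*x_i + d*y_i + k - y'_i`.
#' The x- and y-systems decouple into two three-parameter linear fits.
#' `method = "closed_form"` (default) evaluates the centered-sums closed-form
#' solution; `method = "normal"` solves the stacked normal equations
#' `(A'A) X = A'b` directly. Both give the same answer to numerical precision
#' for any non-degenerate landmark set.
#'
#' @param points a [control_points()] object (n >= 3, non-collinear sources).
#' @param method `"closed_form"` or `"normal"`.
#' @return an object of class `affine_fit` with components `params`
#'   ([affine_params()]), `points`, `residuals` (per-point `n x 2` matrix),
#'   `ssr`, `rms` and `method`.
#' @seealso [compute_residuals()], [apply_affine()], [frame_prealign()]
#' @export
fit_affine <- function(points, method = c("closed_form", "normal")) {
  method <- match.arg(method)
  if (!inherits(points, "control_points"))
    points <- control_points(points$source, points$target)
  src <- points$source; dst <- points$target
  p <- switch(method,
              closed_form = fit_affine_closed_form(src, dst),
              normal = fit_affine_normal(src, dst))
  rep_ <- compute_residuals(points, p)
  structure(list(params = p, points = points,
                 residuals = rep_$per_point, ssr = rep_$ssr, rms = rep_$rms,
                 method = method),
            class = "affine_fit")
}

fit_affine_closed_form <- function(src, dst) {
  x <- src[, 1]; y <- src[, 2]; xp <- dst[, 1]; yp <- dst[, 2]
  n <- length(x)
  xb <- mean(x); yb <- mean(y); xpb <- mean(xp); ypb <- mean(yp)
  Sxx <- sum(x * x) - n * xb * xb
  Syy <- sum(y * y) - n * yb * yb
  Sxy <- sum(x * y) - n * xb * yb
  Sxxp <- sum(x * xp) - n * xb * xpb
  Syxp <- sum(y * xp) - n * yb * xpb
  Sxyp <- sum(x * yp) - n * xb * ypb
  Syyp <- sum(y * yp) - n * yb * ypb
  D <- Sxx * Syy - Sxy * Sxy
  if (abs(D) <= 1e-12 * max(Sxx * Syy, 1))
    pc_stop("degenerate landmark geometry: centered normal matrix is singular",
            "degenerate_geometry_error")
  a <- (Sxxp * Syy - Syxp * Sxy) / D
  b <- (Syxp * Sxx - Sxxp * Sxy) / D
  c <- (Sxyp * Syy - Syyp * Sxy) / D
  d <- (Syyp * Sxx - Sxyp * Sxy) / D
  affine_params(a, b, c, d,
                h = xpb - a * xb - b * yb,
                k = ypb - c * xb - d * yb)
}

fit_affine_normal <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2 * n, 6)
  A[seq(1, 2 * n, 2), 1:3] <- cbind(src, 1)
  A[seq(2, 2 * n, 2), 4:6] <- cbind(src, 1)
  rhs <- as.vector(t(dst))
  AtA <- crossprod(A)
  sol <- tryCatch(solve(AtA, crossprod(A, rhs)),
                  error = function(e)
                    pc_stop("degenerate landmark geometry: normal matrix is singular",
                            "degenerate_geometry_error"))
  affine_params(sol[1], sol[2], sol[4], sol[5], sol[3], sol[6])
}

#' Landmark residuals of an affine transform
#'
#' Per-point residuals `rx_i = a*x_i + b*y_i + h - x'_i`,
#' `ry_i = c*x_i + d*y_i + k - y'_i`, their sum of squares
#' `ssr = sum(rx^2 + ry^2)` and the root-mean-square residual
#' `rms = sqrt(ssr / (2n))` (pixels).
#'
#' @param points a [control_points()] object.
#' @param params an [affine_params()] transform.
#' @return list with `per_point` (`n x 2` matrix, columns `rx`, `ry`), `ssr`
#'   and `rms`.
#' @export
compute_residuals <- function(points, params) {
  mapped <- affine_apply(params, points$source)
  r <- mapped - points$target
  colnames(r) <- c("rx", "ry")
  ssr <- sum(r * r)
  list(per_point = r, ssr = ssr, rms = sqrt(ssr / (2 * nrow(r))))
}

#' @export
print.affine_fit <- function(x, ...) {
  cat(sprintf("Affine least-squares registration (%s, %d landmark pairs)\n",
              x$method, x$points$n))
  print(x$params)
  cat(sprintf("  SSR = %.6g px^2, RMS residual = %.6g px\n", x$ssr, x$rms))
  invisible(x)
}

#' @export
summary.affine_fit <- function(object, ...) {
  cat(sprintf("Affine least-squares registration (%s)\n", object$method))
  print(object$params)
  cat(sprintf("  n = %d landmark pairs\n", object$points$n))
  cat(sprintf("  SSR = %.6g px^2, RMS = %.6g px\n", object$ssr, object$rms))
  cat("  per-point residuals (px):\n")
  print(round(object$residuals, 6))
  invisible(object)
}

#' @export
coef.affine_fit <- function(object, ...) unclass(object$params)

#' @export
residuals.affine_fit <- function(object, ...) object$residuals

#' @param object an `affine_fit`.
#' @param newdata optional `n x 2` matrix of source points to map; defaults to
#'   the fitted landmarks.
#' @rdname fit_affine
#' @export
predict.affine_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$points$source
  affine_apply(object$params, newdata)
}

#' Outer-frame pre-alignment of PET and CT
#'
#' A coarse, landmark-free first registration step: the axis-aligned
#' scale-and-shift affine that maps the bounding box of the PET foreground
#' onto the bounding box of the CT foreground. Foreground is defined
#' parameter-free as the pixels differing from the modal (most frequent)
#' intensity on the image border, i.e. everything inside the field-of-view
#' frame. The returned transform has `b = c = 0`.
#'
#' @param pet,ct [gray_image()] objects.
#' @return an [affine_params()] transform (PET coords -> CT coords).
#' @export
frame_prealign <- function(pet, ct) {
  bp <- foreground_bbox(pet)
  bc <- foreground_bbox(ct)
  ax <- box_scale(bp[1], bp[3], bc[1], bc[3])
  ay <- box_scale(bp[2], bp[4], bc[2], bc[4])
  affine_params(ax[1], 0, 0, ay[1], ax[2], ay[2])
}

box_scale <- function(s0, s1, t0, t1) {
  if (s1 > s0) {
    a <- (t1 - t0) / (s1 - s0)
    c(a, t0 - a * s0)
  } else {
    c(1, t0 - s0)  # degenerate one-pixel-wide box: shift only
  }
}

foreground_bbox <- function(img) {
  m <- as.matrix(img)
  border <- c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
  tab <- table(border)
  modal <- as.numeric(names(tab)[which.max(tab)])
  fg <- which(m != modal, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    pc_stop("image has empty foreground; cannot pre-align frames",
            "degenerate_geometry_error")
  # 0-based (x_min, y_min, x_max, y_max)
  c(min(fg[, 2]) - 1, min(fg[, 1]) - 1, max(fg[, 2]) - 1, max(fg[, 1]) - 1)
}

#' Resample an image through an affine transform
#'
#' Pull-based warping: each output pixel `(x', y')` is sampled from the input
#' at the inverse-mapped location by bilinear interpolation; locations outside
#' the input raster are filled with 0.
#'
#' @param img input [gray_image()].
#' @param params [affine_params()] mapping input coordinates to output
#'   coordinates (must be invertible).
#' @param out_size integer `c(width, height)` of the output raster; defaults
#'   to the input size.
#' @return the resampled [gray_image()].
#' @export
apply_affine <- function(img, params, out_size = NULL) {
  m <- as.matrix(img)
  if (is.null(out_size)) out_size <- c(ncol(m), nrow(m))
  ow <- as.integer(out_size[1]); oh <- as.integer(out_size[2])
  inv <- affine_invert(params)
  xo <- matrix(0:(ow - 1), oh, ow, byrow = TRUE)
  yo <- matrix(0:(oh - 1), oh, ow)
  U <- inv[["a"]] * xo + inv[["b"]] * yo + inv[["h"]]
  V <- inv[["c"]] * xo + inv[["d"]] * yo + inv[["k"]]
  out <- bilinear_sample(m, U, V)
  gray_image(out, attr(img, "modality"), attr(img, "source_id"))
}

# sample matrix m (image) at 0-based float coordinates (U = x, V = y);
# 0 outside the raster
bilinear_sample <- function(m, U, V) {
  w <- ncol(m); h <- nrow(m)
  inb <- U >= 0 & U <= (w - 1) & V >= 0 & V <= (h - 1)
  x0 <- pmin(pmax(floor(U), 0), max(w - 2, 0))
  y0 <- pmin(pmax(floor(V), 0), max(h - 2, 0))
  wx <- U - x0; wy <- V - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  idx <- function(yy, xx) as.vector(xx) * h + as.vector(yy) + 1
  v00 <- m[idx(y0, x0)]; v01 <- m[idx(y0, x1)]
  v10 <- m[idx(y1, x0)]; v11 <- m[idx(y1, x1)]
  val <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
    wy * ((1 - wx) * v10 + wx * v11)
  val[!inb] <- 0
  matrix(val, nrow(U), ncol(U))
}
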