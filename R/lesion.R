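#' Region-growing configuration
#'
#' Parameters of the click-seeded lesion grower: the half-width of the square
#' search window used to refine the click into a seed (default 8, i.e. the
#' -8..+8 pixel window), the relative increase of the gray threshold over the
#' seed value (default 1.0, i.e. the growth criterion `gray < 2 * ValueMin`),
#' and the Chebyshev-radius growth cap around the refined seed (default 10
#' pixels up, down, left and right).
#'
#' @param search_halfwidth window half-width in pixels (> 0).
#' @param threshold_increase fractional threshold increase (> 0).
#' @param max_radius Chebyshev radius cap in pixels (> 0).
#' @return an object of class `grow_config`.
#' @export
grow_config <- function(search_halfwidth = 8L, threshold_increase = 1.0,
                        max_radius = 10L) {
  for (v in list(search_halfwidth, threshold_increase, max_radius))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      pc_stop("grow_config values must all be positive", "validation_error")
  structure(list(search_halfwidth = as.integer(search_halfwidth),
                 threshold_increase = threshold_increase,
                 max_radius = as.integer(max_radius)),
            class = "grow_config")
}

#' Refine a click into a seed point
#'
#' Scans the window `click +/- search_halfwidth` (clipped to the image) for
#' the minimum intensity, the presumed center of strongest uptake. Ties are
#' broken by first occurrence in row-major order (top-to-bottom, then
#' left-to-right).
#'
#' @param pet the registered, enhanced PET [gray_image()].
#' @param click numeric `c(x, y)`, 0-based click position.
#' @param cfg a [grow_config()].
#' @return list with `seed` (`c(x, y)`) and `value_min` (the minimum gray).
#' @export
refine_seed <- function(pet, click, cfg = grow_config()) {
  m <- as.matrix(pet)
  w <- ncol(m); h <- nrow(m)
  cx <- as.integer(click[1]); cy <- as.integer(click[2])
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
    pc_stop(sprintf("click (%d, %d) is outside the %d x %d image", cx, cy, w, h),
            "bounds_error")
  hw <- cfg$search_halfwidth
  x0 <- max(0L, cx - hw); x1 <- min(w - 1L, cx + hw)
  y0 <- max(0L, cy - hw); y1 <- min(h - 1L, cy + hw)
  win <- m[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
  flat <- as.vector(t(win))                 # row-major scan order
  i <- which.min(flat)                      # first minimum in that order
  nx <- ncol(win)
  list(seed = c(x = x0 + (i - 1L) %% nx, y = y0 + (i - 1L) %/% nx),
       value_min = flat[i])
}

#' Grow a lesion region from a seed
#'
#' Stack-based 8-neighborhood region growing. A pixel joins the region iff
#' its intensity is strictly below `value_min * (1 + threshold_increase)`
#' (with the default increase of 100%, strictly below twice the seed value)
#' and its Chebyshev distance from the seed is at most `max_radius`. The seed
#' always belongs to the region; a seed value of 0 therefore degenerates to a
#' single-pixel region. Each pixel is visited at most once.
#'
#' @param pet the registered, enhanced PET [gray_image()].
#' @param seed integer `c(x, y)` refined seed (see [refine_seed()]).
#' @param value_min intensity at the seed.
#' @param cfg a [grow_config()].
#' @return an object of class `lesion_region`: list with `seed`, `value_min`,
#'   `members` (`n x 2` integer matrix of member pixels), `boundary` (ordered
#'   polygon from [trace_boundary()]) and `bbox` (from [bounding_rect()]).
#' @export
region_grow <- function(pet, seed, value_min, cfg = grow_config()) {
  m <- as.matrix(pet)
  w <- ncol(m); h <- nrow(m)
  sx <- as.integer(seed[1]); sy <- as.integer(seed[2])
  if (sx < 0 || sx > w - 1 || sy < 0 || sy > h - 1)
    pc_stop("seed is outside the image", "bounds_error")
  if (!isTRUE(all.equal(m[sy + 1L, sx + 1L], value_min)))
    pc_stop("value_min does not match the intensity at the seed",
            "validation_error")
  thr <- value_min * (1 + cfg$threshold_increase)
  r <- cfg$max_radius
  visited <- matrix(FALSE, h, w)
  member <- matrix(FALSE, h, w)
  visited[sy + 1L, sx + 1L] <- TRUE
  member[sy + 1L, sx + 1L] <- TRUE
  dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  stack_x <- integer(512); stack_y <- integer(512)
  stack_x[1] <- sx; stack_y[1] <- sy; top <- 1L
  while (top > 0L) {
    x <- stack_x[top]; y <- stack_y[top]; top <- top - 1L
    for (nb in 1:8) {
      nx <- x + dx[nb]; ny <- y + dy[nb]
      if (nx < 0L || nx > w - 1L || ny < 0L || ny > h - 1L) next
      if (visited[ny + 1L, nx + 1L]) next
      visited[ny + 1L, nx + 1L] <- TRUE
      if (abs(nx - sx) > r || abs(ny - sy) > r) next
      if (!(m[ny + 1L, nx + 1L] < thr)) next          # strict criterion
      member[ny + 1L, nx + 1L] <- TRUE
      top <- top + 1L
      if (top > length(stack_x)) {
        stack_x <- c(stack_x, integer(length(stack_x)))
        stack_y <- c(stack_y, integer(length(stack_y)))
      }
      stack_x[top] <- nx; stack_y[top] <- ny
    }
  }
  idx <- which(member, arr.ind = TRUE)
  members <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
  region <- structure(list(seed = c(x = sx, y = sy), value_min = value_min,
                           members = members, boundary = NULL, bbox = NULL),
                      class = "lesion_region")
  region$boundary <- trace_boundary(region)
  region$bbox <- bounding_rect(region)
  region
}

#' @export
print.lesion_region <- function(x, ...) {
  cat(sprintf("<lesion_region: %d pixels, seed (%d, %d), ValueMin %.4g>\n",
              nrow(x$members), x$seed[1], x$seed[2], x$value_min))
  if (!is.null(x$bbox))
    cat(sprintf("  bbox (x_min, y_min, x_max, y_max) = (%g, %g, %g, %g)\n",
                x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  invisible(x)
}

#' Trace the boundary polygon of a region
#'
#' Moore-neighbor boundary tracing of the member pixel set, clockwise (in
#' image coordinates, y growing downward), starting at the topmost-then-
#' leftmost member pixel. Every returned vertex is a member pixel that
#' touches (8-connectivity) a non-member pixel or the region's outer margin;
#' thin parts of a region may be visited twice, as in any contour walk.
#'
#' @param region a `lesion_region` (or any list with an `n x 2` `members`
#'   matrix of 0-based pixel coordinates).
#' @return ordered `m x 2` matrix of polygon vertices.
#' @export
trace_boundary <- function(region) {
  mem <- region$members
  if (is.null(mem) || nrow(mem) == 0L)
    pc_stop("cannot trace the boundary of an empty region", "validation_error")
  if (nrow(mem) == 1L)
    return(matrix(as.numeric(mem), 1, 2, dimnames = list(NULL, c("x", "y"))))
  # local occupancy grid with a 1-pixel non-member margin
  x0 <- min(mem[, 1]); y0 <- min(mem[, 2])
  gw <- max(mem[, 1]) - x0 + 3L; gh <- max(mem[, 2]) - y0 + 3L
  grid <- matrix(FALSE, gh, gw)
  grid[cbind(mem[, 2] - y0 + 2L, mem[, 1] - x0 + 2L)] <- TRUE
  inside <- function(x, y) grid[y + 1L, x + 1L]  # grid-local 0-based lookup
  # start: topmost then leftmost member (grid coords)
  sy <- min(mem[, 2]) - y0 + 1L
  sx <- min(mem[mem[, 2] - y0 + 1L == sy, 1]) - x0 + 1L
  # clockwise Moore neighborhood (screen coordinates, y down)
  ring <- rbind(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L),
                c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  ring_index <- function(d) which(ring[, 1] == d[1] & ring[, 2] == d[2])
  cur <- c(sx, sy)
  back <- c(sx - 1L, sy)                     # entered from the left (non-member)
  path <- matrix(0L, 4L * nrow(mem) + 8L, 2L)
  path[1L, ] <- cur; np <- 1L
  start_back <- back
  repeat {
    start_dir <- ring_index(back - cur)
    found <- FALSE
    prev <- back
    for (s in 1:8) {
      d <- ring[(start_dir + s - 1L) %% 8L + 1L, ]
      cand <- cur + d
      if (inside(cand[1], cand[2])) {
        back <- prev
        cur <- cand
        found <- TRUE
        break
      }
      prev <- cand
    }
    if (!found) break                        # isolated pixel among members
    if (cur[1] == sx && cur[2] == sy && all(back == start_back)) break
    np <- np + 1L
    if (np > nrow(path)) path <- rbind(path, path)  # safety growth
    path[np, ] <- cur
    if (np > 8L * nrow(mem) + 16L) break     # safety stop
  }
  out <- path[seq_len(np), , drop = FALSE]
  out <- cbind(out[, 1] + x0 - 1L, out[, 2] + y0 - 1L)  # back to image coords
  colnames(out) <- c("x", "y")
  out
}

#' Tight bounding rectangle of a region
#'
#' The axis-aligned rectangle `(x_min, y_min, x_max, y_max)` spanned by the
#' member pixels; its four corners `(x_min, y_max)`, `(x_max, y_max)`,
#' `(x_max, y_min)`, `(x_min, y_min)` enclose every member.
#'
#' @param region a `lesion_region` (or list with a `members` matrix).
#' @return numeric `c(x_min, y_min, x_max, y_max)`.
#' @export
bounding_rect <- function(region) {
  mem <- region$members
  if (is.null(mem) || nrow(mem) == 0L)
    pc_stop("cannot bound an empty region", "validation_error")
  c(x_min = min(mem[, 1]), y_min = min(mem[, 2]),
    x_max = max(mem[, 1]), y_max = max(mem[, 2]))
}

#' Map a lesion region into CT coordinates
#'
#' After the pipeline has resampled PET into CT space the transform is the
#' identity and coordinates transfer unchanged. Otherwise every member pixel
#' is mapped through `pet_to_ct`, rounded half up to the CT grid, de-
#' duplicated, and the boundary polygon and bounding box are recomputed.
#'
#' @param region a `lesion_region`.
#' @param pet_to_ct an [affine_params()] transform (must be invertible).
#' @return the mapped `lesion_region`.
#' @export
map_region_to_ct <- function(region, pet_to_ct = identity_affine()) {
  if (abs(affine_det(pet_to_ct)) < 1e-12)
    pc_stop("pet_to_ct transform is not invertible", "degenerate_geometry_error")
  if (identical(unclass(pet_to_ct), unclass(identity_affine())))
    return(region)
  mapped <- round_half_up(affine_apply(pet_to_ct, region$members))
  mapped <- unique(mapped)
  storage.mode(mapped) <- "integer"
  colnames(mapped) <- c("x", "y")
  seed <- round_half_up(affine_apply(pet_to_ct, matrix(region$seed, 1, 2)))[1, ]
  out <- structure(list(seed = c(x = seed[1], y = seed[2]),
                        value_min = region$value_min,
                        members = mapped, boundary = NULL, bbox = NULL),
                   class = "lesion_region")
  out$boundary <- trace_boundary(out)
  out$bbox <- bounding_rect(out)
  out
}

#' Standardized uptake value
#'
#' `SUV = concentration / (dose / weight)`: lesion radioactivity
#' concentration (kBq/mL) divided by the injected dose per kilogram of body
#' weight (MBq/kg). Dimensionless by the usual clinical convention.
#'
#' @param concentration lesion radioactivity concentration, kBq/mL.
#' @param dose injected dose, MBq (> 0).
#' @param weight body weight, kg (> 0).
#' @return the SUV value.
#' @export
compute_suv <- function(concentration, dose, weight) {
  stopifnot_scalar_num(concentration, "concentration")
  stopifnot_scalar_num(dose, "dose")
  stopifnot_scalar_num(weight, "weight")
  if (dose <= 0 || weight <= 0)
    pc_stop("dose and weight must be positive", "validation_error")
  concentration / (dose / weight)
}

#' Classify a lesion by its SUV
#'
#' The clinical rule of thumb for 18F-FDG uptake: `SUV > 2.5` suggests a
#' malignant tumor, `2.0 <= SUV <= 2.5` is the critical (indeterminate)
#' range, and `SUV < 2.0` a benign lesion.
#'
#' @param suv non-negative SUV value.
#' @return one of `"malignant"`, `"critical"`, `"benign"`.
#' @export
classify_suv <- function(suv) {
  stopifnot_scalar_num(suv, "suv")
  if (suv < 0)
    pc_stop("suv must be non-negative", "validation_error")
  if (suv > 2.5) "malignant" else if (suv >= 2.0) "critical" else "benign"
}

#' Pixel-overlap agreement between system and manual masks
#'
#' The comparison used to validate semi-automatic labels against an expert's
#' manual mask: `recognition_rate = |system intersect manual| / |manual| * 100`
#' and `false_positive_rate = |system \ manual| / |manual| * 100`, both in
#' percent of the manually marked pixel count.
#'
#' @param system_mask,manual_mask either a logical matrix (TRUE = member) or
#'   an `n x 2` matrix of 0-based `(x, y)` pixel coordinates. The manual mask
#'   must be nonempty.
#' @return named numeric `c(recognition_rate, false_positive_rate)` in percent.
#' @export
agreement_metrics <- function(system_mask, manual_mask) {
  sys_k <- mask_keys(system_mask)
  man_k <- mask_keys(manual_mask)
  if (length(man_k) == 0L)
    pc_stop("manual mask is empty", "validation_error")
  c(recognition_rate = 100 * sum(sys_k %in% man_k) / length(man_k),
    false_positive_rate = 100 * sum(!sys_k %in% man_k) / length(man_k))
}

mask_keys <- function(mask) {
  if (is.logical(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    pts <- cbind(idx[, 2] - 1L, idx[, 1] - 1L)
  } else {
    pts <- as.matrix(mask)
  }
  if (nrow(pts) == 0L) return(character(0))
  unique(paste(pts[, 1], pts[, 2], sep = ","))
}
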