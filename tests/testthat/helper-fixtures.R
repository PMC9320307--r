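# fixtures are synthesized in code at test time; nothing binary ships with
# the package

# minimal explicit-VR little-endian DICOM writer for reader tests
write_test_dicom <- function(values, path, bits = 16L) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem <- function(group, el, vr, payload) {
    u16(group); u16(el)
    writeChar(vr, con, nchars = 2, eos = NULL)
    if (vr %in% c("OB", "OW")) {
      u16(0L)
      writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    } else {
      u16(length(payload))
    }
    writeBin(payload, con)
  }
  str_payload <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
    r
  }
  us_payload <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                     endian = "little")
  values <- as.matrix(values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  elem(0x0002, 0x0010, "UI", str_payload("1.2.840.10008.1.2.1"))
  elem(0x0028, 0x0002, "US", us_payload(1L))
  elem(0x0028, 0x0010, "US", us_payload(nrow(values)))
  elem(0x0028, 0x0011, "US", us_payload(ncol(values)))
  elem(0x0028, 0x0100, "US", us_payload(bits))
  elem(0x0028, 0x0103, "US", us_payload(0L))
  pix <- as.integer(t(values))  # row-major pixel order
  payload <- if (bits == 8L) as.raw(pix) else
    writeBin(pix, raw(), size = 2, endian = "little")
  elem(0x7FE0, 0x0010, "OW", payload)
  invisible(path)
}

# brute-force flood fill under the growth predicate, by repeated dilation;
# independent of the stack-based implementation under test
grow_oracle <- function(m, seed, value_min, threshold_increase = 1.0,
                        max_radius = 10L) {
  h <- nrow(m); w <- ncol(m)
  thr <- value_min * (1 + threshold_increase)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  allowed <- (m < thr) &
    pmax(abs(xs - seed[1]), abs(ys - seed[2])) <= max_radius
  region <- matrix(FALSE, h, w)
  region[seed[2] + 1, seed[1] + 1] <- TRUE
  repeat {
    grown <- region
    # 8-neighborhood dilation by shifting in all directions
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      src_r <- max(1, 1 - dy):min(h, h - dy)
      src_c <- max(1, 1 - dx):min(w, w - dx)
      grown[src_r + dy, src_c + dx] <- grown[src_r + dy, src_c + dx] |
        region[src_r, src_c]
    }
    grown <- (grown & allowed) | region
    if (identical(grown, region)) break
    region <- grown
  }
  idx <- which(region, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

# boundary predicate oracle: members with an edge-adjacent (4-neighbor)
# non-member, the classical characterization of the Moore contour
boundary_oracle <- function(members) {
  key <- function(p) paste(p[, 1], p[, 2], sep = ",")
  inset <- key(members)
  shifts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  is_boundary <- vapply(seq_len(nrow(members)), function(i) {
    for (s in 1:4) {
      if (!(paste(members[i, 1] + shifts[s, 1], members[i, 2] + shifts[s, 2],
                  sep = ",") %in% inset))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  members[is_boundary, , drop = FALSE]
}

point_set_key <- function(pts) sort(paste(pts[, 1], pts[, 2], sep = ","))

# random non-degenerate landmark geometry + generating affine
random_affine_case <- function(n = 5) {
  repeat {
    src <- matrix(stats::runif(2 * n, 0, 200), n, 2)
    ok <- tryCatch({control_points(src, src); TRUE},
                   error = function(e) FALSE)
    if (ok) break
  }
  tru <- affine_params(1 + stats::rnorm(1, 0, 0.05), stats::rnorm(1, 0, 0.02),
                       stats::rnorm(1, 0, 0.02), 1 + stats::rnorm(1, 0, 0.05),
                       stats::rnorm(1, 0, 5), stats::rnorm(1, 0, 5))
  list(src = src, truth = tru, dst = affine_apply(tru, src))
}
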