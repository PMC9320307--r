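test_that("seed refinement scans the clipped window with row-major ties", {
  # flat image: first row-major cell of the window wins
  flat <- gray_image(matrix(77, 64, 64), "PET")
  got <- refine_seed(flat, c(20, 20))
  expect_equal(unname(got$seed), c(12, 12))
  expect_equal(got$value_min, 77)

  # unique minimum inside the 17x17 window is found
  m <- matrix(200, 64, 64); m[19, 26] <- 3   # (x=25, y=18)
  got2 <- refine_seed(gray_image(m, "PET"), c(20, 20))
  expect_equal(unname(got2$seed), c(25, 18))
  expect_equal(got2$value_min, 3)

  # corner click clips the window instead of erroring
  got3 <- refine_seed(flat, c(0, 0))
  expect_equal(unname(got3$seed), c(0, 0))

  expect_error(refine_seed(flat, c(64, 10)), class = "bounds_error")
})

test_that("region growing obeys the strict doubled-threshold criterion", {
  # uniform image: criterion always true, the Chebyshev cap governs
  img <- gray_image(matrix(60, 64, 64), "PET")
  r <- region_grow(img, c(30, 30), 60)
  expect_equal(nrow(r$members), 441)
  expect_true(all(pmax(abs(r$members[, 1] - 30), abs(r$members[, 2] - 30)) <= 10))

  # neighbor at 99 joins a seed of 50; neighbor at 100 does not (100 !< 100)
  m <- matrix(200, 32, 32)
  m[16, 16] <- 50; m[16, 17] <- 99; m[16, 18] <- 100
  r2 <- region_grow(gray_image(m, "PET"), c(15, 15), 50)
  keys <- point_set_key(r2$members)
  expect_true("16,15" %in% keys)
  expect_false("17,15" %in% keys)

  # dark disk on bright background grows to exactly the disk
  m3 <- matrix(200, 64, 64)
  xs <- matrix(0:63, 64, 64, byrow = TRUE); ys <- matrix(0:63, 64, 64)
  disk <- (xs - 30)^2 + (ys - 30)^2 <= 25
  m3[disk] <- 10
  r3 <- region_grow(gray_image(m3, "PET"), c(30, 30), 10)
  idx <- which(disk, arr.ind = TRUE)
  expect_setequal(point_set_key(r3$members),
                  point_set_key(cbind(idx[, 2] - 1L, idx[, 1] - 1L)))

  # seed value 0: criterion never true, single-pixel region
  m4 <- matrix(5, 16, 16); m4[9, 9] <- 0
  r4 <- region_grow(gray_image(m4, "PET"), c(8, 8), 0)
  expect_equal(nrow(r4$members), 1L)

  expect_error(region_grow(img, c(30, 30), 59), class = "validation_error")
})

test_that("region growing equals the brute-force flood-fill oracle", {
  set.seed(31)
  for (rep in 1:100) {
    m <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    seed <- c(sample(0:63, 1), sample(0:63, 1))
    vm <- m[seed[2] + 1, seed[1] + 1]
    got <- region_grow(gray_image(m, "PET"), seed, vm)
    want <- grow_oracle(m, seed, vm)
    expect_identical(point_set_key(got$members), point_set_key(want))
  }
})

test_that("members satisfy the criterion; excluded neighbors violate it", {
  set.seed(32)
  cfg <- grow_config()
  for (rep in 1:10) {
    m <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    seed <- c(sample(5:58, 1), sample(5:58, 1))
    vm <- m[seed[2] + 1, seed[1] + 1]
    r <- region_grow(gray_image(m, "PET"), seed, vm, cfg)
    thr <- vm * 2
    mem <- r$members
    keys <- point_set_key(mem)
    non_seed <- !(mem[, 1] == seed[1] & mem[, 2] == seed[2])
    expect_true(all(m[cbind(mem[non_seed, 2] + 1, mem[non_seed, 1] + 1)] < thr))
    expect_true(all(pmax(abs(mem[, 1] - seed[1]),
                         abs(mem[, 2] - seed[2])) <= cfg$max_radius))
    # every excluded 8-neighbor of a member violates criterion or cap
    for (i in seq_len(nrow(mem))) {
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        nx <- mem[i, 1] + dx; ny <- mem[i, 2] + dy
        if (nx < 0 || nx > 63 || ny < 0 || ny > 63) next
        if (paste(nx, ny, sep = ",") %in% keys) next
        ok_value <- m[ny + 1, nx + 1] < thr
        ok_dist <- max(abs(nx - seed[1]), abs(ny - seed[2])) <= cfg$max_radius
        expect_false(ok_value && ok_dist)
      }
    }
  }
})

test_that("boundary tracing is clockwise from the topmost-leftmost pixel", {
  single <- list(members = cbind(x = 5L, y = 5L))
  expect_equal(trace_boundary(single), cbind(x = 5, y = 5), ignore_attr = TRUE)

  square <- list(members = cbind(x = rep(0:2, 3), y = rep(0:2, each = 3)))
  got <- trace_boundary(square)
  want <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(2, 2),
                c(1, 2), c(0, 2), c(0, 1))
  expect_equal(unname(got), want)

  expect_error(trace_boundary(list(members = cbind(x = integer(0),
                                                   y = integer(0)))),
               class = "validation_error")
})

test_that("traced vertices equal the boundary-predicate oracle on blobs", {
  set.seed(33)
  for (rep in 1:20) {
    # simply connected random blob: union of two overlapping disks
    c1 <- c(sample(8:20, 1), sample(8:20, 1))
    c2 <- c1 + sample(-3:3, 2, replace = TRUE)
    r1 <- sample(3:6, 1); r2 <- sample(2:5, 1)
    xs <- matrix(0:31, 32, 32, byrow = TRUE); ys <- matrix(0:31, 32, 32)
    mask <- (xs - c1[1])^2 + (ys - c1[2])^2 <= r1^2 |
      (xs - c2[1])^2 + (ys - c2[2])^2 <= r2^2
    idx <- which(mask, arr.ind = TRUE)
    mem <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
    trace <- trace_boundary(list(members = mem))
    expect_setequal(point_set_key(unique(trace)),
                    point_set_key(boundary_oracle(mem)))
  }
})

test_that("bounding rectangles are tight", {
  mem <- cbind(x = c(3L, 9L, 5L), y = c(4L, 12L, 5L))
  expect_equal(unname(bounding_rect(list(members = mem))), c(3, 4, 9, 12))
  expect_equal(unname(bounding_rect(list(members = cbind(x = 7L, y = 7L)))),
               c(7, 7, 7, 7))
  full <- expand.grid(x = 0:9, y = 0:7)
  expect_equal(unname(bounding_rect(list(members = as.matrix(full)))),
               c(0, 0, 9, 7))
})

test_that("regions map to CT space consistently", {
  img <- gray_image(matrix(60, 64, 64), "PET")
  r <- region_grow(img, c(30, 30), 60)
  same <- map_region_to_ct(r, identity_affine())
  expect_identical(same$members, r$members)

  shifted <- map_region_to_ct(r, affine_params(1, 0, 0, 1, 10, 0))
  expect_equal(shifted$members[, 1], r$members[, 1] + 10L, ignore_attr = TRUE)
  expect_equal(shifted$members[, 2], r$members[, 2], ignore_attr = TRUE)
  expect_equal(unname(shifted$bbox),
               unname(bounding_rect(list(members = shifted$members))))

  scaled <- map_region_to_ct(r, affine_params(1.5, 0, 0, 1.5, 0.3, -0.2))
  expect_equal(unname(scaled$bbox),
               unname(bounding_rect(list(members = scaled$members))))

  expect_error(map_region_to_ct(r, affine_params(1, 1, 1, 1, 0, 0)),
               class = "degenerate_geometry_error")
})

test_that("SUV follows the concentration per dose-per-kilogram convention", {
  expect_equal(compute_suv(5, 370, 74), 1.0)
  expect_equal(compute_suv(0, 370, 74), 0)
  expect_equal(compute_suv(5, 370, 148), 2 * compute_suv(5, 370, 74))
  expect_error(compute_suv(5, 0, 74), class = "validation_error")
  expect_error(compute_suv(5, 370, -1), class = "validation_error")
})

test_that("SUV classification partitions [0, Inf) with the printed cut-offs", {
  expect_equal(classify_suv(3.0), "malignant")
  expect_equal(classify_suv(2.2), "critical")
  expect_equal(classify_suv(1.9), "benign")
  expect_equal(classify_suv(2.0), "critical")
  expect_equal(classify_suv(2.5), "critical")
  for (s in seq(0, 5, by = 0.1))
    expect_length(intersect(classify_suv(s),
                            c("malignant", "critical", "benign")), 1)
  expect_error(classify_suv(-0.1), class = "validation_error")
})

test_that("agreement metrics implement the pixel-overlap formulas", {
  manual <- cbind(x = rep(0:9, 10), y = rep(0:9, each = 10))
  expect_equal(unname(agreement_metrics(manual, manual)), c(100, 0))
  half <- manual[manual[, 1] < 5, ]
  expect_equal(unname(agreement_metrics(half, manual)), c(50, 0))
  extra <- rbind(manual, cbind(x = 20:29, y = rep(0L, 10)))
  expect_equal(unname(agreement_metrics(extra, manual)), c(100, 10))
  expect_error(agreement_metrics(manual, manual[integer(0), ]),
               class = "validation_error")
  # logical-matrix masks agree with coordinate masks
  lg <- matrix(FALSE, 16, 16); lg[2:4, 3:5] <- TRUE
  idx <- which(lg, arr.ind = TRUE)
  expect_equal(agreement_metrics(lg, cbind(idx[, 2] - 1L, idx[, 1] - 1L)),
               c(recognition_rate = 100, false_positive_rate = 0))
})
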