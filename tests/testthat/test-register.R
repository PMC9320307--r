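test_that("identity and pure translations are recovered exactly", {
  src <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  fit <- fit_affine(control_points(src, src))
  expect_equal(unname(coef(fit)), c(1, 0, 0, 1, 0, 0), tolerance = 1e-12)

  dst <- sweep(src, 2, c(3, -2), "+")
  fit2 <- fit_affine(control_points(src, dst))
  expect_equal(unname(coef(fit2)), c(1, 0, 0, 1, 3, -2), tolerance = 1e-12)
  expect_equal(fit2$ssr, 0, tolerance = 1e-18)
})

test_that("a known generating affine is recovered to 1e-9 (n = 5, no noise)", {
  src <- rbind(c(12, 7), c(110, 15), c(30, 140), c(150, 130), c(80, 60))
  tru <- affine_params(1.02, 0.01, -0.01, 0.98, 4, -3)
  fit <- fit_affine(control_points(src, affine_apply(tru, src)))
  expect_lt(max(abs(coef(fit) - unclass(tru))), 1e-9)
})

test_that("closed form and normal equations agree on random geometries", {
  set.seed(101)
  for (rep in 1:100) {
    case <- random_affine_case(n = sample(3:8, 1))
    noisy <- case$dst + matrix(rnorm(2 * nrow(case$dst), 0, 0.5),
                               ncol = 2)
    pts <- control_points(case$src, noisy)
    cf <- coef(fit_affine(pts, method = "closed_form"))
    ne <- coef(fit_affine(pts, method = "normal"))
    expect_lt(max(abs(cf - ne)), 1e-9)
  }
})

test_that("the fitted solution is a local SSR minimum under perturbation", {
  set.seed(102)
  case <- random_affine_case(n = 6)
  noisy <- case$dst + matrix(rnorm(12, 0, 0.5), ncol = 2)
  pts <- control_points(case$src, noisy)
  fit <- fit_affine(pts)
  base <- fit$ssr
  p0 <- coef(fit)
  for (i in 1:1000) {
    pert <- p0 + rnorm(6, 0, 1e-3)
    ssr <- compute_residuals(pts, do.call(affine_params, as.list(pert)))$ssr
    expect_gte(ssr, base)
  }
})

test_that("residual report matches hand arithmetic", {
  src <- rbind(c(0, 0), c(10, 0), c(0, 10))
  dst <- rbind(c(1, 1), c(10, 0), c(0, 10))
  rep_ <- compute_residuals(control_points(src, dst), identity_affine())
  expect_equal(unname(rep_$per_point[1, ]), c(-1, -1))
  expect_equal(unname(rep_$per_point[2, ]), c(0, 0))
  expect_equal(rep_$ssr, 2)
  expect_equal(rep_$rms, sqrt(2 / 6))

  # residual-free fit, then shift every target x by +1: ssr = n
  case <- list(src = rbind(c(0, 0), c(5, 1), c(2, 7), c(9, 9)))
  dst2 <- affine_apply(affine_params(1.1, 0, 0, 0.9, 2, 1), case$src)
  fit <- fit_affine(control_points(case$src, dst2))
  shifted <- dst2; shifted[, 1] <- shifted[, 1] + 1
  rep2 <- compute_residuals(control_points(case$src, shifted), fit$params)
  expect_equal(rep2$ssr, 4, tolerance = 1e-10)
})

test_that("residuals are orthogonal to the design columns", {
  set.seed(103)
  for (rep in 1:25) {
    case <- random_affine_case(n = sample(4:9, 1))
    noisy <- case$dst + matrix(rnorm(2 * nrow(case$dst), 0, 1), ncol = 2)
    pts <- control_points(case$src, noisy)
    r <- residuals(fit_affine(pts))
    x <- pts$source[, 1]; y <- pts$source[, 2]
    moments <- c(sum(r[, 1]), sum(r[, 2]),
                 sum(r[, 1] * x), sum(r[, 1] * y),
                 sum(r[, 2] * x), sum(r[, 2] * y))
    expect_lt(max(abs(moments)), 1e-6)
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(control_points(rbind(c(0, 0), c(1, 1), c(2, 2)),
                              rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "validation_error")
  expect_error(control_points(rbind(c(0, 0), c(1, 1)),
                              rbind(c(0, 0), c(1, 1))),
               class = "validation_error")
})

test_that("affine_fit behaves like a classed model object", {
  case <- random_affine_case(n = 5)
  fit <- fit_affine(control_points(case$src, case$dst))
  expect_s3_class(fit, "affine_fit")
  expect_named(coef(fit), c("a", "b", "c", "d", "h", "k"))
  expect_equal(predict(fit), case$dst, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(dim(residuals(fit)), c(5L, 2L))
  expect_output(print(fit), "Affine least-squares")
  expect_output(summary(fit), "per-point residuals")
})

test_that("outer-frame pre-alignment maps foreground box onto foreground box", {
  pet <- matrix(0, 120, 120); pet[1:100, 1:100] <- 50   # box (0,0)-(99,99)
  ct <- matrix(0, 240, 240); ct[1:200, 1:200] <- 80     # box (0,0)-(199,199)
  pre <- frame_prealign(gray_image(pet, "PET"), gray_image(ct, "CT"))
  expect_equal(unname(unclass(pre)),
               c(199 / 99, 0, 0, 199 / 99, 0, 0))

  same <- gray_image(pet, "PET")
  pre2 <- frame_prealign(same, gray_image(pet, "CT"))
  expect_equal(unname(unclass(pre2)), c(1, 0, 0, 1, 0, 0))

  expect_error(frame_prealign(gray_image(matrix(5, 10, 10), "PET"),
                              gray_image(ct, "CT")),
               class = "degenerate_geometry_error")
})

test_that("affine resampling: identity, integer translation, constants", {
  set.seed(104)
  m <- matrix(runif(400, 0, 255), 20, 20)
  img <- gray_image(m, "PET")
  expect_equal(as.matrix(apply_affine(img, identity_affine())), m)

  spot <- matrix(0, 30, 30); spot[11, 11] <- 200  # bright pixel at (10,10)
  out <- as.matrix(apply_affine(gray_image(spot, "PET"),
                                affine_params(1, 0, 0, 1, 5, 0)))
  expect_equal(out[11, 16], 200)                   # now at (15,10)
  expect_equal(sum(out != 0), 1)

  const <- gray_image(matrix(100, 40, 40), "CT")
  warped <- as.matrix(apply_affine(const, affine_params(1.05, 0.02, -0.01,
                                                        0.97, 1, -2)))
  expect_equal(warped[10:30, 10:30], matrix(100, 21, 21), tolerance = 1e-9)

  expect_error(apply_affine(img, affine_params(1, 2, 0.5, 1, 0, 0)),
               class = "degenerate_geometry_error")
})

test_that("composition and inversion are consistent with point mapping", {
  A <- affine_params(1.1, 0.1, -0.05, 0.9, 3, -1)
  B <- affine_params(0.95, -0.02, 0.04, 1.05, -2, 5)
  pts <- rbind(c(1, 2), c(30, 40), c(-5, 17))
  expect_equal(affine_apply(affine_compose(B, A), pts),
               affine_apply(B, affine_apply(A, pts)))
  expect_equal(affine_apply(affine_compose(affine_invert(A), A), pts), pts,
               tolerance = 1e-10, ignore_attr = TRUE)
})
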