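test_that("8-bit PNG round trip is bit-exact and preserves constants", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "const.png")
  img <- gray_image(matrix(7, 20, 30), "PET", "const")
  write_gray_image(img, p)
  back <- read_gray_image(p, "PET")
  expect_equal(as.matrix(back), as.matrix(img))
  expect_identical(image_modality(back), "PET")

  set.seed(11)
  m <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  p2 <- file.path(tmp, "rand.png")
  write_gray_image(gray_image(m, "CT"), p2)
  expect_equal(as.matrix(read_gray_image(p2, "CT")), m)
})

test_that("export quantizes floats by rounding half up", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "half.png")
  write_gray_image(gray_image(matrix(127.5, 4, 4), "PET"), p)
  expect_equal(as.matrix(read_gray_image(p, "PET")), matrix(128, 4, 4))
})

test_that("unwritable paths and unreadable files raise I/O errors", {
  expect_error(write_gray_image(gray_image(matrix(1, 2, 2), "CT"),
                                file.path(tempdir(), "no_such_dir", "x.png")),
               class = "io_error")
  expect_error(read_gray_image(file.path(tempdir(), "missing.png"), "CT"),
               class = "io_error")
})

test_that("color PNG input is rejected as unsupported", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "rgb.png")
  png::writePNG(array(runif(4 * 4 * 3), c(4, 4, 3)), p)
  expect_error(read_gray_image(p, "PET"), class = "unsupported_format_error")
})

test_that("grayscale TIFF input passes through unchanged", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "g.tif")
  m <- matrix(c(0, 64, 128, 255), 2, 2)
  tiff::writeTIFF(m / 255, p)
  expect_equal(as.matrix(read_gray_image(p, "CT")), m)
})

test_that("DICOM stored values are min-max rescaled with round half up", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "s.dcm")
  write_test_dicom(matrix(c(0, 500, 1000, 1000), 2, 2, byrow = TRUE), p)
  got <- as.matrix(read_gray_image(p, "CT"))
  expect_equal(got, matrix(c(0, 128, 255, 255), 2, 2, byrow = TRUE))
})

test_that("8-bit DICOM and pixel geometry are read correctly", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "s8.dcm")
  m <- matrix(0:11 * 20, 3, 4, byrow = TRUE)
  write_test_dicom(m, p, bits = 8L)
  got <- as.matrix(read_gray_image(p, "PET"))
  expect_equal(dim(got), c(3L, 4L))
  # min-max rescale of 0..220 onto 0..255
  expect_equal(got, round(floor((m / 220) * 255 + 0.5)))
})

test_that("control-point files parse, validate and round trip", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "pts.csv")
  writeLines(c("x,y,x_prime,y_prime", "0,0,1,1", "10,0,11,1",
               "0,10,1,11", "10,10,11,11"), p)
  pts <- read_control_points(p)
  expect_equal(pts$n, 4L)
  expect_equal(pts$target - pts$source, matrix(1, 4, 2),
               ignore_attr = TRUE)
  p2 <- file.path(tmp, "pts2.csv")
  write_control_points(pts, p2)
  expect_equal(read_control_points(p2)$source, pts$source)

  writeLines(c("x,y,x_prime,y_prime", "0,0,1,1", "1,1,2,2"), p)
  expect_error(read_control_points(p), class = "validation_error")
  writeLines(c("x,y,x_prime,y_prime", "0,0,0,0", "1,1,1,1", "2,2,2,2"), p)
  expect_error(read_control_points(p), class = "validation_error")
  writeLines(c("x,y,x_prime,y_prime", "0,0,1,1", "oops,0,1,1", "0,9,1,10"), p)
  expect_error(read_control_points(p), regexp = "row 2", class = "parse_error")
})

test_that("label export writes the documented schema and re-imports equal", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "labels.json")
  rec <- label_record("img_001", 1L,
                      polygon = rbind(c(3, 4), c(9, 4), c(9, 12), c(3, 12)),
                      bbox = c(3, 4, 9, 12), seed = c(5, 6),
                      label_text = "lymphoma", suv_class = "malignant")
  export_labels(list(rec), p)
  doc <- jsonlite::read_json(p)
  expect_equal(unlist(doc$images[[1]]$lesions[[1]]$bbox), c(3, 4, 9, 12))
  expect_equal(doc$images[[1]]$image_id, "img_001")
  back <- read_labels(p)
  expect_length(back, 1)
  expect_equal(back[[1]]$polygon, rec$polygon)
  expect_equal(back[[1]]$suv_class, "malignant")

  export_labels(list(), p)
  expect_length(jsonlite::read_json(p)$images, 0)
})

test_that("label records enforce their geometric invariants", {
  expect_error(label_record("i", 1L, polygon = rbind(c(0, 0), c(20, 0)),
                            bbox = c(0, 0, 9, 9), seed = c(1, 1)),
               class = "validation_error")
  expect_error(label_record("i", 1L, polygon = rbind(c(5, 5)),
                            bbox = c(6, 0, 2, 9), seed = c(1, 1)),
               class = "validation_error")
  expect_error(label_record("i", 0L, polygon = rbind(c(1, 1)),
                            bbox = c(0, 0, 2, 2), seed = c(1, 1)),
               class = "validation_error")
  expect_error(label_record("i", 1L, polygon = rbind(c(1, 1)),
                            bbox = c(0, 0, 2, 2), seed = c(1, 1),
                            image_size = c(2, 2), suv_class = "benign"),
               class = "validation_error")
})
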