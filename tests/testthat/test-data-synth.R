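test_that("staging thresholds and boundary convention", {
  expect_identical(grade_from_fat_fraction(c(0.04, 0.20, 0.50, 0.70)),
                   c(0L, 1L, 2L, 3L))
  expect_identical(grade_from_fat_fraction(c(0, 1)), c(0L, 3L))
  # shared boundaries belong to the higher grade (left-closed)
  expect_identical(grade_from_fat_fraction(c(0.05, 0.33, 0.66)),
                   c(1L, 2L, 3L))
  expect_error(grade_from_fat_fraction(1.2), "\\[0, 1\\]")
  expect_error(grade_from_fat_fraction(-0.1), "\\[0, 1\\]")
})

test_that("grade is a monotone step function and binarize respects it", {
  fr <- seq(0, 1, by = 0.01)
  g <- grade_from_fat_fraction(fr)
  expect_true(all(diff(g) >= 0))
  lab <- binarize_grade(g)
  expect_identical(unique(lab[g <= 1]), "suitable")
  expect_identical(unique(lab[g >= 2]), "not_suitable")
  expect_identical(binarize_grade(0L), "suitable")
  expect_identical(binarize_grade(2L), "not_suitable")
  expect_identical(binarize_grade(3L), "not_suitable")
  expect_error(binarize_grade(4L), "grade")
})

test_that("slide tiling is a row-major partition with discard rule", {
  img <- array(runif(40 * 48 * 3), c(40, 48, 3))
  tiles <- tile_slide(img, 10)
  expect_length(tiles, 4 * 4) # 48 %/% 10 = 4 columns, floor discard
  expect_identical(tiles[[1]]$row, 1L)
  expect_identical(tiles[[2]]$col, 2L)
  # disjoint cover: reassembling the tiles reproduces the cropped region
  rec <- array(NA_real_, c(40, 40, 3))
  for (t in tiles) {
    rows <- ((t$row - 1) * 10 + 1):(t$row * 10)
    cols <- ((t$col - 1) * 10 + 1):(t$col * 10)
    expect_true(all(is.na(rec[rows, cols, ]))) # no overlap
    rec[rows, cols, ] <- t$pixels
  }
  expect_identical(rec, img[1:40, 1:40, ])

  # one-tile and degenerate cases
  small <- array(0, c(11, 11, 3))
  one <- tile_slide(small, 10)
  expect_length(one, 1L)
  expect_identical(c(one[[1]]$row, one[[1]]$col), c(1L, 1L))
  expect_warning(none <- tile_slide(array(0, c(9, 20, 3)), 10), "smaller")
  expect_length(none, 0L)
})

test_that("center crop takes the centered window and keeps metadata", {
  img <- array(0, c(1024, 1024, 3))
  img[384, 384, 1] <- 1 # top-left corner of the (1024-258)/2 = 383 offset
  cropped <- center_crop(img, 258)
  expect_equal(dim(cropped), c(258, 258, 3))
  expect_equal(cropped[1, 1, 1], 1)

  tl <- list(pixels = img, grade = 2L, label = "not_suitable")
  ct <- center_crop(tl, 258)
  expect_identical(ct$grade, 2L)
  expect_equal(dim(ct$pixels), c(258, 258, 3))

  expect_identical(center_crop(img, 1024), img)
  expect_error(center_crop(img, 0), "between")
  expect_error(center_crop(img, 2000), "between")
})

test_that("synthetic tiles hit the target fraction (pixel-count oracle)", {
  spec <- synthetic_slide_spec(258, 0.50, n_confounders = 0, seed = 7)
  tl <- synthesize_tile(spec)
  expect_identical(tl$grade, 2L)
  # independent oracle: droplets are the only near-white pixels
  white <- tl$pixels[, , 1] > 0.92 & tl$pixels[, , 2] > 0.92 &
    tl$pixels[, , 3] > 0.92
  frac <- mean(white)
  expect_gte(frac, 0.47)
  expect_lte(frac, 0.53)
  expect_equal(tl$fat_fraction, frac, tolerance = 1e-9)

  # zero target, no confounders: no white pixels at all
  empty <- synthesize_tile(synthetic_slide_spec(64, 0, n_confounders = 0,
                                                seed = 2))
  expect_identical(empty$grade, 0L)
  expect_equal(sum(empty$pixels > 0.92), 0)

  # determinism: identical spec -> identical pixels
  again <- synthesize_tile(spec)
  expect_identical(tl$pixels, again$pixels)
})

test_that("confounders add white area that is excluded from the fraction", {
  spec <- synthetic_slide_spec(128, 0.10, n_confounders = 3, seed = 13)
  tl <- synthesize_tile(spec)
  white <- mean(tl$pixels[, , 1] > 0.92 & tl$pixels[, , 2] > 0.92 &
                  tl$pixels[, , 3] > 0.92)
  expect_gt(white, tl$fat_fraction) # vessels/artifacts on top
  expect_identical(tl$grade, grade_from_fat_fraction(tl$fat_fraction))
})

test_that("generator calibration: mean absolute error below 0.015", {
  set.seed(55)
  errs <- replicate(50, {
    target <- runif(1, 0, 0.9)
    tl <- synthesize_tile(synthetic_slide_spec(
      64, target, n_confounders = 0, seed = sample.int(1e6, 1)))
    abs(tl$fat_fraction - target)
  })
  expect_true(all(errs <= 0.03))
  expect_lt(mean(errs), 0.015)
})

test_that("balanced dataset has exact grade and class counts", {
  m1 <- build_balanced_dataset(1, render = FALSE)
  expect_identical(nrow(m1), 4L)
  expect_identical(sort(m1$grade), 0:3)

  m <- build_balanced_dataset(25, render = FALSE, seed = 4)
  expect_identical(nrow(m), 100L)
  expect_true(all(table(m$grade) == 25L))
  expect_identical(sum(m$label == "not_suitable"), 50L)
  expect_identical(sum(m$label == "suitable"), 50L)
  expect_true(all(m$grade == grade_from_fat_fraction(m$fat_fraction)))
  # targets stay 0.01 clear of shared staging boundaries
  expect_true(all(abs(m$fat_fraction - 0.05) >= 0.0099))
  expect_true(all(abs(m$fat_fraction - 0.33) >= 0.0099))
  expect_true(all(abs(m$fat_fraction - 0.66) >= 0.0099))
})

test_that("rendered datasets round-trip through PNG + manifest", {
  dir <- file.path(tempdir(), "synthds")
  on.exit(unlink(dir, recursive = TRUE))
  m <- build_balanced_dataset(2, side_px = 24, seed = 9, dir = dir)
  expect_identical(nrow(m), 8L)
  expect_true(all(file.exists(m$path)))

  m2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(m2$fat_fraction, m$fat_fraction, tolerance = 1e-12)
  expect_identical(m2$grade, m$grade)
  expect_identical(m2$label, m$label)
  expect_identical(m2$patient_id, m$patient_id)

  ds <- load_dataset(m2)
  expect_identical(dim(ds$images), c(8L, 24L, 24L, 3L))
  # 8-bit PNG round trip: regenerating from the stored recipe matches the
  # stored image within one quantization step
  tl <- synthesize_tile(synthetic_slide_spec(
    24, m$target_fat_fraction[1], n_confounders = m$n_confounders[1],
    seed = m$seed[1]))
  expect_lt(max(abs(ds$images[1, , , ] - tl$pixels)), 1 / 255 + 1e-9)

  bad <- m2
  bad$path[2] <- bad$path[1]
  expect_error(steatoq:::validate_manifest(bad), "duplicate")
})

test_that("in-memory synth_dataset is balanced and deterministic", {
  ds <- synth_dataset(5, side_px = 16, seed = 77)
  expect_identical(length(ds$labels), 20L)
  expect_identical(sum(ds$labels == 2L), 10L)
  ds2 <- synth_dataset(5, side_px = 16, seed = 77)
  expect_identical(ds$images, ds2$images)
  expect_true(all(ds$meta$grade == grade_from_fat_fraction(ds$meta$fat_fraction)))
})
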