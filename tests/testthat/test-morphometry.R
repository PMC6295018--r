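# Morphometry: filtering, thresholding, labeling, perimeter, exclusion.

test_that("median filter matches the naive sliding-window oracle", {
  set.seed(42)
  for (i in 1:3) {
    img <- matrix(runif(32 * 32, 0, 255), 32, 32)
    expect_identical(median_filter(img, 3), naive_median_filter(img, 3))
  }
})

test_that("median filter basics: identity, constants, salt noise", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(median_filter(img, 0), img)
  cst <- matrix(7, 20, 20)
  expect_equal(median_filter(cst, 4), cst)
  salt <- matrix(0, 21, 21); salt[11, 11] <- 255
  expect_equal(median_filter(salt, 2), matrix(0, 21, 21))
})

test_that("binarize separates bimodal images and logs its threshold", {
  img <- matrix(40, 30, 30); img[10:20, 10:20] <- 200
  mask <- binarize(img)
  expect_equal(mask, img == 200, ignore_attr = TRUE)
  expect_true(attr(mask, "threshold") > 40 && attr(mask, "threshold") < 200)
  # polarity flag flips the mask
  inv <- binarize(255 - img, polarity = "dark")
  expect_identical(c(inv), c(mask))
  expect_error(binarize(matrix(5, 10, 10)), "constant")
})

test_that("binarize recovers generator masks with high IoU", {
  specs <- c(lapply(1:3, function(i) shape_spec("disk", 12)),
             lapply(1:2, function(i) shape_spec("ellipse", 10,
                                                aspect_ratio = 3)))
  fld <- generate_field(specs, c(200, 200), noise_sd = 3, seed = 9)
  mask <- binarize(median_filter(fld$image, 2))
  truth <- fld$labels > 0
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.95)
})

test_that("label_objects counts, filters debris, and caps circularity", {
  m <- matrix(FALSE, 60, 90)
  m[5:14, 5:14] <- TRUE      # area 100
  m[30:49, 10:29] <- TRUE    # area 400
  m[50:52, 60:62] <- TRUE    # area 9 (debris)
  tab <- label_objects(m, morph_config(min_area_px = 50))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$circularity <= 1))
  expect_equal(nrow(label_objects(matrix(FALSE, 10, 10), morph_config())), 0)
})

test_that("digitized disk circularity is near 1", {
  expect_gte(measure_circ(raster_disk(50)), 0.95)
  expect_lte(measure_circ(raster_disk(50)), 1.0)
})

test_that("holes are filled before measurement", {
  ring <- raster_disk(30, sz = 80) & !raster_disk(12, sz = 80)
  tab <- label_objects(ring, morph_config(min_area_px = 10))
  expect_equal(nrow(tab), 1)
  # outer outline only: circularity near a full disk's, area includes hole
  expect_gte(tab$circularity, 0.95)
  expect_equal(tab$area_px, sum(raster_disk(30, sz = 80)))
})

test_that("exclusion splits cells conservatively by border contact", {
  m <- matrix(FALSE, 50, 50)
  m[1:10, 20:30] <- TRUE    # touches row 1
  m[20:30, 20:30] <- TRUE   # interior
  m[40:50, 5:15] <- TRUE    # touches last row
  tab <- label_objects(m, morph_config(min_area_px = 10))
  sp <- exclude_border(tab)
  expect_equal(nrow(sp$kept), 1)
  expect_equal(nrow(sp$audited), 2)
  expect_equal(nrow(sp$kept) + nrow(sp$audited), nrow(tab))
  # one pixel away from the edge is kept
  m2 <- matrix(FALSE, 40, 40); m2[2:12, 2:12] <- TRUE
  sp2 <- exclude_border(label_objects(m2, morph_config(min_area_px = 10)))
  expect_equal(nrow(sp2$kept), 1)
})

test_that("measured circularity decreases with ellipse aspect ratio", {
  area <- pi * 35^2
  circ <- vapply(c(1, 2, 4, 8), function(ar) {
    a <- sqrt(area * ar / pi); b <- a / ar
    measure_circ(raster_ellipse(a, b, sz = 2 * ceiling(a) + 20, theta = 0.4))
  }, numeric(1))
  expect_true(all(diff(circ) < 0))
})

test_that("measured circularity is scale invariant within 2%", {
  for (shape in list(c(25, 25), c(36, 12))) {
    c1 <- measure_circ(raster_ellipse(shape[1], shape[2]))
    c2 <- measure_circ(raster_ellipse(2 * shape[1], 2 * shape[2]))
    expect_lt(abs(c2 - c1) / c1, 0.02)
  }
})

test_that("analyze_field measures noiseless fields against analytic truth", {
  specs <- lapply(1:4, function(i) shape_spec("disk", 20))
  fld <- generate_field(specs, c(220, 220), noise_sd = 0, seed = 3)
  tab <- analyze_field(fld$image, morph_config(median_radius_px = 2,
                                               min_area_px = 50))
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$circularity >= 0.95))

  # aspect-4 ellipses, large enough that filter erosion is negligible
  sp <- shape_spec("ellipse", 30, aspect_ratio = 4)
  fld2 <- generate_field(list(sp, sp), c(300, 300), noise_sd = 3, seed = 5)
  tab2 <- analyze_field(fld2$image, morph_config())
  expect_equal(mean(tab2$circularity), sp$target_circularity,
               tolerance = 0.05)
})

test_that("analyze_field on an empty field returns an empty table", {
  img <- matrix(30, 80, 80); img[40, 40] <- 200   # speck below min_area
  tab <- analyze_field(img, morph_config(median_radius_px = 0))
  expect_equal(nrow(tab), 0)
})

test_that("metadata propagates into the per-cell table", {
  fld <- generate_field(list(shape_spec("disk", 15)), c(100, 100),
                        noise_sd = 0, seed = 2)
  tab <- analyze_field(fld$image, morph_config(median_radius_px = 2),
                       metadata = list(gene = "RhoE", sirna = "#1",
                                       experiment = 2L, field = 3L))
  expect_equal(tab$gene, "RhoE")
  expect_equal(tab$experiment, 2L)
})
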