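test_that("binary segmentation handles empty, single and multi-object images", {
  blank <- calibrated_image(matrix(0, 20, 20), 1)
  expect_warning(lab <- segment_binary(blank, threshold = 128), "empty")
  expect_equal(max(lab), 0)

  sq <- matrix(0, 20, 20)
  sq[8:12, 8:12] <- 255
  img <- calibrated_image(sq, 1)
  lab <- segment_binary(img, threshold = 128, min_pixels = 4)
  obj <- extract_objects(lab, img)
  expect_equal(nrow(obj), 1L)
  expect_equal(obj$pixel_count, 25L)

  two <- matrix(0, 10, 11)
  two[3:5, 2:4] <- 255   # separated by a fully black column
  two[3:5, 6:8] <- 255
  img2 <- calibrated_image(two, 1)
  expect_equal(max(segment_binary(img2, 128, min_pixels = 1,
                                  connectivity = 4)), 2)
  expect_equal(max(segment_binary(img2, 128, min_pixels = 1,
                                  connectivity = 8)), 2)
})

test_that("connectivity matches a flood-fill oracle on random masks", {
  set.seed(71)
  for (rep in 1:8) {
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    for (conn in c(4, 8)) {
      got <- label_components(mask, connectivity = conn, min_pixels = 1)
      want <- oracle_label(mask, connectivity = conn)
      expect_equal(max(got), max(want))
      # same partition: label pairs must be in bijection
      if (max(want) > 0) {
        tab <- table(got[mask], want[mask])
        expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
      }
    }
  }
  # diagonal touch distinguishes the two connectivities
  m <- matrix(0, 5, 5); m[2, 2] <- 1; m[3, 3] <- 1
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
})

test_that("min_pixels removes specks and otsu splits a bimodal image", {
  m <- matrix(0, 30, 30)
  m[5:14, 5:14] <- 200   # 100 px object
  m[25, 25] <- 200       # 1 px speck
  img <- calibrated_image(m, 1)
  expect_equal(max(segment_binary(img, min_pixels = 5)), 1)
  expect_equal(max(segment_binary(img, min_pixels = 1)), 2)
  thr <- otsu_threshold(m)
  expect_true(thr > 0 && thr < 200)
})

test_that("centroids use pixel centers in the lower-left-origin frame", {
  m <- matrix(0, 10, 12)
  m[1, 1] <- 255   # top-left pixel
  img <- calibrated_image(m, 1)
  obj <- extract_objects(segment_binary(img, 128, min_pixels = 1), img)
  expect_equal(obj$x_um, 0.5)
  expect_equal(obj$y_um, 9.5)

  # symmetric object centered at its geometric center; calibrated units
  m2 <- matrix(0, 20, 20)
  m2[9:12, 5:8] <- 200
  img2 <- calibrated_image(m2, 0.5)
  obj2 <- extract_objects(segment_binary(img2, 128), img2)
  expect_equal(obj2$x_um, mean(c(5, 8) - 0.5) * 0.5)     # columns 5..8
  expect_equal(obj2$y_um, (20 - mean(c(9, 12) - 0.5)) * 0.5)
  expect_equal(obj2$mean_luminosity, 200)
  expect_equal(obj2$area_um2, obj2$pixel_count * 0.5^2)
})

test_that("color segmentation isolates the dominant channel", {
  px <- array(0, dim = c(30, 30, 3))
  px[10:15, 10:15, 1] <- 255   # red square
  img <- calibrated_image(px, 0.5)
  expect_equal(max(segment_color(img, "red")), 1)
  expect_warning(labg <- segment_color(img, "green"), "empty")
  expect_equal(max(labg), 0)
  gray <- calibrated_image(matrix(0, 5, 5), 1)
  expect_error(segment_color(gray, "red"), "requires RGB")
  # dominance margin: dim green over red background is not green
  px2 <- array(0, dim = c(10, 10, 3))
  px2[ , , 1] <- 100; px2[3:6, 3:6, 2] <- 120
  img2 <- calibrated_image(px2, 1)
  expect_warning(expect_equal(max(segment_color(img2, "green", margin = 30)), 0))
  expect_equal(max(segment_color(img2, "green", margin = 10)), 1)
})

test_that("object tables are invariant to label permutation", {
  set.seed(5)
  mask <- matrix(runif(40 * 40) < 0.2, 40, 40)
  lab <- label_components(mask, 8, min_pixels = 1)
  img <- calibrated_image(mask * 255, 1)
  obj <- extract_objects(lab, img)
  perm <- sample(max(lab))
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  lab2[lab > 0] <- perm[lab[lab > 0]]
  obj2 <- extract_objects(lab2, img)
  o1 <- obj[order(obj$x_um, obj$y_um), c("x_um", "y_um", "pixel_count")]
  o2 <- obj2[order(obj2$x_um, obj2$y_um), c("x_um", "y_um", "pixel_count")]
  expect_equal(as.data.frame(o1), as.data.frame(o2),
               ignore_attr = TRUE)
})

test_that("rendered scenes are recovered with sub-pixel centroid accuracy", {
  p <- gen_hardcore(35, r_min = 5, window = c(60, 60), seed = 9, inset = 3)
  r <- render_cells(p, radius = 1.5, calibration = 0.2, window = c(60, 60))
  obj <- extract_objects(segment_binary(r$image, 128), r$image)
  expect_equal(nrow(obj), 35L)
  near <- oracle_nearest_source(obj$x_um, obj$y_um, p$x, p$y)
  expect_lt(max(near[, 2]), 0.2)   # within one pixel
  nb <- neighbor_table(p)
  expect_lt(mean(near[, 2]), 0.05 * mean(nb$nnd1))
})

test_that("object CSV round trip preserves every field exactly", {
  tab <- tibble::tibble(
    id = 1:3,
    x_um = c(0.123456789012345, 10, exp(1)),
    y_um = c(pi, 2.5, 1 / 3),
    area_um2 = c(1.21, 2.42, 3.63),
    pixel_count = c(11L, 22L, 33L),
    channel = c("fg", "fg", "fg"),
    mean_luminosity = c(200.5, 128, 17.777)
  )
  attr(tab, "window") <- c(50, 40)
  f <- tempfile(fileext = ".csv")
  write_object_csv(tab, f)
  back <- read_object_csv(f)
  expect_identical(back$x_um, tab$x_um)
  expect_identical(back$y_um, tab$y_um)
  expect_identical(back$mean_luminosity, tab$mean_luminosity)
  expect_equal(attr(back, "window"), c(50, 40))
  f2 <- tempfile(fileext = ".csv")
  write_object_csv(back, f2)
  expect_identical(read_object_csv(f2), back)

  # empty table: header only
  f3 <- tempfile(fileext = ".csv")
  write_object_csv(tab[0, ], f3)
  expect_equal(nrow(read_object_csv(f3)), 0L)

  # malformed inputs
  f4 <- tempfile(fileext = ".csv")
  writeLines("id,x_um\n1,2", f4)
  expect_error(read_object_csv(f4), "y_um")
  f5 <- tempfile(fileext = ".csv")
  writeLines(c("id,x_um,y_um", "1,2,3", "2,oops,4"), f5)
  expect_error(read_object_csv(f5), "row 2")
})

test_that("images survive a TIFF/PNG write-read cycle", {
  m <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  img <- calibrated_image(m, 0.5, "roundtrip")
  for (ext in c(".tif", ".png")) {
    f <- tempfile(fileext = ext)
    write_image(img, f)
    back <- read_image(f, 0.5)
    expect_lt(max(abs(back$pixels - m)), 0.51)  # 16/8-bit quantization
  }
})
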