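test_that("Otsu threshold separates a bimodal image and matches exhaustive search", {
  two <- matrix(c(rep(40, 300), rep(220, 700)), 20, 50)
  t <- otsu_threshold(two)
  expect_gte(t, 40); expect_lt(t, 220)
  mask <- binarize(two)
  expect_true(all(mask == (two == 40)))
  ## oracle: exhaustive 256-candidate search on random histograms
  set.seed(10)
  for (i in 1:8) {
    img <- matrix(sample(0:255, 600, replace = TRUE,
                         prob = runif(256)^2), 20, 30)
    expect_identical(otsu_threshold(img), otsu_bruteforce(img))
  }
  expect_error(otsu_threshold(matrix(7, 5, 5)), "constant")
})

test_that("threshold background removal whitens background, keeps foreground", {
  sp <- disk_scene(seed = 13)
  sc <- render_scene(sp)
  fg <- holoweigh:::.organism_mask(sp)
  clean <- remove_background(sc$image)
  ## every ground-truth organism pixel retained (not painted white)
  expect_true(all(clean[fg] < 255))
  expect_true(all(clean[fg] == sc$image[fg]))
  ## background away from marker and organism is >= 99% white
  mc <- sc$truth$marker_corners
  mk <- matrix(FALSE, nrow(clean), ncol(clean))
  mk[floor(min(mc[, 2]) - 3):ceiling(max(mc[, 2]) + 3),
     floor(min(mc[, 1]) - 3):ceiling(max(mc[, 1]) + 3)] <- TRUE
  bg <- !fg & !mk
  expect_gte(mean(clean[bg] == 255), 0.99)
  ## degenerate inputs
  white <- matrix(255, 10, 10)
  expect_identical(remove_background(white), white)
  expect_warning(out <- remove_background(matrix(12, 10, 10)), "retained")
  expect_identical(out, matrix(12, 10, 10))
  expect_error(remove_background(sc$image, backend = "matting"), "threshold")
})

test_that("marker masking removes all marker pixels from the foreground", {
  sc <- render_scene(disk_scene(seed = 17))
  obs <- detect_marker(sc$image)
  mask <- binarize(sc$image)
  mc <- sc$truth$marker_corners
  in_quad <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    sum(point_in_polygon(idx[, 2], idx[, 1], mc))
  }
  expect_gt(in_quad(mask), 0)
  masked <- mask_marker_region(mask, obs, margin_px = 3)
  expect_identical(in_quad(masked), 0L)
  ## empty in, empty out
  empty <- matrix(FALSE, nrow(mask), ncol(mask))
  expect_identical(mask_marker_region(empty, obs, 3), empty)
  ## zero margin leaves at most a perimeter-proportional residue
  leftover <- in_quad(mask_marker_region(binarize(sc$image), obs, 0))
  expect_lte(leftover, 4 * 201)
})

test_that("object measurement filters by physical area and sorts by size", {
  cal <- compute_scale(structure(list(marker_id = 1L,
    corners = rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))),
    class = "marker_observation"), 10)  # 10 px/cm
  expect_identical(measure_objects(matrix(FALSE, 50, 50), cal), list())
  ## two square blobs: 2x2 cm (4 cm2) and 3x3 cm (9 cm2)
  m <- matrix(FALSE, 120, 120)
  m[10:29, 10:29] <- TRUE    # 20x20 px = 4 cm2
  m[60:89, 60:89] <- TRUE    # 30x30 px = 9 cm2
  objs <- measure_objects(m, cal, min_area_cm2 = 5)
  expect_length(objs, 1L)
  expect_equal(objs[[1]]$area_cm2, 9, tolerance = 0.01)
  both <- measure_objects(m, cal, min_area_cm2 = 0)
  expect_length(both, 2L)
  expect_gt(both[[1]]$area_cm2, both[[2]]$area_cm2)
  ## the >= boundary is inclusive: filtering at exactly an object's area keeps it
  a_small <- both[[2]]$area_cm2
  expect_length(measure_objects(m, cal, min_area_cm2 = a_small), 2L)
  expect_length(measure_objects(m, cal, min_area_cm2 = a_small + 1e-9), 1L)
  ## raising the filter never increases the count
  ns <- vapply(c(0, 2, 4, 5, 9, 10), function(a)
    length(measure_objects(m, cal, min_area_cm2 = a)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("disk measurement recovers the analytic area and box dimensions", {
  m <- measure_scene(disk_scene(seed = 19))
  expect_length(m$objects, 1L)
  ob <- m$objects[[1]]
  expect_lt(abs(ob$area_cm2 - 78.54) / 78.54, 0.02)
  expect_lt(abs(ob$width_cm - 10) / 10, 0.02)
  expect_lt(abs(ob$height_cm - 10) / 10, 0.02)
  expect_lte(ob$area_cm2, ob$width_cm * ob$height_cm)
  expect_equal(ob$area_cm2, pixels_to_cm2(ob$pixel_area, m$cal))
})

test_that("shoelace contour area agrees with raster pixel counting", {
  cal <- compute_scale(structure(list(marker_id = 1L,
    corners = rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))),
    class = "marker_observation"), 10)
  set.seed(23)
  for (i in 1:6) {
    m <- matrix(FALSE, 80, 80)
    r <- runif(1, 8, 25); cx <- runif(1, 35, 45); cy <- runif(1, 35, 45)
    xs <- matrix(1:80, 80, 80, byrow = TRUE); ys <- matrix(1:80, 80, 80)
    m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- TRUE
    ob <- measure_objects(m, cal, min_area_cm2 = 0)[[1]]
    perim <- holoweigh:::polygon_perimeter(ob$contour)
    expect_lt(abs(ob$pixel_area - ob$pixel_count), perim)
  }
})

test_that("annotation is cosmetic and localized", {
  m <- measure_scene(disk_scene(seed = 29))
  ann <- annotate(m$scene$image, m$objects, m$cal)
  expect_equal(dim(ann), c(nrow(m$scene$image), ncol(m$scene$image), 3))
  ## pixels far from the object's bbox are untouched
  bb <- m$objects[[1]]$bbox
  far_cols <- 1:max(1, floor(bb["xmin"]) - 120)
  expect_identical(ann[, far_cols, 1], m$scene$image[, far_cols])
  ## re-measuring the original image is unaffected by annotation
  m2 <- measure_scene(disk_scene(seed = 29))
  expect_identical(m2$objects[[1]]$pixel_area, m$objects[[1]]$pixel_area)
  ## zero objects: unchanged gray stack plus a notice
  expect_message(ann0 <- annotate(m$scene$image, list(), m$cal), "unchanged")
  expect_identical(ann0[, , 2], m$scene$image)
})
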