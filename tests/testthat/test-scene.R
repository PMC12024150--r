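test_that("rendered ground truth matches analytic geometry", {
  sc <- render_scene(disk_scene())
  expect_equal(sc$truth$analytic_area_cm2, pi * 25, tolerance = 1e-12)
  ## pixel count at 20 px/cm: within 2% of 31416 px
  expect_lt(abs(sc$truth$true_object_pixel_area - pi * 100^2) / (pi * 100^2), 0.02)
  expect_equal(sc$truth$true_pixels_per_cm, 20)
  expect_equal(dim(sc$truth$marker_corners), c(4L, 2L))
})

test_that("degenerate and overlapping layouts are rejected", {
  expect_error(scene_spec(organism = list(shape = "disk", radius_cm = 0)),
               "non-positive area")
  expect_error(scene_spec(organism = list(shape = "ellipse", semi_a_cm = 3,
                                          semi_b_cm = -1)),
               "non-positive area")
  ## organism centred on the marker: layout error
  sp <- disk_scene()
  sp$organism$center <- sp$marker$center
  expect_error(render_scene(sp), "overlap")
  ## marker pushed outside the canvas
  sp2 <- disk_scene()
  sp2$marker$center <- c(10, 10)
  expect_error(render_scene(sp2), "marker does not fit")
})

test_that("rendering is deterministic in the seed", {
  a <- render_scene(disk_scene(seed = 11))
  b <- render_scene(disk_scene(seed = 11))
  expect_identical(a$image, b$image)
  c <- render_scene(disk_scene(seed = 12))
  expect_false(identical(a$image, c$image))
  ## rendering must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(render_scene(disk_scene())); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("pixel-area ground truth satisfies the perimeter-bound rasterization error", {
  for (seed in 1:6) {
    set.seed(seed)
    ppcm <- runif(1, 15, 40)
    org <- if (seed %% 2) list(shape = "disk", radius_cm = runif(1, 3, 6)) else
      list(shape = "ellipse", semi_a_cm = runif(1, 4, 7),
           semi_b_cm = runif(1, 2, 4), angle_deg = runif(1, 0, 180))
    sp <- scene_spec(pixels_per_cm = ppcm, organism = org, seed = seed)
    sc <- render_scene(sp)
    perim_cm <- if (org$shape == "disk") 2 * pi * org$radius_cm else
      pi * (3 * (org$semi_a_cm + org$semi_b_cm) -
              sqrt((3 * org$semi_a_cm + org$semi_b_cm) *
                     (org$semi_a_cm + 3 * org$semi_b_cm)))
    err <- abs(sc$truth$true_object_pixel_area / ppcm^2 - sc$truth$analytic_area_cm2)
    expect_lt(err, 1.0 * perim_cm / ppcm)
  }
})

test_that("supershape blobs carry their own shoelace ground truth", {
  sp <- scene_spec(pixels_per_cm = 20,
                   organism = list(shape = "supershape", size_cm = 4), seed = 3)
  expect_equal(sp$organism$analytic_area_cm2,
               abs(shoelace_area(sp$organism$polygon_cm)))
  sc <- render_scene(sp)
  expect_lt(abs(sc$truth$true_object_pixel_area / 400 -
                  sc$truth$analytic_area_cm2) / sc$truth$analytic_area_cm2, 0.02)
})

test_that("rotation augmentation quadruples the set in deterministic order", {
  imgs <- lapply(1:15, function(i) matrix(i + 0:5, 2, 3))
  aug <- augment_rotations(imgs)
  expect_length(aug, 60L)
  ## order: input order, then orientation order; 0-degree copy bit-identical
  expect_identical(aug[[1]], imgs[[1]])
  expect_identical(aug[[5]], imgs[[2]])
  expect_identical(aug[[2]], rotate_image(imgs[[1]], 1))
  expect_identical(aug[[4]], rotate_image(imgs[[1]], 3))
  expect_error(augment_rotations(list()), "non-empty")
})

test_that("right-angle rotation preserves foreground pixel area and the set is closed", {
  sc <- render_scene(disk_scene(seed = 5))
  aug <- augment_rotations(list(sc$image))
  expect_length(aug, 4L)
  areas <- vapply(aug, function(im) sum(binarize(im)), numeric(1))
  expect_true(all(areas == areas[1]))
  ## closure: augmenting the augmented set yields the same distinct areas
  aug2 <- augment_rotations(aug)
  areas2 <- vapply(aug2, function(im) sum(binarize(im)), numeric(1))
  expect_setequal(unique(areas2), unique(areas))
})

test_that("scenes survive a PNG round-trip bit-exactly", {
  sc <- render_scene(disk_scene(seed = 21))
  path <- tempfile(fileext = ".png")
  write_scene(sc, path)
  back <- read_image(path)
  expect_identical(unname(back), unname(sc$image))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$true_object_pixel_area, sc$truth$true_object_pixel_area)
  unlink(c(path, paste0(path, ".json")))
})
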