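## generate noise-free pairs from a packaged model over a given area range
pairs_from <- function(model, lo, hi, n = 60L) {
  x <- seq(lo, hi, length.out = n)
  aw_pairs(x, predict_weight(model, x, quiet = TRUE))
}

test_that("fitting noise-free data from the printed equations recovers the printed coefficients", {
  black <- load_packaged_models("black")
  pink <- load_packaged_models("pink_warty")
  sand <- load_packaged_models("sandfish")
  m <- fit_weight_model(pairs_from(black$polynomial2, 20, 140), "polynomial2")
  expect_equal(round(unlist(m$coefficients), 4),
               c(a = -0.0075, b = 2.5255, c = -24.8202))
  m <- fit_weight_model(pairs_from(black$power, 20, 140), "power")
  expect_equal(round(m$coefficients$b, 4), 0.9522)
  m <- fit_weight_model(pairs_from(pink$polynomial2, 10, 60), "polynomial2")
  expect_equal(round(m$coefficients$a, 4), -0.0209)
  m <- fit_weight_model(pairs_from(sand$linear, 20, 160), "linear")
  expect_equal(round(unlist(m$coefficients), 4), c(a = 2.2761, b = -10.3947))
})

test_that("every family round-trips its own noise-free data", {
  x <- seq(15, 120, length.out = 60)
  truth <- list(
    linear        = list(a = 1.5, b = -0.3),
    polynomial2   = list(a = -0.02, b = 2.3, c = -8),
    power         = list(a = 1.83, b = 0.95),
    logarithmic   = list(a = -37.3, b = 21.7),
    exponential10 = list(a = 6.287, b = 0.0156))
  for (fam in names(truth)) {
    m0 <- holoweigh:::.new_weight_model(fam, truth[[fam]], NA, 60L, "")
    pairs <- aw_pairs(x, predict_weight(m0, x, quiet = TRUE))
    m <- fit_weight_model(pairs, fam)
    rel <- abs(unlist(m$coefficients) / unlist(truth[[fam]]) - 1)
    expect_lt(max(rel), 1e-6)
    expect_gte(m$r_squared, 1 - 1e-9)
  }
})

test_that("exact linear data gives a = 2, b = 1, R2 = 1", {
  m <- fit_weight_model(aw_pairs(1:10, 2 * (1:10) + 1), "linear")
  expect_equal(m$coefficients$a, 2)
  expect_equal(m$coefficients$b, 1)
  expect_equal(m$r_squared, 1)
})

test_that("fit preconditions are enforced with informative errors", {
  expect_error(fit_weight_model(aw_pairs(c(1, 2), c(1, 2)), "polynomial2"),
               "insufficient")
  expect_error(fit_weight_model(aw_pairs(c(-1, 2, 3), c(1, 2, 3)), "power"),
               "rows 1")
  expect_error(fit_weight_model(aw_pairs(c(1, 2, 3), c(0, 2, 3)), "exponential10"),
               "non-positive weight")
})

test_that("R2 is computed on the original scale about the mean", {
  ## hand-sized case: (10,20),(20,45),(30,55) against y = 2x + 1:
  ## SS_res = 53, SS_tot = 650 -> R2 = 1 - 53/650
  pairs <- aw_pairs(c(10, 20, 30), c(20, 45, 55))
  m <- holoweigh:::.new_weight_model("linear", list(a = 2, b = 1), NA, 3L, "")
  expect_equal(r_squared(m, pairs), 1 - 53 / 650, tolerance = 1e-12)
  ## predicting the mean gives exactly 0
  m0 <- holoweigh:::.new_weight_model("linear", list(a = 0, b = 40), NA, 3L, "")
  expect_equal(r_squared(m0, pairs), 0)
  expect_error(r_squared(m, aw_pairs(c(1, 2), c(5, 5))), "constant")
})

test_that("residuals of OLS families sum to zero", {
  set.seed(5)
  x <- runif(60, 10, 120)
  y <- 2 * x + 5 + rnorm(60, 0, 10)
  for (fam in c("linear", "polynomial2", "logarithmic")) {
    m <- fit_weight_model(aw_pairs(x, y), fam)
    expect_lt(abs(sum(y - predict_weight(m, x, quiet = TRUE))), 1e-8 * sum(abs(y)))
  }
})

test_that("model selection ranks by R2 with the nested-tie rule", {
  x <- seq(10, 100, length.out = 60)
  ## genuine curvature: the quadratic wins uniquely
  sel <- select_best_model(aw_pairs(x, -0.02 * x^2 + 2.3 * x - 8))
  expect_equal(sel$best$family, "polynomial2")
  expect_identical(sel$ties, "polynomial2")
  ## exactly linear: linear and polynomial2 tie, fewest coefficients wins
  sel <- select_best_model(aw_pairs(x, 2 * x + 1))
  expect_equal(sel$best$family, "linear")
  expect_true(all(c("linear", "polynomial2") %in% sel$ties))
  ## adding the quadratic term never lowers R2 vs linear (nested OLS)
  set.seed(7)
  for (i in 1:5) {
    y <- 1.5 * x + rnorm(60, 0, 15)
    fl <- fit_weight_model(aw_pairs(x, y), "linear")
    fq <- fit_weight_model(aw_pairs(x, y), "polynomial2")
    expect_gte(fq$r_squared + 1e-12, fl$r_squared)
    expect_lte(fq$r_squared, 1)
  }
  ## with too few points, 3-coefficient families are excluded, rest ranked
  sel3 <- select_best_model(aw_pairs(c(5, 10, 15), c(11, 21, 31)))
  expect_true("polynomial2" %in% names(sel3$failed))
  expect_false("polynomial2" %in% names(sel3$candidates))
  expect_equal(sel3$best$family, "linear")
})

test_that("prediction evaluates the family formulas at full precision", {
  sand <- load_packaged_models("sandfish")
  expect_equal(predict_weight(sand$linear, 100), 217.2153)
  lin <- holoweigh:::.new_weight_model("linear", list(a = 2, b = 1), NA, 2L, "")
  expect_equal(predict_weight(lin, 10), 21)
  const <- holoweigh:::.new_weight_model("exponential10", list(a = 7, b = 0), NA, 2L, "")
  expect_equal(predict_weight(const, c(1, 50, 500)), c(7, 7, 7))
  expect_error(predict_weight(lin, 0), "positive")
  neg <- holoweigh:::.new_weight_model("polynomial2",
                                       list(a = -1, b = 0, c = 0), NA, 3L, "")
  expect_message(v <- predict_weight(neg, 10), "negative")
  expect_equal(v, -100)
})

test_that("packaged models carry the printed coefficients and R2", {
  black <- load_packaged_models("black")
  expect_equal(unlist(black$polynomial2$coefficients),
               c(a = -0.0075, b = 2.5255, c = -24.8202))
  expect_equal(black$polynomial2$r_squared, 0.9699)
  expect_equal(unlist(load_packaged_models("pink_warty")$exponential10$coefficients),
               c(a = 6.2870, b = 0.0756))
  sand <- load_packaged_models("sandfish")
  expect_equal(unlist(sand$linear$coefficients), c(a = 2.2761, b = -10.3947))
  expect_equal(sand$linear$r_squared, 0.9882)
  expect_error(load_packaged_models("unknown"), "black.*pink_warty.*sandfish")
})

test_that("models survive a JSON round-trip at full precision", {
  m <- fit_weight_model(aw_pairs(seq(10, 100, 2), 1.83 * seq(10, 100, 2)^0.95),
                        "power", species_label = "black")
  path <- tempfile(fileext = ".json")
  write_weight_model(m, path)
  back <- read_weight_model(path)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-14)
  expect_equal(back$family, m$family)
  expect_equal(back$species_label, "black")
  unlink(path)
})
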