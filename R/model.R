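## Area-weight regression: five model families relating top-view area
## x (cm2) to body weight y (g), coefficient of determination on the
## original weight scale, and selection of the best family by R2.
##
## Families:
##   linear        y = a*x + b
##   polynomial2   y = a*x^2 + b*x + c
##   power         y = a*x^b
##   logarithmic   y = a + b*ln(x)
##   exponential10 y = a*10^(b*x)
## The exponential family is base-10, matching the printed equations.

WEIGHT_MODEL_FAMILIES <- c("linear", "polynomial2", "power", "logarithmic",
                           "exponential10")

.family_ncoef <- c(linear = 2L, polynomial2 = 3L, power = 2L,
                   logarithmic = 2L, exponential10 = 2L)

#' Assemble area-weight pairs
#'
#' @param area_cm2 top-view areas (cm2).
#' @param weight_g actual weights (g).
#' @return data frame with columns `area_cm2`, `weight_g`.
#' @export
aw_pairs <- function(area_cm2, weight_g) {
  stopifnot(length(area_cm2) == length(weight_g))
  data.frame(area_cm2 = as.numeric(area_cm2), weight_g = as.numeric(weight_g))
}

.as_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("area_cm2", "weight_g") %in% names(pairs)))
  pairs
}

.new_weight_model <- function(family, coefficients, r_squared, n, species_label) {
  structure(list(family = family, coefficients = coefficients,
                 r_squared = r_squared, n = as.integer(n),
                 species_label = species_label),
            class = "weight_model")
}

#' Fit one area-weight model family
#'
#' Linear, quadratic and logarithmic families are ordinary least squares
#' in closed form; power and base-10 exponential are nonlinear least
#' squares on the original weight scale (Levenberg-Marquardt), initialized
#' from the corresponding log-linear transform fit. Coefficients are kept
#' at full precision; rounding to 4 decimals happens only when printing.
#'
#' @param pairs data frame with `area_cm2` (x) and `weight_g` (y).
#' @param family one of `r paste(WEIGHT_MODEL_FAMILIES, collapse = ", ")`.
#' @param species_label free-text label stored with the model.
#' @return a `weight_model`.
#' @export
fit_weight_model <- function(pairs, family = WEIGHT_MODEL_FAMILIES,
                             species_label = "") {
  family <- match.arg(family)
  pairs <- .as_pairs(pairs)
  x <- pairs$area_cm2; y <- pairs$weight_g
  n <- length(x)
  if (n < .family_ncoef[[family]] + 1L)
    stop("insufficient points to fit the ", family, " family: need at least ",
         .family_ncoef[[family]] + 1L, ", got ", n)
  if (family %in% c("power", "logarithmic") && any(x <= 0))
    stop("non-positive area is incompatible with the ", family,
         " family (rows ", paste(which(x <= 0), collapse = ", "), ")")
  if (family %in% c("power", "exponential10") && any(y <= 0))
    stop("non-positive weight is incompatible with the ", family,
         " family (rows ", paste(which(y <= 0), collapse = ", "), ")")

  co <- switch(family,
    linear = {
      f <- lm(y ~ x)
      list(a = unname(coef(f)[2]), b = unname(coef(f)[1]))
    },
    polynomial2 = {
      f <- lm(y ~ x + I(x^2))
      list(a = unname(coef(f)[3]), b = unname(coef(f)[2]), c = unname(coef(f)[1]))
    },
    logarithmic = {
      f <- lm(y ~ log(x))
      list(a = unname(coef(f)[1]), b = unname(coef(f)[2]))
    },
    power = {
      init <- coef(lm(log(y) ~ log(x)))
      f <- minpack.lm::nlsLM(y ~ a * x^b,
                             start = list(a = exp(unname(init[1])),
                                          b = unname(init[2])),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      as.list(coef(f))
    },
    exponential10 = {
      init <- coef(lm(log10(y) ~ x))
      f <- minpack.lm::nlsLM(y ~ a * 10^(b * x),
                             start = list(a = 10^unname(init[1]),
                                          b = unname(init[2])),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      as.list(coef(f))
    })

  m <- .new_weight_model(family, co, NA_real_, n, species_label)
  m$r_squared <- r_squared(m, pairs)
  m
}

#' Coefficient of determination on the original weight scale
#'
#' `1 - SS_res / SS_tot` with `SS_tot` about the mean weight and residuals
#' taken on the untransformed weight scale for every family, so values are
#' comparable across families.
#'
#' @param model a `weight_model`.
#' @param pairs data frame with `area_cm2`, `weight_g`.
#' @return numeric R2 (at most 1; can be negative for a bad model).
#' @export
r_squared <- function(model, pairs) {
  pairs <- .as_pairs(pairs)
  y <- pairs$weight_g
  if (length(y) < 2L) stop("R2 needs at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R2 is undefined for constant weights")
  yhat <- predict_weight(model, pairs$area_cm2, quiet = TRUE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Predict weight from top-view area
#'
#' Evaluates the family formula at full coefficient precision. Negative
#' predictions (possible for polynomial families at extreme areas) are
#' returned as-is with a notice.
#'
#' @param model a `weight_model`.
#' @param area_cm2 positive areas (cm2); vectorized.
#' @param quiet suppress the negative-prediction notice.
#' @return predicted weights (g).
#' @export
predict_weight <- function(model, area_cm2, quiet = FALSE) {
  if (any(area_cm2 <= 0)) stop("area_cm2 must be positive")
  co <- model$coefficients
  y <- switch(model$family,
    linear        = co$a * area_cm2 + co$b,
    polynomial2   = co$a * area_cm2^2 + co$b * area_cm2 + co$c,
    power         = co$a * area_cm2^co$b,
    logarithmic   = co$a + co$b * log(area_cm2),
    exponential10 = co$a * 10^(co$b * area_cm2),
    stop("unknown model family: ", model$family))
  if (!quiet && any(y < 0))
    message("note: ", sum(y < 0), " negative weight prediction(s) returned as-is")
  y
}

#' Fit all families and select the best by R2
#'
#' Every family that satisfies its preconditions is fitted; failures are
#' recorded, not fatal. Candidates are ranked by R2; families whose R2
#' agrees with the top value after rounding to 4 decimals are reported as
#' ties, and the tie with the fewest coefficients (then the conventional
#' family order) is designated best - so exactly linear data selects the
#' linear family even though the quadratic fits equally well.
#'
#' @param pairs data frame with `area_cm2`, `weight_g`.
#' @param families families to try (default: all five).
#' @param species_label stored with each fitted model.
#' @return a `model_selection`: `candidates` (fitted `weight_model`s),
#'   `best`, `ties` (family names), `failed` (named character vector of
#'   error messages).
#' @export
select_best_model <- function(pairs, families = WEIGHT_MODEL_FAMILIES,
                              species_label = "") {
  pairs <- .as_pairs(pairs)
  fits <- list(); failed <- character(0)
  for (fam in families) {
    res <- tryCatch(fit_weight_model(pairs, fam, species_label),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "weight_model")) fits[[fam]] <- res
    else failed[[fam]] <- res
  }
  if (length(fits) == 0L)
    stop("no model family could be fitted: ",
         paste(names(failed), failed, sep = ": ", collapse = "; "))
  r2 <- vapply(fits, function(m) m$r_squared, numeric(1))
  r2r <- round(r2, 4)
  tie_fams <- names(fits)[r2r == max(r2r)]
  nc <- .family_ncoef[tie_fams]
  pick <- tie_fams[order(nc, match(tie_fams, WEIGHT_MODEL_FAMILIES))][1]
  structure(list(candidates = fits, best = fits[[pick]], ties = tie_fams,
                 failed = failed),
            class = "model_selection")
}

.format_equation <- function(model) {
  co <- lapply(model$coefficients, round, 4)
  switch(model$family,
    linear        = sprintf("y = %.4fx %+.4f", co$a, co$b),
    polynomial2   = sprintf("y = %.4fx^2 %+.4fx %+.4f", co$a, co$b, co$c),
    power         = sprintf("y = %.4fx^%.4f", co$a, co$b),
    logarithmic   = sprintf("y = %.4f %+.4f ln(x)", co$a, co$b),
    exponential10 = sprintf("y = %.4f * 10^(%.4fx)", co$a, co$b))
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("%s model%s: %s  (R2 = %.4f, n = %d)\n", x$family,
              if (nzchar(x$species_label)) paste0(" [", x$species_label, "]") else "",
              .format_equation(x), x$r_squared, x$n))
  invisible(x)
}

#' @export
print.model_selection <- function(x, ...) {
  cat("model selection by R2 (4-decimal ties reported):\n")
  for (m in x$candidates) {
    tag <- if (m$family == x$best$family) " <- best"
           else if (m$family %in% x$ties) " (tie)" else ""
    cat(sprintf("  %-13s R2 = %.4f  %s%s\n", m$family, m$r_squared,
                .format_equation(m), tag))
  }
  for (fam in names(x$failed)) cat(sprintf("  %-13s failed: %s\n", fam, x$failed[[fam]]))
  invisible(x)
}

#' Write a weight model to a JSON file
#'
#' @param model a `weight_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_model <- function(model, path) {
  jsonlite::write_json(
    list(family = model$family, coefficients = model$coefficients,
         r_squared = model$r_squared, n = model$n,
         species_label = model$species_label,
         tool = paste0("holoweigh ", as.character(packageVersion("holoweigh")))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a weight model from a JSON file
#'
#' @param path path written by [write_weight_model()].
#' @return a `weight_model`.
#' @export
read_weight_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  .new_weight_model(j$family, lapply(j$coefficients, as.numeric),
                    as.numeric(j$r_squared), j$n,
                    if (is.null(j$species_label)) "" else j$species_label)
}
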