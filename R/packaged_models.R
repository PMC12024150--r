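## Published area-weight equations for the three study species, shipped as
## ready-to-use models. Coefficients and R2 values are as printed for
## black sea cucumber (Holothuria leucospilota), pink warty sea cucumber
## (Cercodemas anceps) and sandfish (Holothuria scabra); the underlying
## 60-point datasets are not public, so these are fixtures, not refits.

.packaged_model_table <- list(
  black = list(
    linear        = list(co = list(a = 1.4993, b = -0.3209),              r2 = 0.9344),
    polynomial2   = list(co = list(a = -0.0075, b = 2.5255, c = -24.8202), r2 = 0.9699),
    power         = list(co = list(a = 1.8313, b = 0.9522),               r2 = 0.9370),
    logarithmic   = list(co = list(a = -195.3286, b = 72.1146),           r2 = 0.9129),
    exponential10 = list(co = list(a = 33.5828, b = 0.0135),              r2 = 0.7906)),
  pink_warty = list(
    linear        = list(co = list(a = 1.6247, b = -3.9756),              r2 = 0.9741),
    polynomial2   = list(co = list(a = -0.0209, b = 2.2369, c = -8.0638),  r2 = 0.9774),
    power         = list(co = list(a = 0.8102, b = 1.1886),               r2 = 0.9698),
    logarithmic   = list(co = list(a = -37.3202, b = 21.7212),            r2 = 0.9602),
    exponential10 = list(co = list(a = 6.2870, b = 0.0756),               r2 = 0.9232)),
  sandfish = list(
    linear        = list(co = list(a = 2.2761, b = -10.3947),             r2 = 0.9882),
    polynomial2   = list(co = list(a = 0.0002, b = 2.2602, c = -10.1545),  r2 = 0.9882),
    power         = list(co = list(a = 1.3355, b = 1.1086),               r2 = 0.9866),
    logarithmic   = list(co = list(a = -132.1002, b = 67.0347),           r2 = 0.8979),
    exponential10 = list(co = list(a = 38.1773, b = 0.0187),              r2 = 0.9064))
)

#' Packaged area-weight models for the three study species
#'
#' Returns the five published regression models (one per family) for the
#' requested species, each fitted on n = 60 augmented images in the
#' original study.
#'
#' @param species_label one of `"black"`, `"pink_warty"`, `"sandfish"`.
#' @return a named list of five `weight_model`s, in the conventional
#'   family order.
#' @export
load_packaged_models <- function(species_label) {
  if (!species_label %in% names(.packaged_model_table))
    stop("unknown species label '", species_label, "'; valid labels: ",
         paste(names(.packaged_model_table), collapse = ", "))
  tab <- .packaged_model_table[[species_label]]
  out <- lapply(names(tab), function(fam)
    .new_weight_model(fam, tab[[fam]]$co, tab[[fam]]$r2, 60L, species_label))
  setNames(out, names(tab))
}

#' Species labels with packaged models
#' @return character vector of valid labels.
#' @export
packaged_species <- function() names(.packaged_model_table)
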