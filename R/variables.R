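#' Catalogue of modeled chronic diseases
#'
#' The 14 chronic diseases modeled as time-varying indicator covariates
#' alongside the anchoring heart-disease (HD) diagnosis. HD itself is not a
#' covariate: every subject has it, so it is absorbed into the baseline
#' hazard. Abbreviations: AL allergies, BP back pain, CAN cancer, COPD
#' chronic obstructive pulmonary disease, DEM dementia, DEP depression,
#' DIA diabetes, HC high cholesterol, HT hypertension, JD joint disease,
#' OA osteoarthritis, OP osteoporosis, SCH schizophrenia, ST stroke.
#'
#' @return Character vector of 14 disease labels.
#' @export
portfolio_diseases <- function() {
  c("AL", "BP", "CAN", "COPD", "DEM", "DEP", "DIA", "HC",
    "HT", "JD", "OA", "OP", "SCH", "ST")
}

#' Educational attainment levels
#'
#' Six-level factor used as an intrinsic variable; "none" is the reference
#' level. Missingness is carried as ordinary levels ("missing",
#' "missing_before_1920") rather than dropped.
#'
#' @return Character vector of the 6 levels, reference first.
#' @export
education_levels <- function() {
  c("none", "short", "medium", "long", "missing", "missing_before_1920")
}

# Intrinsic variable labels eligible for interactions (linear components only).
intrinsic_vars <- function() c("sex_female", "education", "age", "cal")

# Polynomial labels: main effects only, never inside an interaction term.
poly_vars <- function() c("age2", "age3", "cal2", "cal3")

# Design columns contributed by one variable label.
var_columns <- function(var) {
  if (var == "education") paste0("edu_", education_levels()[-1]) else var
}

# All base (order-1) variable labels for a cohort with the given diseases.
main_effect_vars <- function(diseases) {
  c(diseases, "sex_female", "education", "age", "age2", "age3",
    "cal", "cal2", "cal3")
}
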