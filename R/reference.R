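#' Published IqOR components from the RECORD walking analysis
#'
#' Interquartile odds ratios for the spatially unstructured and structured
#' between-neighborhood variance components, as reported by the RECORD cohort
#' analysis of recreational walking in the Paris region for each modelling
#' stage and outcome, together with the published total IqOR and percentage
#' of structured variance. These are reference inputs for internal-consistency
#' checks of [combine_iqors()]; they cannot be recomputed from synthetic data.
#'
#' @return a tibble with columns `outcome` (`binary` = reporting any
#'   recreational walking, `ordinal` = neighborhood walking time), `stage`
#'   (`age_sex`, `individual_level`, `environmental`), `iqor_unstructured`,
#'   `iqor_structured`, `iqor_total_published`, `pct_structured_published`.
#' @export
record_iqor_components <- function() {
  tibble::tibble(
    outcome = rep(c("binary", "ordinal"), each = 3L),
    stage = rep(c("age_sex", "individual_level", "environmental"), 2L),
    iqor_unstructured = c(1.56, 1.58, 1.57, 1.52, 1.53, 1.61),
    iqor_structured = c(1.77, 1.64, 1.34, 1.85, 1.97, 1.36),
    iqor_total_published = c(2.07, 1.97, 1.71, 2.12, 2.24, 1.77),
    pct_structured_published = c(62, 53, 29, 68, 72, 30)
  )
}
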