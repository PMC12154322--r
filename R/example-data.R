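#' Bundled pre-scored example cohort
#'
#' Eight example instances (ages 34--58) with measured biomarker values,
#' precomputed cognitive-impairment scores and assigned risk labels, used
#' throughout the documentation and tests as a small worked classification
#' example: two Safe and six Mild Risk instances.  Note its CSF Ab42 and
#' Tau values are on the laboratory pg/mL scale, not the template
#' threshold scale.
#'
#' @return Data frame with columns `Age`, the four biomarkers, `CI` and
#'   `Risk_Level`.
#' @export
#' @examples
#' ex <- example_classified_cohort()
#' classify_ci(ex$Age, ex$CI)
example_classified_cohort <- function() {
  path <- system.file("extdata", "example_classified_cohort.csv",
                      package = "adrisk", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}
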