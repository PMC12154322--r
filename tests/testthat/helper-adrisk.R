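# Shared fixtures built in code.

# Small hand-written cohort with duplicate and non-integer ages.
toy_cohort_df <- function() {
  data.frame(
    Age         = c(30, 30, 45, 52.4, 20),
    CSF_Ab42    = c(400, 420, 380, 350, 450),
    Amyloid_PET = c(1, 2, 8, 11, 0.5),
    CSF_Tau     = c(300, 310, 360, 400, 250),
    MRI_FDG_PET = c(2, 2.5, 6, 9, 1))
}

# The bundled pre-scored example with zones normalised to factor levels.
example_with_zones <- function() {
  ex <- example_classified_cohort()
  ex$zone <- adrisk:::zone_from_display(ex$Risk_Level)
  ex
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
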