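#' Construct a cohort table
#'
#' A cohort table is a data frame with columns `Age`, `CSF_Ab42`,
#' `Amyloid_PET`, `CSF_Tau`, `MRI_FDG_PET`, sorted by age, carrying a
#' free-text `provenance` attribute.  Biomarker cells may be `NA`
#' (missing); ages must be finite and within `[10, 110]`, biomarker values
#' non-negative.
#'
#' @param df Data frame holding (at least) the canonical columns.
#' @param provenance Free-text source tag.
#' @return A `cohort_table` (a data frame subclass).
#' @seealso [read_cohort()], [generate_cohort()]
#' @export
cohort_table <- function(df, provenance = "unspecified") {
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[cohort_columns()]
  for (col in cohort_columns()) df[[col]] <- as.numeric(df[[col]])
  bad <- !is.finite(df$Age) | df$Age < 10 | df$Age > 110
  if (any(bad))
    stop("age(s) outside [10, 110] or non-finite: rows ",
         paste(which(bad), collapse = ", "))
  for (bm in biomarker_names()) {
    v <- df[[bm]]
    bad <- !is.na(v) & (!is.finite(v) | v < 0)
    if (any(bad))
      stop("negative or non-finite ", bm, " in rows ",
           paste(which(bad), collapse = ", "))
  }
  df <- df[order(df$Age), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("cohort_table", "data.frame"),
            provenance = provenance)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d record(s), ages %s, provenance: %s\n",
              nrow(x),
              if (nrow(x)) sprintf("%g-%g", min(x$Age), max(x$Age)) else "-",
              attr(x, "provenance") %||% "unspecified"))
  print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

# Map a header name onto the canonical schema, tolerating case, separators
# and the beta-spelling variants of Ab42 (Ab42 / AB42 / Abeta42 / A<beta>42).
canonical_column <- function(name) {
  key <- tolower(name)
  key <- gsub("β", "b", key)        # Greek beta
  key <- gsub("beta", "b", key)
  key <- gsub("[^a-z0-9]", "", key)
  map <- c(age = "Age",
           csfab42 = "CSF_Ab42",
           amyloidpet = "Amyloid_PET",
           csftau = "CSF_Tau",
           mrifdgpet = "MRI_FDG_PET",
           ci = "CI",
           cognitiveimpairment = "CI",
           risklevel = "Risk_Level")
  out <- unname(map[key])
  ifelse(is.na(out), name, out)
}

#' Read a cohort table from CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `Age,CSF_Ab42,Amyloid_PET,CSF_Tau,MRI_FDG_PET` (column-name matching is
#' case-insensitive and tolerates `Aβ42` / `AB42` / `Abeta42`
#' spellings).  Empty cells encode missing biomarker values and are kept as
#' `NA` for later imputation.  Rows that fail validation (age outside
#' `[10, 110]`, negative or non-numeric values) are dropped with a warning,
#' or raise an error when `strict = TRUE`.
#'
#' @param path Path to the CSV file.
#' @param strict Raise instead of drop-and-warn on invalid rows.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character", strip.white = TRUE)
  names(raw) <- canonical_column(names(raw))
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- raw[cohort_columns()]
  for (col in cohort_columns()) {
    cell <- df[[col]]
    num <- suppressWarnings(as.numeric(cell))
    coerced <- !is.na(cell) & nzchar(cell) & is.na(num)
    if (any(coerced)) {
      if (strict)
        stop("non-numeric ", col, " cell(s) in rows ",
             paste(which(coerced), collapse = ", "))
      warning("dropping ", sum(coerced), " non-numeric ", col, " cell(s)")
    }
    df[[col]] <- num
  }
  keep <- is.finite(df$Age) & df$Age >= 10 & df$Age <= 110
  for (bm in biomarker_names())
    keep <- keep & (is.na(df[[bm]]) | (is.finite(df[[bm]]) & df[[bm]] >= 0))
  if (any(!keep)) {
    msg <- paste0(sum(!keep), " row(s) failed validation (age outside ",
                  "[10, 110] or invalid biomarker value)")
    if (strict) stop(msg)
    warning(msg, "; dropped")
  }
  cohort_table(df[keep, , drop = FALSE], provenance = path)
}

# 9 significant digits round-trips the precision cohort tables are
# published with.
format_cell <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 9, format = "g"))
}

#' Write a cohort table to CSV
#'
#' Emits the canonical schema with values formatted to 9 significant
#' digits; `NA` cells are written as empty fields.  Extra columns (e.g. a
#' precomputed `CI` or `Risk_Level`) present in `cohort` are appended after
#' the canonical ones.
#'
#' @param cohort A [cohort_table()] or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  extra <- setdiff(names(df), cohort_columns())
  df <- df[c(cohort_columns(), extra)]
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- format_cell(out[[col]])
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Average duplicate records sharing an age
#'
#' Records whose ages round to the same integer are collapsed into a single
#' record holding the arithmetic mean of each column (age included, so a
#' group of identical ages keeps its exact age).  Missing cells are ignored
#' in the mean; a cell missing in every group member stays `NA`.  The
#' operation is idempotent and leaves cohorts with unique ages untouched.
#'
#' @param cohort A [cohort_table()].
#' @return A [cohort_table()] with unique (rounded) ages, sorted ascending.
#' @export
aggregate_duplicates <- function(cohort) {
  df <- as.data.frame(cohort)
  key <- round(df$Age)
  if (!anyDuplicated(key)) return(cohort)
  mean_na <- function(v) {
    m <- mean(v, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  }
  agg <- stats::aggregate(df[cohort_columns()], by = list(.key = key),
                          FUN = mean_na)
  agg$.key <- NULL
  cohort_table(agg, provenance = attr(cohort, "provenance") %||% "unspecified")
}

#' Fill missing ages (and missing cells) from the sigmoid model
#'
#' Every integer age in `age_range` with no record in the cohort gains a
#' synthetic record whose biomarker values come from
#' [simulate_trajectory()] under `params`; with the default noiseless spec
#' the filled values equal `sigmoid(age)` exactly.  Missing individual
#' cells of existing records are filled through the same mechanism.  The
#' ages of synthetic records are recorded in the `synthetic_ages` attribute
#' and the provenance tag is extended.
#'
#' @param cohort A [cohort_table()].
#' @param params Named list mapping each biomarker to its
#'   [sigmoid_params()].
#' @param age_range Length-2 numeric `(lower, upper)` age interval.
#' @param noise A [noise_spec()] applied to the filled values; default none.
#' @return A [cohort_table()] dense over the integer ages of `age_range`.
#' @export
impute_missing_ages <- function(cohort, params, age_range,
                                noise = noise_spec("none")) {
  missing_params <- setdiff(biomarker_names(), names(params))
  if (length(missing_params))
    stop("no sigmoid parameters supplied for: ",
         paste(missing_params, collapse = ", "))
  noise <- as_noise_spec(noise)
  df <- as.data.frame(cohort)
  grid <- seq(ceiling(age_range[1]), floor(age_range[2]))
  absent <- setdiff(grid, round(df$Age))
  new_rows <- NULL
  if (length(absent)) {
    new_rows <- data.frame(Age = absent)
    for (i in seq_along(biomarker_names())) {
      bm <- biomarker_names()[i]
      ns <- noise
      ns$seed <- child_seed(noise$seed, i)
      new_rows[[bm]] <- simulate_trajectory(absent, params[[bm]], ns)
    }
  }
  # same mechanism for isolated missing cells of observed records
  for (i in seq_along(biomarker_names())) {
    bm <- biomarker_names()[i]
    hole <- which(is.na(df[[bm]]))
    if (length(hole)) {
      ns <- noise
      ns$seed <- child_seed(noise$seed, 100L + i)
      df[[bm]][hole] <- simulate_trajectory(df$Age[hole], params[[bm]], ns)
      message("filled ", length(hole), " missing ", bm, " cell(s)")
    }
  }
  out <- if (is.null(new_rows)) df else rbind(df, new_rows)
  prov <- attr(cohort, "provenance") %||% "unspecified"
  if (length(absent)) prov <- paste0(prov, "+sigmoid-imputed")
  res <- cohort_table(out, provenance = prov)
  attr(res, "synthetic_ages") <- as.numeric(absent)
  res
}
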