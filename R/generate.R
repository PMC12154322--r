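#' Illustrative default sigmoid parameters for the four biomarkers
#'
#' A parameter set chosen so the four age trajectories show the qualitative
#' shapes expected of preclinical Alzheimer's progression on the template
#' threshold scale (see [default_threshold_tables()]): CSF amyloid-beta 42
#' falls with age, while amyloid PET, CSF Tau and MRI FDG-PET rise.  These
#' defaults are illustrative configuration, not clinically calibrated
#' constants; supply your own parameters for any scientific use.
#'
#' @return Named list of [sigmoid_params()], one per biomarker.
#' @export
#' @examples
#' p <- default_sigmoid_params()
#' sigmoid(c(30, 50, 70), p$CSF_Ab42)
default_sigmoid_params <- function() {
  list(
    CSF_Ab42    = sigmoid_params(L = 22, k = 0.08,  x0 = 55),  # declining
    Amyloid_PET = sigmoid_params(L = 20, k = -0.07, x0 = 50),  # rising
    CSF_Tau     = sigmoid_params(L = 16, k = -0.06, x0 = 60),  # rising
    MRI_FDG_PET = sigmoid_params(L = 14, k = -0.06, x0 = 60)   # rising
  )
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n_per_age` records at every integer age in `age_range`.  Each
#' biomarker follows its sigmoid trajectory perturbed per `noise`, with an
#' independent child RNG stream per biomarker derived from `seed` (so
#' results do not depend on column order).  CSF Tau additionally receives
#' `tau_coupling` times the deviation of CSF amyloid-beta 42 from its mean
#' trajectory, so that with `tau_coupling < 0` Tau and Ab42 fluctuations
#' are negatively correlated — the inverse amyloid--Tau relationship seen
#' in observed cohorts.  All values are floored at 0.
#'
#' @param n_per_age Records per integer age (default 5).
#' @param age_range Length-2 `(lower, upper)` ages; default `c(31, 60)`,
#'   giving 150 records over 30 ages at the default `n_per_age`, all
#'   inside the default age-band registry (whose bands are left-open, so
#'   age 30 itself is uncovered).
#' @param params Named list of per-biomarker [sigmoid_params()].
#' @param noise A [noise_spec()]; its `seed` field is ignored in favour of
#'   the `seed` argument.
#' @param tau_coupling Coupling coefficient (non-positive by convention).
#' @param seed Optional root seed; fixing it makes the cohort
#'   bit-reproducible.
#' @return A [cohort_table()] with provenance `"synthetic"`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 42)
#' nrow(cohort)
generate_cohort <- function(n_per_age = 5L, age_range = c(31, 60),
                            params = default_sigmoid_params(),
                            noise = noise_spec("additive", sd = 0.5),
                            tau_coupling = -0.5, seed = NULL) {
  stopifnot(n_per_age >= 1L, length(age_range) == 2L,
            age_range[2] >= age_range[1])
  missing_params <- setdiff(biomarker_names(), names(params))
  if (length(missing_params))
    stop("no sigmoid parameters supplied for: ",
         paste(missing_params, collapse = ", "))
  noise <- as_noise_spec(noise)
  ages <- rep(seq(ceiling(age_range[1]), floor(age_range[2])),
              each = n_per_age)
  if (!length(ages)) stop("empty age range")
  df <- data.frame(Age = ages)
  for (i in seq_along(biomarker_names())) {
    bm <- biomarker_names()[i]
    ns <- noise
    ns$seed <- child_seed(seed, i) %||% noise$seed
    df[[bm]] <- simulate_trajectory(ages, params[[bm]], ns)
  }
  ab_mu <- sigmoid(ages, as_sigmoid_params(params$CSF_Ab42))
  df$CSF_Tau <- pmax(df$CSF_Tau + tau_coupling * (df$CSF_Ab42 - ab_mu), 0)
  cohort_table(df, provenance = "synthetic")
}

#' Per-age-bin descriptive summary of a cohort
#'
#' Bins ages into `[10, 10 + w), [10 + w, 10 + 2w), ...` and reports, per
#' bin and biomarker, the mean, standard deviation (0 for singleton bins),
#' minimum, maximum and count.  Empty bins are omitted.
#'
#' @param cohort A [cohort_table()].
#' @param bin_width Positive bin width in years.
#' @return A long data frame with columns `bin_lower`, `bin_upper`,
#'   `biomarker`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
descriptive_summary <- function(cohort, bin_width = 10) {
  stopifnot(bin_width > 0)
  df <- as.data.frame(cohort)
  bin <- floor((df$Age - 10) / bin_width)
  rows <- list()
  for (b in sort(unique(bin))) {
    in_bin <- df[bin == b, , drop = FALSE]
    for (bm in biomarker_names()) {
      v <- in_bin[[bm]][!is.na(in_bin[[bm]])]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        bin_lower = 10 + b * bin_width,
        bin_upper = 10 + (b + 1) * bin_width,
        biomarker = bm,
        mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        min = min(v), max = max(v), n = length(v))
    }
  }
  do.call(rbind, rows)
}

#' Least-squares association between two biomarker columns
#'
#' Ordinary least-squares fit of `y_col` on `x_col` plus the Pearson
#' correlation, used e.g. to quantify the inverse amyloid-beta--Tau
#' relationship in a cohort.
#'
#' @param cohort A [cohort_table()] (or data frame with the two columns).
#' @param x_col,y_col Column names.
#' @return A list of class `regression_summary` with elements `slope`,
#'   `intercept`, `r` and `n`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' correlate(cohort, "CSF_Ab42", "CSF_Tau")
correlate <- function(cohort, x_col, y_col) {
  df <- as.data.frame(cohort)
  stopifnot(x_col %in% names(df), y_col %in% names(df))
  ok <- is.finite(df[[x_col]]) & is.finite(df[[y_col]])
  x <- df[[x_col]][ok]
  y <- df[[y_col]][ok]
  if (length(x) < 2L) stop("need at least 2 complete records")
  if (stats::sd(x) == 0) stop("zero variance in ", x_col)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = stats::cor(x, y),
                 n = length(x)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf(
    "<regression_summary> slope = %.4g, intercept = %.4g, r = %.3f, n = %d\n",
    x$slope, x$intercept, x$r, x$n))
  invisible(x)
}
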