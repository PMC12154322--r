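#' Age-band registry for CI risk zoning
#'
#' An age-band registry is a data frame with one row per band and columns
#' `lower`, `upper` (years; bands are `(lower, upper]`), `gamma` and
#' `delta` (the Safe/Mild and Mild/Unsafe CI cut-points), and `safe_lo`,
#' `unsafe_hi` (display/plausibility edges only — classification uses
#' `gamma`/`delta` alone).  Bands must be contiguous, non-overlapping and
#' sorted, with `gamma < delta`.
#'
#' @param df Data frame with the columns above.
#' @return A validated `age_band_registry`.
#' @export
age_band_registry <- function(df) {
  need <- c("lower", "upper", "gamma", "delta", "safe_lo", "unsafe_hi")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[need]
  df <- df[order(df$lower), , drop = FALSE]
  rownames(df) <- NULL
  stopifnot(all(df$lower < df$upper), all(df$gamma < df$delta))
  if (nrow(df) > 1L && any(df$lower[-1L] != df$upper[-nrow(df)]))
    stop("age bands must be contiguous and non-overlapping")
  structure(df, class = c("age_band_registry", "data.frame"))
}

#' Default age-band registry
#'
#' Four decade-wide bands covering ages (30, 70], with CI cut-points
#' `(gamma, delta)` of (3, 6), (4, 7), (5, 8) and (6, 9) and display
#' ranges rising from 0--10 to 2--14.  Cut-points relax with age so that
#' the same CI score is judged more strictly in younger adults.
#'
#' @return An [age_band_registry()].
#' @export
#' @examples
#' default_age_bands()
default_age_bands <- function() {
  age_band_registry(data.frame(
    lower     = c(30, 40, 50, 60),
    upper     = c(40, 50, 60, 70),
    gamma     = c(3, 4, 5, 6),
    delta     = c(6, 7, 8, 9),
    safe_lo   = c(0, 1, 1.5, 2),
    unsafe_hi = c(10, 12, 13, 14)))
}

# Vectorised band index under the (lower, upper] convention; 0 outside.
band_index <- function(age, registry) {
  edges <- c(registry$lower[1L], registry$upper)
  idx <- findInterval(age, edges, left.open = TRUE)
  idx[idx > nrow(registry)] <- 0L
  idx
}

#' Look up the age band covering an age
#'
#' Bands are half-open `(lower, upper]`, so e.g. age 40 belongs to a
#' 30--40 band, not 40--50.
#'
#' @param age Scalar age in years.
#' @param registry An [age_band_registry()].
#' @return The matching one-row band (a data frame row).
#' @export
#' @examples
#' band_for_age(40, default_age_bands())
band_for_age <- function(age, registry = default_age_bands()) {
  stopifnot(length(age) == 1L)
  idx <- band_index(age, registry)
  if (idx == 0L)
    stop("age ", age, " is outside the registry (",
         registry$lower[1L], ", ", registry$upper[nrow(registry)], "]")
  registry[idx, , drop = FALSE]
}

#' Classify CI scores into risk zones
#'
#' Applies the age band's cut-points: Safe when `ci <= gamma`, Mild Risk
#' when `gamma < ci <= delta`, Unsafe when `ci > delta` (both boundaries
#' belong to the less severe zone).  Vectorised over `age` and `ci`.  A CI
#' below the band's display floor still classifies Safe but triggers a
#' plausibility warning.
#'
#' @param age Numeric vector of ages; each must fall in a band.
#' @param ci Numeric vector of CI scores (recycled against `age`).
#' @param registry An [age_band_registry()].
#' @param warn_implausible Emit the below-display-floor warning.
#' @return Factor with levels `Safe`, `MildRisk`, `Unsafe`.
#' @export
#' @examples
#' classify_ci(c(58, 40), c(3.18, 3.37))
classify_ci <- function(age, ci, registry = default_age_bands(),
                        warn_implausible = TRUE) {
  n <- max(length(age), length(ci))
  age <- rep_len(age, n)
  ci <- rep_len(ci, n)
  idx <- band_index(age, registry)
  if (any(idx == 0L))
    stop("age(s) outside the registry: ",
         paste(unique(age[idx == 0L]), collapse = ", "))
  gamma <- registry$gamma[idx]
  delta <- registry$delta[idx]
  zone <- ifelse(ci <= gamma, "Safe", ifelse(ci <= delta, "MildRisk", "Unsafe"))
  if (warn_implausible && any(ci < registry$safe_lo[idx]))
    warning(sum(ci < registry$safe_lo[idx]),
            " CI score(s) below the band display floor; classified Safe")
  factor(zone, levels = zone_levels())
}

#' Optional four-level zone relabeling
#'
#' Re-expresses the three CI zones on the four-level Normal / Mild Risk /
#' High Risk / MCI scale sometimes used for lifespan trajectory plots:
#' Safe maps to Normal, Mild Risk stays, and Unsafe splits at the band's
#' display upper edge (`unsafe_hi`) into High Risk (at or below it) versus
#' MCI (above it).  The three-zone system of [classify_ci()] remains the
#' default output everywhere else, since only the two cut-points
#' `gamma`/`delta` are formally defined.
#'
#' @inheritParams classify_ci
#' @return Factor with levels `Normal`, `MildRisk`, `HighRisk`, `MCI`.
#' @export
#' @examples
#' classify_ci_four(c(35, 35, 35, 35), c(2, 4, 8, 12))
classify_ci_four <- function(age, ci, registry = default_age_bands()) {
  n <- max(length(age), length(ci))
  age <- rep_len(age, n)
  ci <- rep_len(ci, n)
  zone <- classify_ci(age, ci, registry, warn_implausible = FALSE)
  idx <- band_index(age, registry)
  out <- c(Safe = "Normal", MildRisk = "MildRisk",
           Unsafe = "HighRisk")[as.character(zone)]
  out[zone == "Unsafe" & ci > registry$unsafe_hi[idx]] <- "MCI"
  factor(unname(out), levels = c("Normal", "MildRisk", "HighRisk", "MCI"))
}

#' Age-group biomarker threshold table
#'
#' Per-biomarker Normal / Low Risk / High Risk value ranges for one age
#' group.  `direction` is `"higher"` when larger values are riskier
#' (amyloid PET, CSF Tau, MRI FDG-PET, CI) and `"lower"` for CSF
#' amyloid-beta 42, whose ranges run the opposite way (higher is safer).
#' Within each biomarker the three ranges must be non-overlapping and
#' ordered along the risk direction.
#'
#' @param lower,upper Age interval covered, `(lower, upper]`.
#' @param rows Data frame with columns `biomarker`, `normal_lo`,
#'   `normal_hi`, `lowrisk_lo`, `lowrisk_hi`, `highrisk_lo`, `highrisk_hi`,
#'   `direction`.
#' @return A `threshold_table`.
#' @export
threshold_table <- function(lower, upper, rows) {
  need <- c("biomarker", "normal_lo", "normal_hi", "lowrisk_lo",
            "lowrisk_hi", "highrisk_lo", "highrisk_hi", "direction")
  stopifnot(lower < upper, all(need %in% names(rows)),
            all(rows$direction %in% c("higher", "lower")))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    ok <- if (r$direction == "higher")
      r$normal_lo < r$normal_hi && r$normal_hi <= r$lowrisk_lo &&
        r$lowrisk_lo < r$lowrisk_hi && r$lowrisk_hi <= r$highrisk_lo &&
        r$highrisk_lo < r$highrisk_hi
    else
      r$highrisk_lo < r$highrisk_hi && r$highrisk_hi <= r$lowrisk_lo &&
        r$lowrisk_lo < r$lowrisk_hi && r$lowrisk_hi <= r$normal_lo &&
        r$normal_lo < r$normal_hi
    if (!ok) stop("ranges for ", r$biomarker,
                  " are overlapping or mis-ordered for direction '",
                  r$direction, "'")
  }
  structure(list(lower = lower, upper = upper,
                 rows = as.data.frame(rows)[need]),
            class = "threshold_table")
}

threshold_rows <- function(lower, upper, m) {
  # m: list biomarker -> c(n_lo, n_hi, l_lo, l_hi, h_lo, h_hi)
  rows <- do.call(rbind, lapply(names(m), function(bm) {
    v <- m[[bm]]
    data.frame(biomarker = bm,
               normal_lo = v[1], normal_hi = v[2],
               lowrisk_lo = v[3], lowrisk_hi = v[4],
               highrisk_lo = v[5], highrisk_hi = v[6],
               direction = if (bm == "CSF_Ab42") "lower" else "higher")
  }))
  threshold_table(lower, upper, rows)
}

#' Default biomarker threshold templates
#'
#' Three age-group templates (ages 30--40, 40--50 and 55--65) giving, per
#' biomarker plus the CI score itself, the Normal, Low Risk and High Risk
#' value ranges on the template (sigmoid-scaled) unit system.  The 30--40
#' group is strictest; ranges drift upward with age to allow for normal
#' biomarker drift.  Note the age groups are the templates' own and are
#' looked up independently of the CI band registry (the 55--65 group
#' deliberately does not align with any CI band).
#'
#' @return Named list of [threshold_table()] objects.
#' @seealso [clinical_reference_ranges()] for the separate pg/mL-scale
#'   reference values; the two scales are never mixed.
#' @export
default_threshold_tables <- function() {
  list(
    "30-40" = threshold_rows(30, 40, list(
      CSF_Ab42             = c(15, 22, 10, 15, 5, 10),
      Amyloid_PET          = c(4, 7, 7, 10, 10, 15),
      CSF_Tau              = c(3, 6, 6, 9, 9, 12),
      MRI_FDG_PET          = c(2, 5, 5, 8, 8, 12),
      Cognitive_Impairment = c(0, 3, 3, 6, 6, 10))),
    "40-50" = threshold_rows(40, 50, list(
      CSF_Ab42             = c(12, 18, 8, 12, 5, 8),
      Amyloid_PET          = c(5, 9, 9, 12, 12, 18),
      CSF_Tau              = c(4, 7, 7, 10, 10, 14),
      MRI_FDG_PET          = c(3, 6, 6, 9, 9, 13),
      Cognitive_Impairment = c(1, 4, 4, 7, 7, 12))),
    "55-65" = threshold_rows(55, 65, list(
      CSF_Ab42             = c(10, 15, 6, 10, 3, 6),
      Amyloid_PET          = c(7, 12, 12, 16, 16, 22),
      CSF_Tau              = c(5, 8, 8, 12, 12, 16),
      MRI_FDG_PET          = c(4, 7, 7, 10, 10, 15),
      Cognitive_Impairment = c(2, 5, 5, 9, 9, 14)))
  )
}

#' Clinical reference ranges (pg/mL scale)
#'
#' Literature-derived clinical cut-offs on the laboratory (pg/mL /
#' Centiloid) scale, shipped separately from the template-scale
#' [default_threshold_tables()] because the two unit systems are not
#' interconvertible within this package: CSF amyloid-beta 42 below
#' 480 pg/mL (plaque accumulation) or normal between 600 and 800 pg/mL;
#' CSF Tau below 300 pg/mL for ages 21--50 and below 450 pg/mL for ages
#' 51--70; amyloid PET Centiloid 0 typical of young adults, approaching
#' 100 with neurodegenerative change.
#'
#' @return Nested list of reference values with units.
#' @export
clinical_reference_ranges <- function() {
  list(
    CSF_Ab42 = list(units = "pg/mL", low_cut = 480,
                    normal = c(600, 800), high_cut = 800),
    CSF_Tau = list(units = "pg/mL",
                   upper_by_age = data.frame(lower = c(21, 51),
                                             upper = c(50, 70),
                                             max_normal = c(300, 450))),
    Amyloid_PET = list(units = "Centiloid", young_normal = 0,
                       neurodegenerative = 100)
  )
}

#' Flag a biomarker value against an age-group threshold table
#'
#' Categories are scanned along the risk direction with half-open ranges:
#' a boundary shared by two ranges belongs to the riskier one (e.g. a
#' value equal to the Normal/Low-Risk boundary flags Low Risk).  Values
#' beyond the risky extreme flag `HighRisk`; values beyond the safe
#' extreme flag `OutOfRange`.
#'
#' @param table A [threshold_table()].
#' @param biomarker Biomarker name present in the table.
#' @param value Numeric vector of values to flag.
#' @return Character vector in
#'   `{"Normal", "LowRisk", "HighRisk", "OutOfRange"}`.
#' @export
#' @examples
#' t34 <- default_threshold_tables()[["30-40"]]
#' flag_biomarker(t34, "Amyloid_PET", c(5, 7, 11))
flag_biomarker <- function(table, biomarker, value) {
  stopifnot(inherits(table, "threshold_table"))
  r <- table$rows[table$rows$biomarker == biomarker, ]
  if (nrow(r) != 1L) stop("unknown biomarker: ", biomarker)
  if (r$direction == "higher") {
    ifelse(value >= r$highrisk_lo, "HighRisk",
           ifelse(value >= r$lowrisk_lo, "LowRisk",
                  ifelse(value >= r$normal_lo, "Normal", "OutOfRange")))
  } else {
    ifelse(value <= r$highrisk_hi, "HighRisk",
           ifelse(value <= r$lowrisk_hi, "LowRisk",
                  ifelse(value <= r$normal_hi, "Normal", "OutOfRange")))
  }
}

# Threshold table covering an age, under (lower, upper]; NULL when none.
threshold_table_for_age <- function(age, tables = default_threshold_tables()) {
  for (t in tables) if (t$lower < age && age <= t$upper) return(t)
  NULL
}

#' Classify one measured instance
#'
#' Chains [ci_from_observation()] and [classify_ci()]; when threshold
#' tables are supplied and one covers the instance's age, per-biomarker
#' flags from [flag_biomarker()] are attached.
#'
#' @param record One-row [cohort_table()] or compatible data frame.
#' @param ci_params A [ci_params()] object.
#' @param registry An [age_band_registry()].
#' @param thresholds Optional list of [threshold_table()]s.
#' @return A list of class `risk_assessment` with elements `age`, `ci`,
#'   `zone`, `band` and `flags` (possibly `NULL`).
#' @export
classify_instance <- function(record, ci_params,
                              registry = default_age_bands(),
                              thresholds = NULL) {
  df <- as.data.frame(record)
  stopifnot(nrow(df) == 1L)
  ci <- ci_from_observation(df, ci_params)
  zone <- classify_ci(df$Age, ci, registry, warn_implausible = FALSE)
  flags <- NULL
  if (!is.null(thresholds)) {
    tab <- threshold_table_for_age(df$Age, thresholds)
    if (!is.null(tab)) {
      flags <- vapply(biomarker_names(),
                      function(bm) flag_biomarker(tab, bm, df[[bm]]),
                      character(1L))
      if ("Cognitive_Impairment" %in% tab$rows$biomarker)
        flags <- c(flags,
                   Cognitive_Impairment =
                     flag_biomarker(tab, "Cognitive_Impairment", ci))
    }
  }
  structure(list(age = df$Age, ci = ci, zone = zone,
                 band = band_for_age(df$Age, registry), flags = flags),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> age %g: CI = %.3f -> %s (band %g-%g)\n",
              x$age, x$ci, zone_display(x$zone), x$band$lower, x$band$upper))
  if (!is.null(x$flags))
    cat("  flags:", paste(names(x$flags), x$flags, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Screen a cohort into risk zones
#'
#' Scores every record (reusing a precomputed `CI` column when present, or
#' via `ci` / `ci_params`), classifies it, and tallies per-zone counts.
#' Deterministic and invariant to record order (up to row ordering of the
#' per-instance table, which follows the input).
#'
#' @param cohort A [cohort_table()] or data frame (may carry a `CI`
#'   column).
#' @param ci_params A [ci_params()]; only needed when no CI is supplied.
#' @param registry An [age_band_registry()].
#' @param ci Optional explicit CI vector overriding both other sources.
#' @return A list of class `screen_result`: `counts` (named integer vector
#'   over the three zones) and `assessments` (a data frame mirroring the
#'   cohort with `CI` and `Risk_Level` columns).
#' @export
#' @examples
#' screen_cohort(generate_cohort(seed = 3), default_ci_params())
screen_cohort <- function(cohort, ci_params = NULL,
                          registry = default_age_bands(), ci = NULL) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0L) {
    counts <- stats::setNames(integer(3L), zone_levels())
    return(structure(list(counts = counts,
                          assessments = cbind(df, CI = numeric(0),
                                              Risk_Level = character(0))),
                     class = "screen_result"))
  }
  if (is.null(ci)) {
    ci <- if ("CI" %in% names(df)) {
      df$CI
    } else {
      if (is.null(ci_params))
        stop("supply ci_params, an explicit ci vector, or a CI column")
      ci_from_observation(df, ci_params)
    }
  }
  zone <- classify_ci(df$Age, ci, registry, warn_implausible = FALSE)
  counts <- table(zone)
  counts <- stats::setNames(as.integer(counts[zone_levels()]), zone_levels())
  out <- df[setdiff(names(df), c("CI", "Risk_Level"))]
  out$CI <- ci
  out$Risk_Level <- unname(zone_display(zone))
  structure(list(counts = counts, assessments = out),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", sum(x$counts), " instance(s): ",
      paste(names(x$counts), x$counts, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Biomarker range keeping an instance in the Safe zone
#'
#' Holding age and the other three biomarkers fixed, solves the linear
#' Safe-zone inequality
#' \eqn{\alpha e^{\beta A} + \sum_i w_i x_i \le \gamma} for the varying
#' biomarker and intersects the resulting half-line with `[0, Inf)`.  A
#' positive weight yields an upper limit `[0, b]`; a negative (protective)
#' weight a lower limit `[max(0, b), Inf)`.
#'
#' @param age Scalar age (must fall in a band).
#' @param ci_params A [ci_params()] with a non-zero weight for `vary`.
#' @param registry An [age_band_registry()].
#' @param vary Name of the biomarker to solve for.
#' @param fixed Named numeric vector with the other three biomarker
#'   values.
#' @return Numeric `c(lower, upper)`; `c(NA, NA)` when no non-negative
#'   value keeps the instance Safe.
#' @export
safe_biomarker_bounds <- function(age, ci_params,
                                  registry = default_age_bands(),
                                  vary, fixed) {
  params <- as_ci_params(ci_params)
  stopifnot(vary %in% biomarker_names())
  others <- setdiff(biomarker_names(), vary)
  if (!all(others %in% names(fixed)))
    stop("fixed must name the other three biomarkers: ",
         paste(others, collapse = ", "))
  w <- stats::setNames(params$terms$w, params$terms$biomarker)
  if (w[[vary]] == 0) stop("zero weight for ", vary, "; bound undefined")
  gamma <- band_for_age(age, registry)$gamma
  base <- params$alpha * exp(params$beta * age) +
    sum(w[others] * fixed[others])
  b <- (gamma - base) / w[[vary]]
  if (w[[vary]] > 0) {
    if (b < 0) return(c(lower = NA_real_, upper = NA_real_))
    c(lower = 0, upper = unname(b))
  } else {
    c(lower = max(0, unname(b)), upper = Inf)
  }
}

# First age in (lo, hi] where pred(age) is TRUE, given pred(lo) FALSE and
# pred(hi) TRUE, bisected to tol.
bisect_crossing <- function(pred, lo, hi, tol = 1e-6) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pred(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Retrospective intervention-window estimate
#'
#' Scans the model-based CI trajectory [ci_from_age()] over an age range,
#' finds the first age whose zone leaves Safe (`onset_age`) and the first
#' age entering Unsafe (`unsafe_age`), refining each crossing by bisection
#' to 1e-6 years.  The intervention window is `[onset_age, unsafe_age)` —
#' the span during which the modeled trajectory is at mild risk but not
#' yet unsafe; its upper end falls back to the range end when the
#' trajectory never turns Unsafe.  Crossings can arise both from CI growth
#' and from cut-point changes at band boundaries.
#'
#' @param ci_params A [ci_params()] object.
#' @param registry An [age_band_registry()].
#' @param age_range Length-2 interval, contained in the registry.
#' @param step Positive scan resolution in years (default 0.25).
#' @return List with `onset_age`, `unsafe_age` (each `NA` when no crossing
#'   occurs) and `window` (`c(lower, upper)` or `NULL` when empty).
#' @export
#' @examples
#' intervention_window(default_ci_params(), age_range = c(31, 70))
intervention_window <- function(ci_params, registry = default_age_bands(),
                                age_range, step = 0.25) {
  stopifnot(step > 0, length(age_range) == 2L, age_range[1] < age_range[2])
  grid <- unique(c(seq(age_range[1], age_range[2], by = step), age_range[2]))
  zones <- classify_ci(grid, ci_from_age(grid, ci_params), registry,
                       warn_implausible = FALSE)
  zone_at <- function(a) classify_ci(a, ci_from_age(a, ci_params), registry,
                                     warn_implausible = FALSE)
  not_safe <- zones != "Safe"
  unsafe <- zones == "Unsafe"
  onset_age <- if (!any(not_safe)) NA_real_ else if (not_safe[1L]) grid[1L]
  else bisect_crossing(function(a) zone_at(a) != "Safe",
                       grid[which(not_safe)[1L] - 1L],
                       grid[which(not_safe)[1L]])
  unsafe_age <- if (!any(unsafe)) NA_real_ else if (unsafe[1L]) grid[1L]
  else bisect_crossing(function(a) zone_at(a) == "Unsafe",
                       grid[which(unsafe)[1L] - 1L],
                       grid[which(unsafe)[1L]])
  window <- NULL
  if (!is.na(onset_age)) {
    upper <- if (is.na(unsafe_age)) age_range[2] else unsafe_age
    if (upper > onset_age) window <- c(lower = onset_age, upper = upper)
  }
  list(onset_age = onset_age, unsafe_age = unsafe_age, window = window)
}
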