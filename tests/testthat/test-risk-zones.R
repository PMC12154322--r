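test_that("band lookup follows the (lower, upper] convention", {
  reg <- default_age_bands()
  b40 <- band_for_age(40, reg)
  expect_equal(c(b40$lower, b40$upper, b40$gamma, b40$delta), c(30, 40, 3, 6))
  b41 <- band_for_age(41, reg)
  expect_equal(c(b41$lower, b41$upper), c(40, 50))
  expect_error(band_for_age(30, reg), "outside the registry")
  expect_error(band_for_age(70.5, reg), "outside the registry")
  # default cut-points across the four bands
  expect_equal(reg$gamma, c(3, 4, 5, 6))
  expect_equal(reg$delta, c(6, 7, 8, 9))
  expect_error(age_band_registry(
    data.frame(lower = c(30, 45), upper = c(40, 55), gamma = c(3, 4),
               delta = c(6, 7), safe_lo = 0, unsafe_hi = 10)),
    "contiguous")
})

test_that("CI classification matches the bundled example and its boundaries", {
  expect_equal(as.character(classify_ci(58, 3.18)), "Safe")
  expect_equal(as.character(classify_ci(40, 3.37)), "MildRisk")
  expect_equal(as.character(classify_ci(47, 5.30)), "MildRisk")
  expect_equal(as.character(classify_ci(35, 3.0)), "Safe")    # ci == gamma
  expect_equal(as.character(classify_ci(35, 6.0)), "MildRisk") # ci == delta
  ex <- example_with_zones()
  expect_identical(classify_ci(ex$Age, ex$CI), ex$zone)
  expect_warning(classify_ci(55, 0.5), "display floor")
})

test_that("classification is total, exclusive and monotone in CI", {
  set.seed(41)
  age <- runif(10000, 30 + 1e-9, 70)
  ci <- runif(10000, -2, 20)
  z <- classify_ci(age, ci, warn_implausible = FALSE)
  expect_false(anyNA(z))                       # total
  expect_equal(length(z), 10000L)              # exactly one label each
  # monotone non-decreasing in ci at fixed age
  for (a in c(31, 40, 47.5, 60, 70)) {
    zz <- classify_ci(rep(a, 400), sort(runif(400, -1, 18)),
                      warn_implausible = FALSE)
    expect_true(all(diff(as.integer(zz)) >= 0))
  }
})

test_that("four-level relabeling splits Unsafe at the display upper edge", {
  # 30-40 band: gamma 3, delta 6, display upper edge 10
  z <- classify_ci_four(rep(35, 5), c(2, 4, 8, 10, 12))
  expect_equal(as.character(z),
               c("Normal", "MildRisk", "HighRisk", "HighRisk", "MCI"))
  # collapses back onto the three-zone system
  z3 <- classify_ci(rep(35, 5), c(2, 4, 8, 10, 12),
                    warn_implausible = FALSE)
  expect_equal(z == "Normal", z3 == "Safe")
  expect_equal(z == "MildRisk", z3 == "MildRisk")
  expect_equal(z %in% c("HighRisk", "MCI"), z3 == "Unsafe")
})

test_that("threshold flagging matches the template tables and conventions", {
  tabs <- default_threshold_tables()
  expect_equal(flag_biomarker(tabs[["30-40"]], "Amyloid_PET", 5), "Normal")
  expect_equal(flag_biomarker(tabs[["30-40"]], "CSF_Tau", 11), "HighRisk")
  expect_equal(flag_biomarker(tabs[["40-50"]], "CSF_Ab42", 13), "Normal")
  # shared boundary belongs to the riskier range
  expect_equal(flag_biomarker(tabs[["30-40"]], "Amyloid_PET", 7), "LowRisk")
  expect_equal(flag_biomarker(tabs[["30-40"]], "CSF_Ab42", 15), "LowRisk")
  # beyond the risky extreme stays HighRisk; beyond the safe extreme is
  # OutOfRange
  expect_equal(flag_biomarker(tabs[["30-40"]], "Amyloid_PET", 40), "HighRisk")
  expect_equal(flag_biomarker(tabs[["30-40"]], "Amyloid_PET", 1), "OutOfRange")
  expect_equal(flag_biomarker(tabs[["30-40"]], "CSF_Ab42", 2), "HighRisk")
  expect_equal(flag_biomarker(tabs[["30-40"]], "CSF_Ab42", 30), "OutOfRange")
  expect_error(flag_biomarker(tabs[["30-40"]], "nope", 1), "unknown biomarker")
  # every cell of every table, probed at its midpoint
  for (tab in tabs) {
    for (i in seq_len(nrow(tab$rows))) {
      r <- tab$rows[i, ]
      expect_equal(flag_biomarker(tab, r$biomarker,
                                  (r$normal_lo + r$normal_hi) / 2), "Normal")
      expect_equal(flag_biomarker(tab, r$biomarker,
                                  (r$lowrisk_lo + r$lowrisk_hi) / 2), "LowRisk")
      expect_equal(flag_biomarker(tab, r$biomarker,
                                  (r$highrisk_lo + r$highrisk_hi) / 2),
                   "HighRisk")
    }
  }
  # the 55-65 template is keyed by its own interval, not the CI bands
  expect_null(adrisk:::threshold_table_for_age(52, tabs))
  expect_equal(adrisk:::threshold_table_for_age(65, tabs)$lower, 55)
})

test_that("classify_instance chains scoring, zoning and flagging", {
  p <- default_ci_params()
  rec <- data.frame(Age = 45, CSF_Ab42 = 14, Amyloid_PET = 7,
                    CSF_Tau = 5, MRI_FDG_PET = 4)
  a <- classify_instance(rec, p, thresholds = default_threshold_tables())
  expect_equal(a$ci, ci_from_observation(rec, p))
  expect_identical(a$zone, classify_ci(45, a$ci))
  expect_equal(unname(a$flags[["CSF_Ab42"]]), "Normal")
  # zero-weight params: zone determined purely by the age term
  p0 <- ci_params(p$alpha, p$beta, rep(0, 4), p$terms$k, p$terms$m)
  a0 <- classify_instance(rec, p0)
  expect_identical(a0$zone, classify_ci(45, p$alpha * exp(p$beta * 45)))
  # raising Ab42 (w1 < 0) can only move the zone toward Safe
  for (ab in seq(0, 30, by = 2)) {
    r2 <- rec; r2$CSF_Ab42 <- rec$CSF_Ab42 + ab
    expect_lte(as.integer(classify_instance(r2, p)$zone),
               as.integer(a$zone))
  }
})

test_that("screen_cohort tallies zones exactly and ignores record order", {
  ex <- example_with_zones()
  res <- screen_cohort(ex)                      # uses the CI column
  expect_equal(res$counts, c(Safe = 2L, MildRisk = 6L, Unsafe = 0L))
  expect_equal(sum(res$counts), nrow(ex))
  expect_equal(res$assessments$Risk_Level, ex$Risk_Level)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  expect_equal(screen_cohort(ex[perm, ])$counts, res$counts)
  empty <- screen_cohort(ex[0, ])
  expect_equal(sum(empty$counts), 0L)
  # seeded generator pool: counts reproducible bit-for-bit
  p <- default_ci_params()
  c1 <- screen_cohort(generate_cohort(seed = 9), p)
  c2 <- screen_cohort(generate_cohort(seed = 9), p)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$assessments, c2$assessments)
})

test_that("safe biomarker bounds solve the Safe inequality exactly", {
  p <- default_ci_params()
  fixed <- c(CSF_Ab42 = 15, Amyloid_PET = 5, CSF_Tau = 4, MRI_FDG_PET = 3)
  # positive weight: upper limit; negative weight: lower limit
  up <- safe_biomarker_bounds(45, p, vary = "CSF_Tau",
                              fixed = fixed[names(fixed) != "CSF_Tau"])
  expect_equal(unname(up["lower"]), 0)
  expect_true(is.finite(up["upper"]))
  lo <- safe_biomarker_bounds(45, p, vary = "CSF_Ab42",
                              fixed = fixed[names(fixed) != "CSF_Ab42"])
  expect_identical(unname(lo["upper"]), Inf)
  # brute-force grid oracle around each returned bound
  set.seed(53)
  for (i in 1:12) {
    pp <- ci_params(runif(1, 0, 0.6), runif(1, 0, 0.05),
                    w = c(-runif(1, 0.01, 0.1), runif(3, 0.01, 0.3)),
                    k = rep(1, 4), m = rep(0, 4))
    age <- runif(1, 30 + 1e-6, 70)
    vary <- sample(biomarker_names(), 1)
    others <- setdiff(biomarker_names(), vary)
    fx <- stats::setNames(runif(3, 0, 10), others)
    b <- safe_biomarker_bounds(age, pp, vary = vary, fixed = fx)
    zone_at <- function(v) {
      rec <- as.data.frame(as.list(c(Age = age, fx, stats::setNames(v, vary))))
      as.character(classify_instance(rec, pp)$zone)
    }
    eps <- 1e-6
    if (anyNA(b)) {
      expect_false(zone_at(0) == "Safe")        # even 0 cannot stay Safe
    } else if (is.finite(b["upper"])) {         # positive weight: [0, b]
      expect_equal(zone_at(max(b["upper"] - eps, 0)), "Safe")
      expect_false(zone_at(b["upper"] + eps) == "Safe")
    } else {                                    # negative weight: [b, Inf)
      expect_equal(zone_at(b["lower"] + eps), "Safe")
      if (b["lower"] > eps)
        expect_false(zone_at(b["lower"] - eps) == "Safe")
    }
  }
  expect_error(
    safe_biomarker_bounds(45, ci_params(1, 0, c(0, 1, 1, 1), rep(1, 4),
                                        rep(0, 4)),
                          vary = "CSF_Ab42",
                          fixed = fixed[-1]),
    "zero weight")
})

test_that("intervention window matches a dense-grid search", {
  p <- default_ci_params()
  w <- intervention_window(p, age_range = c(31, 70), step = 0.25)
  dense <- seq(31, 70, by = 1e-4)
  z <- classify_ci(dense, ci_from_age(dense, p), warn_implausible = FALSE)
  onset_ref <- dense[which(z != "Safe")[1]]
  unsafe_ref <- dense[which(z == "Unsafe")[1]]
  expect_lt(abs(w$onset_age - onset_ref), 1e-3)
  expect_lt(abs(w$unsafe_age - unsafe_ref), 1e-3)
  expect_equal(unname(w$window), c(w$onset_age, w$unsafe_age))
  # trajectory that never leaves Safe: empty window
  flat <- ci_params(0.1, 0, rep(0, 4), rep(1, 4), rep(0, 4))
  wf <- intervention_window(flat, age_range = c(31, 70))
  expect_true(is.na(wf$onset_age) && is.null(wf$window))
  # already Unsafe at range start: onset = unsafe = start, empty window
  hot <- ci_params(20, 0, rep(0, 4), rep(1, 4), rep(0, 4))
  wh <- intervention_window(hot, age_range = c(31, 70))
  expect_equal(wh$onset_age, 31)
  expect_equal(wh$unsafe_age, 31)
  expect_null(wh$window)
  expect_error(intervention_window(p, age_range = c(31, 70), step = 0),
               "step > 0")
})
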