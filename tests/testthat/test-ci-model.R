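test_that("biomarker_term and ci_from_age match independent evaluation", {
  expect_equal(biomarker_term(0, 2, 0.05), 2)
  expect_equal(biomarker_term(10, 2, 0.05), 2 * exp(-0.5), tolerance = 1e-9)
  expect_equal(biomarker_term(c(1, 50), 3, 0), c(3, 3))

  # pure age term when all weights vanish
  p0 <- ci_params(1.2, 0.03, w = rep(0, 4), k = 1:4, m = rep(0.1, 4))
  expect_equal(ci_from_age(c(30, 60), p0), 1.2 * exp(0.03 * c(30, 60)))
  # constants sum
  pc <- ci_params(1, 0, w = c(1, 0, 0, 0), k = c(1, 1, 1, 1),
                  m = rep(0, 4))
  expect_equal(ci_from_age(c(10, 99), pc), c(2, 2))
  # four-term expression, summed independently term by term
  p <- ci_params(0.5, 0.02,
                 w = c(-0.001, 0.1, 0.005, 0.2),
                 k = c(480, 5, 300, 2),
                 m = c(0.01, -0.02, 0.005, -0.01))
  a <- 40
  hand <- 0.5 * exp(0.02 * a) +
    (-0.001) * 480 * exp(-0.01 * a) +
    0.1 * 5 * exp(0.02 * a) +
    0.005 * 300 * exp(-0.005 * a) +
    0.2 * 2 * exp(0.01 * a)
  expect_equal(ci_from_age(a, p), hand, tolerance = 1e-12)
})

test_that("observation-based CI is linear in biomarkers and consistent with the model form", {
  p <- default_ci_params()
  rec <- data.frame(Age = 45, CSF_Ab42 = 12, Amyloid_PET = 6,
                    CSF_Tau = 5, MRI_FDG_PET = 4)
  # all-zero weights reduce to the age term
  p0 <- ci_params(p$alpha, p$beta, rep(0, 4), p$terms$k, p$terms$m)
  expect_equal(ci_from_observation(rec, p0), ci_from_age(45, p0))
  # doubling a positively weighted biomarker raises CI by exactly w * value
  rec2 <- rec; rec2$Amyloid_PET <- 12
  w2 <- p$terms$w[p$terms$biomarker == "Amyloid_PET"]
  expect_equal(ci_from_observation(rec2, p) - ci_from_observation(rec, p),
               w2 * 6)
  # protective direction: raising Ab42 strictly lowers CI (w1 < 0)
  rec3 <- rec; rec3$CSF_Ab42 <- 20
  expect_lt(ci_from_observation(rec3, p), ci_from_observation(rec, p))
  # consistency: measured values on their model trajectories reproduce
  # ci_from_age exactly
  ages <- c(35, 50, 65)
  on_model <- data.frame(
    Age = ages,
    CSF_Ab42 = biomarker_term(ages, p$terms$k[1], p$terms$m[1]),
    Amyloid_PET = biomarker_term(ages, p$terms$k[2], p$terms$m[2]),
    CSF_Tau = biomarker_term(ages, p$terms$k[3], p$terms$m[3]),
    MRI_FDG_PET = biomarker_term(ages, p$terms$k[4], p$terms$m[4]))
  expect_equal(ci_from_observation(on_model, p), ci_from_age(ages, p),
               tolerance = 1e-12)
})

test_that("ci_from_age is monotone in age under the documented sign pattern", {
  # beta > 0, protective Ab42 decaying (w1 < 0, m1 > 0), others rising
  p <- default_ci_params()
  ages <- seq(30, 70, by = 0.5)
  expect_true(all(diff(ci_from_age(ages, p)) > 0))
})

test_that("trajectory fitting recovers exponential parameters", {
  a <- seq(5, 60, by = 5)
  fit <- fit_trajectory_params(a, 3 * exp(-0.1 * a))
  expect_equal(fit$k, 3, tolerance = 1e-9)
  expect_equal(fit$m, 0.1, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)
  # constant data: k = c, m = 0
  cfit <- fit_trajectory_params(a, rep(4.2, length(a)))
  expect_equal(cfit$k, 4.2, tolerance = 1e-12)
  expect_equal(cfit$m, 0, tolerance = 1e-12)
  # 2% multiplicative noise, n = 50: within 5% of truth
  set.seed(31)
  ages <- seq_len(50)
  noisy <- 3 * exp(-0.1 * ages) * (1 + rnorm(50, 0, 0.02))
  nfit <- fit_trajectory_params(ages, noisy)
  expect_lt(abs(nfit$k - 3) / 3, 0.05)
  expect_lt(abs(nfit$m - 0.1) / 0.1, 0.05)
  expect_error(fit_trajectory_params(a, c(-1, rep(1, length(a) - 1))),
               "finite and > 0")
  expect_error(fit_trajectory_params(c(10, 10), c(1, 2)), "distinct ages")
})

test_that("calibration is optimal, order-invariant and unique under ridge", {
  set.seed(17)
  n <- 40
  df <- data.frame(Age = runif(n, 31, 69),
                   CSF_Ab42 = runif(n, 5, 22),
                   Amyloid_PET = runif(n, 2, 18),
                   CSF_Tau = runif(n, 2, 15),
                   MRI_FDG_PET = runif(n, 1, 12))
  truth <- ci_params(0.4, 0.03, w = c(-0.05, 0.2, 0.1, 0.15),
                     k = rep(1, 4), m = rep(0, 4))
  co <- cohort_table(df)
  y <- ci_from_observation(co, truth)
  fit <- calibrate_ci_params(co, y, ridge = 1e-10)
  sse <- function(p) sum((ci_from_observation(co, p) - y)^2)
  expect_lte(sse(fit), sse(truth) + 1e-8)        # optimality certificate
  # record order invariance: shuffled input rows resort by age inside
  # cohort_table, so the age-aligned targets pair up identically
  perm <- sample(n)
  fit3 <- calibrate_ci_params(cohort_table(df[perm, ]), y, ridge = 1e-10)
  expect_equal(fit3$terms$w, fit$terms$w, tolerance = 1e-6)
  expect_equal(fit3$alpha, fit$alpha, tolerance = 1e-6)
  # a single record with ridge > 0 still has a unique solution
  one <- calibrate_ci_params(cohort_table(df[1, ]), y[1], ridge = 1e-3)
  expect_s3_class(one, "ci_params")
  expect_error(calibrate_ci_params(cohort_table(df[1, ]), y[1], ridge = 0),
               "singular")
})

test_that("calibrating on the bundled example reproduces its eight zone labels", {
  ex <- example_with_zones()
  ex <- ex[order(ex$Age), ]
  fit <- calibrate_ci_params(cohort_table(ex[c("Age", biomarker_names())]),
                             ex$CI)
  ci_hat <- ci_from_observation(ex, fit)
  expect_identical(classify_ci(ex$Age, ci_hat), ex$zone)
})
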