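#' Cognitive-impairment model parameters
#'
#' Parameters of the composite cognitive-impairment score
#' \deqn{CI(A) = \alpha e^{\beta A} + \sum_{i=1}^4 w_i k_i e^{-m_i A},}
#' an age-scaled exponential plus a weighted sum of exponential biomarker
#' terms in the fixed order CSF amyloid-beta 42, amyloid PET, CSF Tau,
#' MRI FDG-PET.  Each term `k_i e^{-m_i A}` models that biomarker's age
#' trajectory; negative `m_i` yields a rising trajectory (PET, Tau,
#' FDG-PET), positive `m_i` a falling one (Ab42).  The protective effect of
#' amyloid-beta 42 is encoded through a negative weight `w_1`.
#'
#' @param alpha Non-negative CI scale factor.
#' @param beta Age rate (1/years) of the exponential ageing term.
#' @param w,k,m Numeric vectors of length 4 (weights, amplitudes, rates),
#'   in biomarker order; optionally named by biomarker.
#' @return An object of class `ci_params` with elements `alpha`, `beta`
#'   and a `terms` data frame (`biomarker`, `w`, `k`, `m`).
#' @export
#' @examples
#' p <- default_ci_params()
#' ci_from_age(c(35, 50, 65), p)
ci_params <- function(alpha, beta, w, k, m) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            alpha >= 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            length(w) == 4L, length(k) == 4L, length(m) == 4L,
            all(is.finite(c(w, k, m))))
  reorder4 <- function(v) {
    if (!is.null(names(v)) && setequal(names(v), biomarker_names()))
      v <- v[biomarker_names()]
    unname(v)
  }
  structure(list(alpha = alpha, beta = beta,
                 terms = data.frame(biomarker = biomarker_names(),
                                    w = reorder4(w), k = reorder4(k),
                                    m = reorder4(m))),
            class = "ci_params")
}

#' @export
print.ci_params <- function(x, ...) {
  cat(sprintf("<ci_params> alpha = %g, beta = %g\n", x$alpha, x$beta))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Illustrative default CI parameters
#'
#' A visibly non-canonical default set whose CI output over ages 30--60
#' stays inside the display range (0--14) of the default age bands: the
#' ageing term dominates, amyloid-beta 42 contributes protectively
#' (`w < 0`, decaying trajectory) and the other three biomarkers rise.
#' Supply calibrated parameters (see [calibrate_ci_params()]) for any
#' scientific use.
#'
#' @return A [ci_params()] object.
#' @export
default_ci_params <- function() {
  ci_params(alpha = 0.5, beta = 0.04,
            w = c(CSF_Ab42 = -0.02, Amyloid_PET = 0.05,
                  CSF_Tau = 0.05, MRI_FDG_PET = 0.05),
            k = c(22, 2, 1.5, 1),
            m = c(0.01, -0.03, -0.03, -0.03))
}

as_ci_params <- function(p) {
  if (inherits(p, "ci_params")) return(p)
  ci_params(p$alpha, p$beta, p$terms$w, p$terms$k, p$terms$m)
}

#' Exponential biomarker term
#'
#' Evaluates \eqn{B(A) = k e^{-m A}}, the modeled trajectory of one
#' biomarker at age `A`.
#'
#' @param age Numeric vector of ages (years).
#' @param k Amplitude (biomarker units, the value at age 0).
#' @param m Rate (1/years); negative for biomarkers that rise with age.
#' @return Numeric vector.
#' @export
biomarker_term <- function(age, k, m) {
  k * exp(-m * age)
}

#' Model-based cognitive-impairment score
#'
#' Evaluates the CI model at given ages with every biomarker on its
#' modeled trajectory: \eqn{\alpha e^{\beta A} + \sum_i w_i k_i e^{-m_i A}}.
#'
#' @param age Numeric vector of ages (years).
#' @param params A [ci_params()] object.
#' @return Numeric vector of CI scores.
#' @export
ci_from_age <- function(age, params) {
  params <- as_ci_params(params)
  out <- params$alpha * exp(params$beta * age)
  for (i in seq_len(4L)) {
    t <- params$terms[i, ]
    out <- out + t$w * biomarker_term(age, t$k, t$m)
  }
  out
}

#' Observation-based cognitive-impairment score
#'
#' Scores measured records by substituting each observed biomarker value
#' for its modeled trajectory term:
#' \eqn{\alpha e^{\beta A} + \sum_i w_i x_i}, linear in each biomarker at
#' fixed age.  When every measured value equals its modeled trajectory
#' \eqn{k_i e^{-m_i A}}, this reduces exactly to [ci_from_age()].
#'
#' @param record A [cohort_table()] or data frame with the canonical
#'   columns; scored row-wise.
#' @param params A [ci_params()] object.
#' @return Numeric vector of CI scores, one per record.
#' @export
ci_from_observation <- function(record, params) {
  params <- as_ci_params(params)
  df <- as.data.frame(record)
  x <- as.matrix(df[biomarker_names()])
  drop(params$alpha * exp(params$beta * df$Age) + x %*% params$terms$w)
}

#' Fit an exponential trajectory to (age, value) data
#'
#' Log-linear least squares fit of `value = k * exp(-m * age)`: regresses
#' `log(value)` on age and back-transforms.  Exact on noiseless
#' exponential data.
#'
#' @param ages Numeric vector (at least two distinct ages).
#' @param values Strictly positive numeric vector, same length.
#' @return List with `k`, `m` and `rmse` (root-mean-square error on the
#'   original scale).
#' @export
#' @examples
#' a <- 1:20
#' fit_trajectory_params(a, 3 * exp(-0.1 * a))
fit_trajectory_params <- function(ages, values) {
  stopifnot(length(ages) == length(values), length(ages) >= 2L)
  if (any(!is.finite(values) | values <= 0))
    stop("all values must be finite and > 0 (log-linear fit)")
  if (length(unique(ages)) < 2L)
    stop("need at least two distinct ages")
  fit <- stats::lm(log(values) ~ ages)
  k <- exp(unname(stats::coef(fit)[1L]))
  m <- -unname(stats::coef(fit)[2L])
  pred <- biomarker_term(ages, k, m)
  list(k = k, m = m, rmse = sqrt(mean((pred - values)^2)))
}

#' Calibrate CI parameters against target scores
#'
#' Fits `alpha`, `beta` and the four weights of the observation-based CI
#' score to a cohort with known target CI values by penalised least
#' squares: `beta` is profiled over a fixed grid, and at each `beta` the
#' linear coefficients `(alpha, w)` solve the ridge system
#' \eqn{(X'X + \lambda I)\theta = X'y}.  The ridge penalty makes the fit
#' unique even when the cohort is smaller than the parameter count.  A
#' negative fitted `alpha` is reset to 0 and the weights refit (the CI
#' scale factor is non-negative by definition).  The returned parameters
#' carry unit trajectory terms (`k = 1`, `m = 0`): calibration from
#' cross-sectional data identifies the weights, not the per-biomarker age
#' trajectories, so the result is intended for [ci_from_observation()].
#'
#' @param cohort A [cohort_table()].  Note cohort tables are sorted by
#'   age, so `target_ci` must be aligned with that (sorted) row order.
#' @param target_ci Numeric vector of target CI scores, one per record.
#' @param ridge Non-negative penalty (default `1e-3`).
#' @param beta_grid Candidate `beta` values (default `seq(0, 0.1, 0.001)`).
#' @return A [ci_params()] object.
#' @export
calibrate_ci_params <- function(cohort, target_ci, ridge = 1e-3,
                                beta_grid = seq(0, 0.1, by = 0.001)) {
  df <- as.data.frame(cohort)
  stopifnot(nrow(df) == length(target_ci), nrow(df) >= 1L, ridge >= 0)
  x <- as.matrix(df[biomarker_names()])
  y <- as.numeric(target_ci)
  age <- df$Age
  best <- NULL
  for (beta in beta_grid) {
    design <- cbind(exp(beta * age), x)
    theta <- tryCatch(
      solve(crossprod(design) + ridge * diag(5L), crossprod(design, y)),
      error = function(e) stop("singular design; use ridge > 0", call. = FALSE))
    loss <- sum((design %*% theta - y)^2) +
      ridge * (sum(theta^2) + beta^2)
    if (is.null(best) || loss < best$loss)
      best <- list(beta = beta, theta = drop(theta), loss = loss)
  }
  alpha <- best$theta[1L]
  w <- best$theta[-1L]
  if (alpha < 0) {            # refit with the ageing term removed
    alpha <- 0
    w <- drop(tryCatch(
      solve(crossprod(x) + ridge * diag(4L), crossprod(x, y)),
      error = function(e) stop("singular design; use ridge > 0", call. = FALSE)))
  }
  ci_params(alpha = alpha, beta = best$beta, w = w,
            k = rep(1, 4), m = rep(0, 4))
}
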