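#' Sigmoid trajectory parameters
#'
#' Parameters of the logistic curve \eqn{S(x) = L / (1 + e^{k (x - x_0)})}
#' used to model a biomarker's age trajectory.  `L` is the curve's maximum
#' (same units as the biomarker), `k` a scaling rate (1/units of `x`), and
#' `x0` the reference point where \eqn{S(x_0) = L/2}.
#'
#' Note the sign convention: as written, the curve is *decreasing* in `x`
#' when `k > 0` and *increasing* when `k < 0`.  Rising trajectories
#' (amyloid PET, CSF Tau, FDG-PET) therefore use negative `k`.
#'
#' @param L Positive curve maximum.
#' @param k Finite scaling rate; sign selects direction (see above).
#' @param x0 Finite reference point (here: an age, in years).
#' @return An object of class `sigmoid_params`.
#' @export
#' @examples
#' p <- sigmoid_params(L = 22, k = 0.08, x0 = 55)
#' sigmoid(c(30, 55, 80), p)
sigmoid_params <- function(L, k, x0) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0,
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(x0), length(x0) == 1L, is.finite(x0))
  structure(list(L = L, k = k, x0 = x0), class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("<sigmoid_params> L = %g, k = %g, x0 = %g (%s in x)\n",
              x$L, x$k, x$x0,
              if (x$k > 0) "decreasing" else if (x$k < 0) "increasing"
              else "constant"))
  invisible(x)
}

as_sigmoid_params <- function(p) {
  if (inherits(p, "sigmoid_params")) return(p)
  sigmoid_params(p$L, p$k, p$x0)
}

#' Evaluate the sigmoid trajectory
#'
#' Computes \eqn{S(x) = L / (1 + e^{k (x - x_0)})}, vectorised over `x`.
#' For arguments where \eqn{k (x - x_0)} overflows `exp()`, the exact
#' asymptote (`0` or `L`) is returned.
#'
#' @param x Numeric vector of evaluation points (ages, in years, when used
#'   for trajectory simulation).
#' @param params A [sigmoid_params()] object.
#' @return Numeric vector of the same length as `x`, within `[0, L]`.
#' @export
sigmoid <- function(x, params) {
  params <- as_sigmoid_params(params)
  z <- params$k * (x - params$x0)
  # exp() saturates cleanly: exp(>709) = Inf -> S = 0; exp(<-745) = 0 -> S = L
  params$L / (1 + exp(z))
}

#' Derivative of the sigmoid trajectory
#'
#' Closed-form derivative \eqn{S'(x) = -k\,S(x)\,(1 - S(x)/L)} of the curve
#' in [sigmoid()], used to locate the steepest part of a biomarker's
#' trajectory (its inflection at `x0`).
#'
#' @inheritParams sigmoid
#' @return Numeric vector of derivatives.
#' @export
sigmoid_derivative <- function(x, params) {
  params <- as_sigmoid_params(params)
  s <- sigmoid(x, params)
  -params$k * s * (1 - s / params$L)
}

#' Noise specification for trajectory simulation
#'
#' @param kind One of `"none"`, `"additive"` (Gaussian, `sd` in value units)
#'   or `"multiplicative"` (Gaussian relative error; `sd` is a fraction).
#' @param sd Non-negative noise scale.
#' @param seed Optional integer seed; when supplied, draws are taken from a
#'   local RNG stream so the surrounding session RNG state is untouched.
#' @return An object of class `noise_spec`.
#' @export
#' @examples
#' noise_spec("additive", sd = 0.5, seed = 1)
noise_spec <- function(kind = c("none", "additive", "multiplicative"),
                       sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sd), length(sd) == 1L, is.finite(sd), sd >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_spec")
}

as_noise_spec <- function(x) {
  if (inherits(x, "noise_spec")) return(x)
  noise_spec(x$kind %||% "none", x$sd %||% 0, x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

noise_draw <- function(n, noise) {
  if (is.null(noise$seed)) {
    stats::rnorm(n, 0, noise$sd)
  } else {
    withr::with_seed(as.integer(noise$seed), stats::rnorm(n, 0, noise$sd))
  }
}

#' Simulate a biomarker trajectory over a set of ages
#'
#' Evaluates the sigmoid curve at each age and perturbs it according to a
#' [noise_spec()].  Values are floored at 0 (biomarker measurements are
#' non-negative).  With `kind = "none"` the output equals `sigmoid(ages)`
#' exactly; with a fixed `seed` the output is reproducible.
#'
#' @param ages Non-empty numeric vector of ages (years).
#' @param params A [sigmoid_params()] object.
#' @param noise A [noise_spec()]; default no noise.
#' @return Numeric vector of simulated values, one per age.
#' @export
#' @examples
#' p <- sigmoid_params(20, -0.07, 50)
#' simulate_trajectory(30:40, p, noise_spec("additive", 0.5, seed = 7))
simulate_trajectory <- function(ages, params, noise = noise_spec("none")) {
  stopifnot(length(ages) >= 1L)
  noise <- as_noise_spec(noise)
  mu <- sigmoid(ages, params)
  if (noise$kind == "none" || noise$sd == 0) return(mu)
  eps <- noise_draw(length(ages), noise)
  out <- switch(noise$kind,
                additive = mu + eps,
                multiplicative = mu * (1 + eps))
  pmax(out, 0)
}
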