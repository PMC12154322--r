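#' Default run configuration
#'
#' A fully populated configuration for [run_pipeline()]: per-biomarker
#' sigmoid parameters, CI model parameters, the age-band registry,
#' threshold templates, noise spec, generator settings, the root seed and
#' artifact paths.  Serialisable to YAML with [save_config()].
#'
#' @return A named list of class `run_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
default_config <- function() {
  bands <- default_age_bands()
  thr <- default_threshold_tables()
  ci <- default_ci_params()
  structure(list(
    seed = 20260928L,
    simulate = list(n_per_age = 5, age_range = c(31, 60)),
    noise = list(kind = "additive", sd = 0.5),
    tau_coupling = -0.5,
    sigmoid = lapply(default_sigmoid_params(), function(p)
      list(L = p$L, k = p$k, x0 = p$x0)),
    ci = list(alpha = ci$alpha, beta = ci$beta,
              terms = stats::setNames(lapply(seq_len(4L), function(i)
                list(w = ci$terms$w[i], k = ci$terms$k[i],
                     m = ci$terms$m[i])), ci$terms$biomarker)),
    bands = lapply(seq_len(nrow(bands)), function(i) as.list(bands[i, ])),
    thresholds = lapply(thr, function(t)
      list(lower = t$lower, upper = t$upper,
           rows = stats::setNames(lapply(seq_len(nrow(t$rows)), function(i)
             as.list(t$rows[i, setdiff(names(t$rows), "biomarker")])),
             t$rows$biomarker))),
    window = list(age_range = c(31, 70), step = 0.25),
    paths = list(input = NULL, out_dir = ".")
  ), class = "run_config")
}

config_keys <- function() {
  c("seed", "simulate", "noise", "tau_coupling", "sigmoid", "ci",
    "bands", "thresholds", "window", "paths")
}

#' Validate a run configuration
#'
#' Checks that only known top-level keys are present, that all required
#' sections exist, and that every section converts into its validated
#' object (sigmoid/CI parameters, band registry, threshold tables).
#' Numeric leaves are coerced to double so a load/save round trip is
#' stable.
#'
#' @param config A list as produced by [default_config()] or
#'   [load_config()].
#' @return The validated config (class `run_config`), invisibly usable
#'   downstream.
#' @export
validate_config <- function(config) {
  config <- unclass(config)
  unknown <- setdiff(names(config), config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing_keys <- setdiff(config_keys(), names(config))
  if (length(missing_keys))
    stop("missing config key(s): ", paste(missing_keys, collapse = ", "))
  config$seed <- as.integer(config$seed)
  config$tau_coupling <- as.numeric(config$tau_coupling)
  config$simulate$n_per_age <- as.numeric(config$simulate$n_per_age)
  config$simulate$age_range <- as.numeric(config$simulate$age_range)
  config$noise$sd <- as.numeric(config$noise$sd)
  config$window$age_range <- as.numeric(config$window$age_range)
  config$window$step <- as.numeric(config$window$step)
  numify <- function(x) if (is.list(x)) lapply(x, numify) else
    if (is.numeric(x)) as.numeric(x) else x
  config$sigmoid <- numify(config$sigmoid)
  config$ci <- numify(config$ci)
  config$bands <- numify(config$bands)
  config$thresholds <- lapply(config$thresholds, function(t) {
    t$lower <- as.numeric(t$lower); t$upper <- as.numeric(t$upper)
    t$rows <- lapply(t$rows, function(r) {
      r[setdiff(names(r), "direction")] <-
        lapply(r[setdiff(names(r), "direction")], as.numeric)
      r
    })
    t
  })
  # conversion doubles as validation
  config_sigmoid_params(config)
  config_ci_params(config)
  config_bands(config)
  config_thresholds(config)
  noise_spec(config$noise$kind, config$noise$sd)
  structure(config, class = "run_config")
}

config_sigmoid_params <- function(config) {
  lapply(config$sigmoid, function(p) sigmoid_params(p$L, p$k, p$x0))
}

config_ci_params <- function(config) {
  terms <- config$ci$terms[biomarker_names()]
  ci_params(alpha = config$ci$alpha, beta = config$ci$beta,
            w = vapply(terms, `[[`, numeric(1L), "w"),
            k = vapply(terms, `[[`, numeric(1L), "k"),
            m = vapply(terms, `[[`, numeric(1L), "m"))
}

config_bands <- function(config) {
  age_band_registry(do.call(rbind, lapply(config$bands, as.data.frame)))
}

config_thresholds <- function(config) {
  lapply(config$thresholds, function(t) {
    rows <- do.call(rbind, lapply(names(t$rows), function(bm)
      cbind(data.frame(biomarker = bm), as.data.frame(t$rows[[bm]]))))
    threshold_table(t$lower, t$upper, rows)
  })
}

config_noise <- function(config, seed = NULL) {
  noise_spec(config$noise$kind, config$noise$sd, seed)
}

#' Load / save a run configuration (YAML)
#'
#' `load_config()` reads and validates a YAML configuration;
#' `save_config()` writes one.  A load/save/load round trip yields an
#' identical configuration.
#'
#' @param path YAML file path.
#' @param config A validated config list.
#' @return `load_config()`: a `run_config`; `save_config()`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_config(config)), path)
  invisible(path)
}
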