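#' @importFrom rlang .data abort warn %||%
#' @importFrom stats plogis pnorm qnorm rbinom rlnorm rnorm runif setNames
#' @importFrom utils modifyList
NULL

# Registry of every tunable scalar input: base value, sensitivity range,
# sampling distribution for probabilistic sensitivity analysis (PSA), and a
# coarse type used for validation.  `check_range` is FALSE for the utility
# rows whose published sensitivity ranges do not bracket the base value;
# both are stored verbatim and are not reconciled.
parameter_registry <- function() {
  tribble_names <- c("name", "base", "low", "high", "dist", "type", "check_range")
  rows <- list(
    # relative risks of fracture under treatment
    list("rr_risedronate_hip",        0.72, 0.58, 0.88, "log_normal", "rr", TRUE),
    list("rr_risedronate_vertebral",  0.58, 0.50, 0.67, "log_normal", "rr", TRUE),
    list("rr_risedronate_wrist",      0.82, 0.74, 0.90, "log_normal", "rr", TRUE),
    list("rr_vitd_calcium",           0.88, 0.83, 0.95, "log_normal", "rr", TRUE),
    list("rr_physical_activity_hip",  0.62, 0.54, 0.69, "log_normal", "rr", TRUE),
    # excess mortality after fracture
    list("rr_death_hip",              4.31, NA,   NA,   "fixed", "rr", TRUE),
    list("rr_death_vertebral",        2.85, NA,   NA,   "fixed", "rr", TRUE),
    # care pathways and the post-fracture cascade
    list("p_investigation",           0.21, 0.017, 0.50, "uniform", "prob", TRUE),
    list("p_treat_osteoporosis",      0.756, NA,  NA,   "fixed", "prob", TRUE),
    list("p_treat_low_bmd",           0.294, NA,  NA,   "fixed", "prob", TRUE),
    list("p_treat_normal_bmd",        0.09,  NA,  NA,   "fixed", "prob", TRUE),
    list("p_compliance",              0.49, 0.30, 0.75, "uniform", "prob", TRUE),
    list("p_participation",           0.531, 0.30, 0.70, "uniform", "prob", TRUE),
    list("p_hip_rehab",               0.48, NA,   NA,   "fixed", "prob", TRUE),
    list("p_hip_ltc",                 0.20, 0.10, 0.282, "uniform", "prob", TRUE),
    list("p_hip_followup",            0.80, NA,   NA,   "fixed", "prob", TRUE),
    list("p_wrist_surgery",           0.18, NA,   NA,   "fixed", "prob", TRUE),
    list("p_vertebral_hosp",          0.10, NA,   NA,   "fixed", "prob", TRUE),
    # prescreening questionnaires
    list("sens_ost",                  0.768, 0.70, 0.95, "uniform", "prob", TRUE),
    list("spec_ost",                  0.514, 0.30, 0.70, "uniform", "prob", TRUE),
    list("sens_score",                0.90, 0.80, 1.00, "uniform", "prob", TRUE),
    list("spec_score",                0.32, 0.20, 0.50, "uniform", "prob", TRUE),
    list("sens_orai",                 0.933, 0.85, 1.00, "uniform", "prob", TRUE),
    list("spec_orai",                 0.464, 0.30, 0.80, "uniform", "prob", TRUE),
    # health-state utilities (HUI3-derived point values)
    list("u_baseline",                1.00, NA,   NA,   "fixed", "utility", TRUE),
    list("u_hip_hosp",                0.30, 0.51, 0.60, "uniform", "utility", FALSE),
    list("u_hip_rehab",               0.56, 0.63, 0.70, "uniform", "utility", FALSE),
    list("u_hip_post",                0.85, 0.73, 0.90, "uniform", "utility", TRUE),
    list("u_vert_hosp",               0.33, NA,   NA,   "fixed", "utility", TRUE),
    list("u_vert_rehab",              0.68, NA,   NA,   "fixed", "utility", TRUE),
    list("u_vert_post",               0.85, 0.76, 0.90, "uniform", "utility", TRUE),
    list("u_wrist_er",                0.61, NA,   NA,   "fixed", "utility", TRUE),
    list("u_wrist_rehab",             0.88, NA,   NA,   "fixed", "utility", TRUE),
    list("u_wrist_post",              1.00, 0.82, 1.00, "uniform", "utility", TRUE),
    # within-cycle phase durations (days)
    list("d_hip_hosp",                14, NA, NA, "fixed", "days", TRUE),
    list("d_hip_rehab",               30, NA, NA, "fixed", "days", TRUE),
    list("d_vert_hosp",               9,  NA, NA, "fixed", "days", TRUE),
    list("d_vert_rehab",              30, NA, NA, "fixed", "days", TRUE),
    list("d_wrist_er",                1,  NA, NA, "fixed", "days", TRUE),
    list("d_wrist_rehab",             30, NA, NA, "fixed", "days", TRUE),
    # unit costs, fiscal 2007-2008 $CAD, public-payer perspective
    list("c_hip_acute",               4070,  NA, NA, "fixed", "cost", TRUE),
    list("c_hip_hosp",                19760, 15808, 23712, "uniform", "cost", TRUE),
    list("c_hip_inpatient_visits",    229,   NA, NA, "fixed", "cost", TRUE),
    list("c_hip_rehab",               24639, NA, NA, "fixed", "cost", TRUE),
    list("c_ltc_year",                74646, NA, NA, "fixed", "cost", TRUE),
    list("c_hip_followup",            990,   NA, NA, "fixed", "cost", TRUE),
    list("c_vert_acute",              1004,  NA, NA, "fixed", "cost", TRUE),
    list("c_vert_hosp",               8047,  6261, 9891, "uniform", "cost", TRUE),
    list("c_vert_inpatient_visits",   146,   NA, NA, "fixed", "cost", TRUE),
    list("c_vert_followup",           550,   NA, NA, "fixed", "cost", TRUE),
    list("c_wrist_conservative",      1250,  NA, NA, "fixed", "cost", TRUE),
    list("c_wrist_surgery",           3839,  NA, NA, "fixed", "cost", TRUE),
    list("c_wrist_followup",          467,   NA, NA, "fixed", "cost", TRUE),
    list("c_screen_visit",            160,   NA, NA, "fixed", "cost", TRUE),
    list("c_dxa",                     107.5, NA, NA, "fixed", "cost", TRUE),
    list("c_vitd_annual",             160,   NA, NA, "fixed", "cost", TRUE),
    list("c_pa_annual",               5,     NA, NA, "fixed", "cost", TRUE),
    list("c_risedronate_annual",      162.25, NA, NA, "fixed", "cost", TRUE),
    list("c_followup_visit",          99.53, NA, NA, "fixed", "cost", TRUE),
    list("c_control_dxa",             98.5,  NA, NA, "fixed", "cost", TRUE),
    # discounting and schedule conventions
    list("discount_rate",             0.03, 0, 0.05, "fixed", "rate", TRUE),
    list("mortality_rr_window",       2, NA, NA, "fixed", "count", TRUE),
    list("dxa_interval",              2, NA, NA, "fixed", "count", TRUE),
    list("dxa_interval_low_risk",     5, NA, NA, "fixed", "count", TRUE)
  )
  out <- tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    stats::setNames(data.frame(r[[1]], as.numeric(r[[2]]), as.numeric(r[[3]]),
                               as.numeric(r[[4]]), r[[5]], r[[6]], r[[7]],
                               stringsAsFactors = FALSE), tribble_names)
  })))
  out
}

# Non-numeric run options carried alongside the numeric registry.
default_options <- function() {
  list(
    treatment_duration = "until_death", # one of until_death, 5y, 10y
    ltc_recurring = TRUE                # long-term-care cost recurs annually
  )
}

new_parameter_set <- function(values, options, provenance) {
  structure(c(values, options),
            meta = parameter_registry(),
            provenance = provenance,
            class = c("osteo_params", "list"))
}

#' Default model parameters
#'
#' Returns the full set of model inputs at their base-case values: treatment
#' relative risks, care-pathway and behavioural probabilities, prescreening
#' questionnaire sensitivity/specificity, health-state utilities and phase
#' durations, unit costs (fiscal 2007-2008 $CAD, public-payer perspective),
#' and the 3% annual discount rate.
#'
#' @return A `osteo_params` object: a named list of parameter values with a
#'   metadata table (base, sensitivity range, PSA distribution) retrievable
#'   via [tidy()].
#' @export
#' @examples
#' p <- default_parameters()
#' p$rr_risedronate_hip
default_parameters <- function() {
  reg <- parameter_registry()
  values <- as.list(stats::setNames(reg$base, reg$name))
  prov <- stats::setNames(rep("default", length(values) + 2),
                          c(names(values), names(default_options())))
  new_parameter_set(values, default_options(), prov)
}

#' Load parameters from a YAML configuration file
#'
#' Reads a flat YAML mapping of parameter overrides. Absent keys take their
#' default values; unknown keys and out-of-range values are rejected. The
#' provenance of every value (default vs override) is recorded.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file (same rules).
#' @return A validated `osteo_params` object.
#' @export
load_parameters <- function(path = NULL, overrides = list()) {
  params <- default_parameters()
  conf <- list()
  if (!is.null(path)) {
    conf <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) abort(paste0("failed to parse config '", path, "': ",
                                       conditionMessage(e)))
    )
    if (is.null(conf)) conf <- list()
  }
  conf <- modifyList(conf, overrides)
  if (length(conf)) {
    known <- setdiff(names(params), NULL)
    unknown <- setdiff(names(conf), known)
    if (length(unknown)) {
      abort(paste0("unknown parameter key(s): ", paste(unknown, collapse = ", ")))
    }
    prov <- attr(params, "provenance")
    for (nm in names(conf)) {
      params[[nm]] <- conf[[nm]]
      prov[nm] <- "override"
    }
    attr(params, "provenance") <- prov
  }
  validate_parameters(params)
  params
}

#' Write a parameter set to YAML
#'
#' Serialises the active parameter values (numeric inputs and run options) to
#' a flat YAML mapping; `load_parameters()` on the result reproduces the set.
#'
#' @param params A `osteo_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "osteo_params"))
  yaml::write_yaml(params[names(params)], path)
  invisible(path)
}

#' Validate a parameter set
#'
#' Checks type constraints (probabilities and utilities in \[0, 1\], relative
#' risks positive, costs non-negative, non-negative rates) and, where a
#' sensitivity range is declared as bracketing, that low <= base <= high.
#'
#' @param params A `osteo_params` object.
#' @return `params`, invisibly; aborts with the offending parameter named.
#' @export
validate_parameters <- function(params) {
  reg <- attr(params, "meta")
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("parameter '", nm, "' must be a single finite number"))
    }
    ok <- switch(reg$type[i],
      prob = , utility = v >= 0 && v <= 1,
      rr = v > 0,
      cost = , rate = , days = , count = v >= 0,
      TRUE)
    if (!ok) {
      bound <- switch(reg$type[i], prob = , utility = "[0, 1]",
                      rr = "(0, Inf)", "[0, Inf)")
      abort(paste0("parameter '", nm, "' = ", v, " outside ", bound))
    }
  }
  if (!params$treatment_duration %in% c("until_death", "5y", "10y")) {
    abort("treatment_duration must be one of until_death, 5y, 10y")
  }
  if (!is.logical(params$ltc_recurring)) {
    abort("ltc_recurring must be logical")
  }
  invisible(params)
}

treatment_duration_cycles <- function(params) {
  switch(params$treatment_duration,
         until_death = Inf, "5y" = 5, "10y" = 10)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Re-draws every parameter that carries a sensitivity range and a sampling
#' distribution: uniform-tagged parameters uniformly on \[low, high\];
#' log-normal-tagged relative risks from a log-normal with
#' `meanlog = log(base)` and `sdlog = (log(high) - log(low)) / (2 * 1.96)`,
#' i.e. the published range is read as a 95% CI and the base value is the
#' median. Fixed parameters are returned unchanged. Draws come from the
#' current RNG stream, so `set.seed()` fixes the whole draw.
#'
#' @param params A `osteo_params` object (the base-case set).
#' @return A new `osteo_params` object with the varied values replaced.
#' @export
#' @examples
#' set.seed(1)
#' sample_psa(default_parameters())$p_participation
sample_psa <- function(params) {
  reg <- attr(params, "meta")
  out <- params
  for (i in seq_len(nrow(reg))) {
    d <- reg$dist[i]
    if (d == "fixed") next
    nm <- reg$name[i]
    lo <- reg$low[i]; hi <- reg$high[i]
    if (is.na(lo) || is.na(hi)) {
      abort(paste0("parameter '", nm, "' is tagged '", d,
                   "' but has no sensitivity range"))
    }
    if (lo == hi) { out[[nm]] <- lo; next }
    out[[nm]] <- switch(d,
      uniform = runif(1, lo, hi),
      log_normal = rlnorm(1, meanlog = log(params[[nm]]),
                          sdlog = (log(hi) - log(lo)) / (2 * 1.96)),
      abort(paste0("unknown distribution tag '", d, "'")))
  }
  validate_parameters(out)
  out
}

#' @export
print.osteo_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  n_over <- sum(prov == "override")
  cat("<osteo_params> ", length(x), " inputs (",
      n_over, " overridden)\n", sep = "")
  cat("  discount rate: ", x$discount_rate,
      "; treatment duration: ", x$treatment_duration, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter set
#'
#' @param x A `osteo_params` object.
#' @param ... Unused.
#' @return A tibble with one row per numeric parameter: name, current value,
#'   base value, sensitivity range, PSA distribution, and provenance.
#' @export
tidy.osteo_params <- function(x, ...) {
  reg <- attr(x, "meta")
  prov <- attr(x, "provenance")
  dplyr::mutate(reg,
                value = unname(unlist(x[reg$name])),
                provenance = unname(prov[reg$name]),
                .after = "name")
}
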