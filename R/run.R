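#' Run the full strategy comparison end to end
#'
#' Generates a cohort, optionally calibrates the baseline hazards to the
#' lifetime-risk targets, runs every requested policy with common random
#' numbers (or a full PSA when `reps > 1`), ranks strategies on both effect
#' scales, and (optionally) writes the result tables, frontiers and manifest
#' to a directory.
#'
#' @param cohort_size Women at baseline.
#' @param policies Character vector of policy names, or `"all"`.
#' @param seed Master seed for all randomness.
#' @param reps Replications; 1 runs the base case, more runs a PSA.
#' @param params A `osteo_params` object.
#' @param tables Lookup tables; defaults to the shipped surfaces,
#'   calibrated when `calibrate = TRUE`.
#' @param calibrate Calibrate baseline hazards before simulating?
#' @param calibrate_n Women per calibration refinement run.
#' @param rolling_entry Add annual cohorts of 40-year-olds for 10 years?
#' @param annual_entry Entrants per year under rolling entry.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `osteo_analysis` list: `results` (all strata), `frontier_ce`,
#'   `frontier_cu` (whole-population frontiers), `psa` (when `reps > 1`),
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' an <- run_analysis(500, policies = c("Status quo", "Physical activity"),
#'                    seed = 42)
#' an$results
#' }
run_analysis <- function(cohort_size, policies = "all", seed = 1L, reps = 1L,
                         params = default_parameters(), tables = NULL,
                         calibrate = FALSE, calibrate_n = 20000L,
                         rolling_entry = FALSE, annual_entry = 0L,
                         out_dir = NULL) {
  if (identical(policies, "all")) policies <- policy_catalog()$name
  invisible(lapply(policies, policy))  # validate names early
  if (is.null(tables)) {
    if (calibrate) {
      cal <- calibrate_lifetime_risk(params = params,
                                     refine_n = calibrate_n,
                                     refine_seed = seed + 613L)
      tables <- model_tables(cal$hazards)
    } else {
      tables <- model_tables()
    }
  }
  spec <- cohort_spec(cohort_size, rolling_entry = rolling_entry,
                      annual_entry = annual_entry, seed = seed + 1L)
  psa <- NULL
  if (reps > 1L) {
    psa <- run_psa(policies, reps, spec, seed = seed, params = params,
                   tables = tables)
    results <- psa |>
      dplyr::group_by(.data$stratum, .data$policy) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                       .groups = "drop") |>
      dplyr::select(-"rep")
  } else {
    cohort <- generate_cohort(spec)
    results <- purrr::map_dfr(policies, function(pn) {
      sim <- run_lifetime(cohort, policy(pn), seed = seed + 2L,
                          params = params, tables = tables)
      aggregate_results(sim)
    })
  }
  all_res <- results[results$stratum == "all", ]
  frontier_ce <- if (nrow(all_res) > 1L) {
    rank_and_frontier(all_res, "fractures_averted")
  }
  frontier_cu <- if (nrow(all_res) > 1L) rank_and_frontier(all_res, "qalys")
  manifest <- list(
    seed = seed, cohort_size = cohort_size, policies = policies, reps = reps,
    discount_rate = params$discount_rate,
    rolling_entry = rolling_entry, annual_entry = annual_entry,
    calibrated = calibrate,
    parameter_hash = rlang::hash(params[names(params)]))
  out <- structure(list(results = results, frontier_ce = frontier_ce,
                        frontier_cu = frontier_cu, psa = psa,
                        manifest = manifest),
                   class = "osteo_analysis")
  if (!is.null(out_dir)) {
    write_results(results, frontier = frontier_ce, dir = out_dir,
                  manifest = manifest)
  }
  out
}

#' @export
print.osteo_analysis <- function(x, ...) {
  cat("<osteo_analysis> ", length(unique(x$results$policy)), " policies, ",
      x$manifest$cohort_size, " women, seed ", x$manifest$seed, "\n", sep = "")
  print(ce_table(x$results[x$results$stratum == "all", ]))
  invisible(x)
}
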