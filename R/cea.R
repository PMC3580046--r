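effect_value <- function(results, effect) {
  switch(effect,
         fractures_averted = -results$total_fractures,
         qalys = results$total_qalys,
         abort("effect must be 'fractures_averted' or 'qalys'"))
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' `(cost_b - cost_a) / (effect_b - effect_a)` where the effect is either
#' fractures averted (fewer total fractures = more effect) or QALYs.
#'
#' @param a,b One-row strategy results (as from [aggregate_results()]); `b`
#'   the more effective, more costly strategy.
#' @param effect `"fractures_averted"` or `"qalys"`.
#' @return The ratio; `NA` (with a warning) when the effect difference is 0.
#' @export
icer <- function(a, b, effect = "fractures_averted") {
  d_cost <- b$total_cost - a$total_cost
  d_eff <- effect_value(b, effect) - effect_value(a, effect)
  if (d_eff == 0) {
    warn("equal effects: incremental ratio undefined")
    return(NA_real_)
  }
  d_cost / d_eff
}

#' Cost-effectiveness frontier with strict and extended dominance
#'
#' Sorts strategies by cost (ties broken by effect, descending), removes
#' strictly dominated strategies (at least as costly and no more effective
#' than another, one strictly), then iteratively removes extended-dominated
#' strategies until incremental ratios strictly increase along the frontier.
#' The cheapest strategy anchors the frontier.
#'
#' @param results Tibble with one row per strategy: `policy`, `total_cost`,
#'   and `total_fractures` or `total_qalys`.
#' @param effect `"fractures_averted"` or `"qalys"`.
#' @return A `osteo_frontier` tibble: `policy`, `cost`, `effect`, `status`
#'   (`"frontier"`, `"dominated"`, `"extended"`), and along the frontier
#'   `inc_cost`, `inc_effect`, `icer`.
#' @export
rank_and_frontier <- function(results, effect = "fractures_averted") {
  d <- tibble::tibble(policy = results$policy,
                      cost = results$total_cost,
                      effect = effect_value(results, effect))
  if (anyDuplicated(d$policy)) abort("one result per strategy required")
  d <- d[order(d$cost, -d$effect), ]
  n <- nrow(d)
  status <- rep("frontier", n)
  for (i in seq_len(n)) {
    dom <- d$cost <= d$cost[i] & d$effect >= d$effect[i] &
      (d$cost < d$cost[i] | d$effect > d$effect[i])
    if (any(dom)) status[i] <- "dominated"
  }
  chain <- which(status == "frontier")
  repeat {
    if (length(chain) < 3L) break
    r <- diff(d$cost[chain]) / diff(d$effect[chain])
    bad <- which(diff(r) <= 0)
    if (!length(bad)) break
    status[chain[bad[1] + 1L]] <- "extended"
    chain <- chain[-(bad[1] + 1L)]
  }
  d$status <- status
  d$inc_cost <- NA_real_; d$inc_effect <- NA_real_; d$icer <- NA_real_
  if (length(chain) > 1L) {
    d$inc_cost[chain[-1]] <- diff(d$cost[chain])
    d$inc_effect[chain[-1]] <- diff(d$effect[chain])
    d$icer[chain[-1]] <- d$inc_cost[chain[-1]] / d$inc_effect[chain[-1]]
  }
  ic <- d$icer[chain[-1]]
  stopifnot(!is.unsorted(ic, strictly = TRUE))
  structure(d, effect_measure = effect,
            class = c("osteo_frontier", class(d)))
}

psa_rep_seed <- function(seed, r) (as.integer(seed) + 7919L * as.integer(r))

#' Probabilistic sensitivity analysis
#'
#' For each replicate: draw a parameter set from the PSA distributions,
#' generate a fresh cohort, and run every policy on it with a shared seed
#' (common random numbers across policies within a replicate). Fully
#' reproducible from `seed`.
#'
#' @param policies Character vector of policy names (or `"all"`).
#' @param n_reps Number of replicates.
#' @param spec A `osteo_cohort_spec` (its seed is re-derived per replicate).
#' @param seed Master seed.
#' @param params Base-case `osteo_params`.
#' @param tables Lookup tables from [model_tables()].
#' @return A `osteo_psa` tibble of strategy results with `rep` and `stratum`
#'   columns.
#' @export
run_psa <- function(policies, n_reps, spec, seed = 1L,
                    params = default_parameters(), tables = model_tables()) {
  if (n_reps < 1L) abort("n_reps must be at least 1")
  if (identical(policies, "all")) policies <- policy_catalog()$name
  out <- purrr::map_dfr(seq_len(n_reps), function(r) {
    rs <- psa_rep_seed(seed, r)
    set.seed(rs)
    rep_params <- if (n_reps > 1L) sample_psa(params) else params
    rep_spec <- spec
    rep_spec$seed <- rs + 1L
    cohort <- generate_cohort(rep_spec)
    purrr::map_dfr(policies, function(pname) {
      sim <- run_lifetime(cohort, policy(pname), seed = rs + 2L,
                          params = rep_params, tables = tables)
      dplyr::mutate(aggregate_results(sim), rep = r, .before = 1)
    })
  })
  structure(out, class = c("osteo_psa", class(out)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each ceiling ratio lambda, the probability across PSA replicates that
#' the strategy's incremental net monetary benefit against the comparator,
#' `lambda * delta_effect - delta_cost`, is positive (exact ties count 0.5).
#'
#' @param psa A `osteo_psa` from [run_psa()].
#' @param strategy,comparator Policy names to compare.
#' @param lambda Grid of ceiling ratios ($CAD per unit effect).
#' @param effect `"fractures_averted"` or `"qalys"`.
#' @param stratum Which stratum of the results to use (default `"all"`).
#' @return A `osteo_ceac` tibble: `lambda`, `probability`.
#' @export
acceptability <- function(psa, strategy, comparator,
                          lambda = seq(0, 150000, by = 2500),
                          effect = "fractures_averted", stratum = "all") {
  d <- psa[psa$stratum == stratum & psa$policy %in% c(strategy, comparator), ]
  wide <- tidyr::pivot_wider(
    d[, c("rep", "policy", "total_cost", "total_fractures", "total_qalys")],
    names_from = "policy",
    values_from = c("total_cost", "total_fractures", "total_qalys"))
  if (nrow(wide) < 2L) abort("at least 2 PSA replicates are required")
  d_cost <- wide[[paste0("total_cost_", strategy)]] -
    wide[[paste0("total_cost_", comparator)]]
  d_eff <- if (effect == "fractures_averted") {
    wide[[paste0("total_fractures_", comparator)]] -
      wide[[paste0("total_fractures_", strategy)]]
  } else {
    wide[[paste0("total_qalys_", strategy)]] -
      wide[[paste0("total_qalys_", comparator)]]
  }
  prob <- vapply(lambda, function(l) {
    nmb <- l * d_eff - d_cost
    mean(nmb > 0) + 0.5 * mean(nmb == 0)
  }, numeric(1))
  structure(tibble::tibble(lambda = lambda, probability = prob),
            strategy = strategy, comparator = comparator,
            effect_measure = effect,
            class = c("osteo_ceac", class(tibble::tibble())))
}

#' One-way sensitivity analysis of an incremental ratio
#'
#' Re-runs a pair of strategies with one parameter set to the bounds of its
#' published sensitivity range (shared seeds, so the comparison uses common
#' random numbers) and reports the incremental ratio of `strategy` against
#' `comparator` at the low, base and high values.
#'
#' @param param_name Registry name of the parameter to vary.
#' @param strategy,comparator Policy names.
#' @param spec A `osteo_cohort_spec`.
#' @param seed Seed shared by all runs.
#' @param params Base-case parameters.
#' @param tables Lookup tables.
#' @param effect `"fractures_averted"` or `"qalys"`.
#' @param stratum Stratum for the comparison.
#' @param vary_in `"both"` varies the parameter in both arms; `"strategy"`
#'   varies it only in the strategy under evaluation, holding the comparator
#'   at the base case (the usual reading for uptake-style parameters, where
#'   a joint rescaling leaves the incremental ratio unchanged by
#'   construction).
#' @return A tibble: `param`, `level`, `value`, `icer`.
#' @export
one_way_sa <- function(param_name, strategy, comparator, spec, seed = 1L,
                       params = default_parameters(),
                       tables = model_tables(),
                       effect = "fractures_averted", stratum = "all",
                       vary_in = c("both", "strategy")) {
  vary_in <- match.arg(vary_in)
  reg <- attr(params, "meta")
  row <- reg[reg$name == param_name, ]
  if (nrow(row) != 1L || is.na(row$low)) {
    abort(paste0("parameter '", param_name, "' has no sensitivity range"))
  }
  cohort <- generate_cohort(spec)
  run_pair <- function(value) {
    p <- params
    p[[param_name]] <- value
    arm_params <- list(p, p)
    if (vary_in == "strategy") arm_params[[1]] <- params
    res <- purrr::map2_dfr(c(comparator, strategy), arm_params,
                           function(pn, ap) {
      sim <- run_lifetime(cohort, policy(pn), seed = seed + 2L, params = ap,
                          tables = tables)
      aggregate_results(sim)
    })
    res <- res[res$stratum == stratum, ]
    icer(res[res$policy == comparator, ], res[res$policy == strategy, ],
         effect)
  }
  levels <- c(low = row$low, base = params[[param_name]], high = row$high)
  tibble::tibble(param = param_name, level = names(levels),
                 value = unname(levels),
                 icer = vapply(levels, run_pair, numeric(1)))
}

# Sequential-incremental presentation: strategies sorted by total cost, each
# compared with the immediately cheaper one (negative "averted" entries are
# possible for dominated options); the clean frontier is reported separately.
#' Cost-effectiveness and cost-utility result tables
#'
#' `ce_table()` lays out total costs, sequential incremental costs, total
#' fractures, fractures averted vs the immediately cheaper strategy, and the
#' resulting ICERs. `cu_table()` is the per-person analogue with QALYs and
#' ICURs.
#'
#' @param results Strategy results for one stratum (one row per policy).
#' @return A tibble sorted by ascending cost.
#' @export
ce_table <- function(results) {
  d <- results[order(results$total_cost), ]
  d$incremental_cost <- c(NA, diff(d$total_cost))
  d$fractures_averted <- c(NA, -diff(d$total_fractures))
  d$icer <- ifelse(!is.na(d$fractures_averted) & d$fractures_averted > 0,
                   d$incremental_cost / d$fractures_averted, NA_real_)
  d[, c("stratum", "policy", "n", "total_cost", "incremental_cost",
        "total_fractures", "fractures_averted", "icer")]
}

#' @rdname ce_table
#' @export
cu_table <- function(results) {
  d <- results[order(results$cost_per_person), ]
  d$incremental_cost_pp <- c(NA, diff(d$cost_per_person))
  d$incremental_qalys_pp <- c(NA, diff(d$qalys_per_person))
  d$icur <- ifelse(!is.na(d$incremental_qalys_pp) & d$incremental_qalys_pp > 0,
                   d$incremental_cost_pp / d$incremental_qalys_pp, NA_real_)
  d[, c("stratum", "policy", "n", "cost_per_person", "incremental_cost_pp",
        "qalys_per_person", "incremental_qalys_pp", "icur")]
}

#' Write run outputs to a directory
#'
#' Writes the per-stratum cost-effectiveness and cost-utility tables,
#' frontier, acceptability curves (CSV and, optionally, plots) and a JSON
#' run manifest (seed, parameter hash, package version) that suffices to
#' reproduce the run.
#'
#' @param results Strategy results (all strata stacked).
#' @param frontier Optional `osteo_frontier`.
#' @param curves Optional named list of `osteo_ceac` objects.
#' @param dir Output directory (created if absent).
#' @param manifest Named list of extra manifest fields (seed, spec, ...).
#' @param plots Also write acceptability plots as PNG?
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, frontier = NULL, curves = NULL, dir,
                          manifest = list(), plots = FALSE) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory '", dir, "'"))
  }
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p)
    paths <<- c(paths, p)
  }
  for (s in unique(results$stratum)) {
    rs <- results[results$stratum == s, ]
    tag <- gsub("[^0-9A-Za-z]+", "_", s)
    wr(ce_table(rs), paste0("cost_effectiveness_", tag, ".csv"))
    wr(cu_table(rs), paste0("cost_utility_", tag, ".csv"))
  }
  wr(results, "strategy_results.csv")
  if (!is.null(frontier)) wr(tibble::as_tibble(frontier), "frontier.csv")
  if (!is.null(curves)) {
    for (nm in names(curves)) {
      wr(tibble::as_tibble(curves[[nm]]), paste0("acceptability_", nm, ".csv"))
      if (plots) {
        p <- file.path(dir, paste0("acceptability_", nm, ".png"))
        ggplot2::ggsave(p, ggplot2::autoplot(curves[[nm]]),
                        width = 6, height = 4, dpi = 120)
        paths <- c(paths, p)
      }
    }
  }
  man <- c(list(package_version = as.character(utils::packageVersion("osteosim")),
                written = format(Sys.time(), tz = "UTC", usetz = TRUE)),
           manifest)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}
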