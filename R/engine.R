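# Vectorised annual-cycle engine.  All stochastic steps consume a fixed
# block of 12 uniforms per woman per cycle, drawn in id order for the whole
# population (dead rows included).  Because the block layout never depends
# on the policy, two runs with the same seed and the same cohort share fate
# streams woman-by-woman across policies (common random numbers).
N_DRAWS <- 12L
DRAW <- c(f_hip = 1L, f_vert = 2L, f_wrist = 3L, hip_rehab = 4L, hip_ltc = 5L,
          hip_fu = 6L, wrist_surg = 7L, vert_hosp = 8L, invest = 9L,
          treat = 10L, comply = 11L, death = 12L)

# Engine state columns appended to a freshly generated cohort.
init_state <- function(pop, entry_cycle = 0L) {
  n <- nrow(pop)
  dplyr::mutate(pop,
    n_hip = 0L, n_vert = 0L, n_wrist = 0L,
    last_hip_cycle = NA_integer_, last_vert_cycle = NA_integer_,
    on_risedronate = FALSE, ris_compliant = FALSE, ris_start = NA_integer_,
    pa_program = FALSE, vitd_program = FALSE,
    care_ltc = FALSE,
    screened = FALSE, screen_cycle = NA_integer_, risk_category = NA_character_,
    entry_cycle = as.integer(entry_cycle),
    cum_cost = 0, cum_cost_undisc = 0,
    cum_cost_fracture = 0, cum_cost_treatment = 0, cum_cost_screening = 0,
    cum_cost_followup = 0, cum_cost_ltc = 0,
    cum_qaly = 0, cum_ly = 0,
    died_cycle = NA_integer_)
}

#' Treatment effect on an annual fracture probability
#'
#' Applies the treatment relative risks multiplicatively to a baseline annual
#' fracture probability. Risedronate acts on all three sites (site-specific
#' RR), vitamin D + calcium on all sites, physical activity on the hip only.
#' When several preventive measures apply, the strongest single effect (the
#' minimum applicable RR) is used — never the product. Non-compliant women
#' receive no effect.
#'
#' @param base_p Baseline annual fracture probability (vectorised).
#' @param site One of `"hip"`, `"vertebral"`, `"wrist"`.
#' @param treatment One of `"none"`, `"risedronate"`, `"vitd_calcium"`,
#'   `"physical_activity"`, `"combined"` (vitamin D + calcium together with
#'   physical activity). Vectorised.
#' @param compliant Logical; non-compliant women keep `base_p`.
#' @param params A `osteo_params` object.
#' @return Adjusted probability, same length as the inputs.
#' @export
#' @examples
#' apply_treatment_effect(0.10, "hip", "risedronate", TRUE, default_parameters())
apply_treatment_effect <- function(base_p, site, treatment, compliant = TRUE,
                                   params = default_parameters()) {
  stopifnot(all(base_p >= 0 & base_p <= 1))
  site <- match.arg(site, SITES)
  known <- c("none", "risedronate", "vitd_calcium", "physical_activity",
             "combined")
  if (!all(treatment %in% known)) {
    abort(paste0("unknown treatment: ",
                 paste(setdiff(unique(treatment), known), collapse = ", ")))
  }
  rr_ris <- params[[paste0("rr_risedronate_", site)]]
  rr_pa <- if (site == "hip") params$rr_physical_activity_hip else 1
  rr <- dplyr::case_when(
    treatment == "risedronate" ~ rr_ris,
    treatment == "vitd_calcium" ~ params$rr_vitd_calcium,
    treatment == "physical_activity" ~ rr_pa,
    treatment == "combined" ~ pmin(params$rr_vitd_calcium, rr_pa),
    TRUE ~ 1
  )
  rr[!compliant] <- 1
  base_p * rr
}

# Minimum applicable RR for each woman given her current state flags.
state_rr <- function(pop, site, params) {
  rr <- rep(1, nrow(pop))
  ris <- pop$on_risedronate & pop$ris_compliant
  rr[ris] <- pmin(rr[ris], params[[paste0("rr_risedronate_", site)]])
  rr <- pmin(rr, ifelse(pop$takes_vitd_calcium, params$rr_vitd_calcium, 1))
  if (site == "hip") {
    rr <- pmin(rr, ifelse(pop$physically_active,
                          params$rr_physical_activity_hip, 1))
  }
  rr
}

#' Annual fracture probability for each woman
#'
#' Looks up the baseline hazard for the woman's current age and BMD category
#' and applies her current treatment effect (minimum applicable relative
#' risk). Returns 0 for the hip once a woman has had two hip fractures (both
#' are assumed to lead to hemiarthroplasty).
#'
#' @param pop Population tibble with engine state (see [run_lifetime()]); at
#'   minimum `age` and `t_score`.
#' @param site Fracture site.
#' @param params A `osteo_params` object.
#' @param tables Lookup tables from [model_tables()].
#' @return Numeric vector of probabilities.
#' @export
annual_fracture_probability <- function(pop, site,
                                        params = default_parameters(),
                                        tables = model_tables()) {
  site <- match.arg(site, SITES)
  if (any(pop$age < 40 | pop$age > MAX_AGE)) {
    abort("age outside the hazard table (40-110)")
  }
  cat_idx <- match(bmd_category(pop$t_score), BMD_CATEGORIES)
  p <- tables$hazard_arr[cbind(pop$age - 39L, cat_idx,
                               match(site, SITES))]
  p <- p * state_rr(pop, site, params)
  if (site == "hip" && "n_hip" %in% names(pop)) {
    p[pop$n_hip >= 2L] <- 0
  }
  p
}

#' Annual death probability for each woman
#'
#' Baseline life-table probability at the current age, multiplied by the
#' post-fracture excess-mortality relative risk when a hip (RR 4.31) or
#' clinical vertebral (RR 2.85) fracture occurred within the elevated-risk
#' window (the fracture cycle plus the following cycle by default; hip takes
#' precedence), capped at 1.
#'
#' @inheritParams annual_fracture_probability
#' @param cycle Current cycle index (used to test the elevated-risk window).
#' @return Numeric vector of probabilities.
#' @export
annual_death_probability <- function(pop, params = default_parameters(),
                                     tables = model_tables(), cycle = 0L) {
  q0 <- tables$q_death[pmin(pop$age, MAX_AGE) - 39L]
  w <- params$mortality_rr_window
  hip_win <- if ("last_hip_cycle" %in% names(pop)) {
    !is.na(pop$last_hip_cycle) & (cycle - pop$last_hip_cycle) < w
  } else rep(FALSE, nrow(pop))
  vert_win <- if ("last_vert_cycle" %in% names(pop)) {
    !is.na(pop$last_vert_cycle) & (cycle - pop$last_vert_cycle) < w
  } else rep(FALSE, nrow(pop))
  rr <- ifelse(hip_win, params$rr_death_hip,
               ifelse(vert_win, params$rr_death_vertebral, 1))
  pmin(1, q0 * rr)
}

#' Resolve the care pathway of an incident fracture
#'
#' For every woman in `pop`, assumed to have sustained a fracture at `site`
#' this cycle, draws the site's care pathway: hip fractures always lead to
#' hemiarthroplasty, with acute ambulatory rehabilitation (p = 0.48),
#' transfer to long-term care (p = 0.20, an absorbing residence state) and
#' follow-up (p = 0.80); wrist fractures undergo surgery with p = 0.18 (else
#' conservative management); clinical vertebral fractures are hospitalized
#' with p = 0.10.
#'
#' @inheritParams annual_fracture_probability
#' @return A tibble of logical pathway flags (`rehab`, `ltc`, `followup`,
#'   `surgery`, `hospitalized` as applicable to the site).
#' @export
resolve_fracture <- function(pop, site, params = default_parameters()) {
  site <- match.arg(site, SITES)
  n <- nrow(pop)
  if (site == "hip" && "n_hip" %in% names(pop) && any(pop$n_hip >= 2L)) {
    abort("hip fracture drawn for a woman who already has two")
  }
  switch(site,
    hip = tibble::tibble(surgery = rep(TRUE, n),
                         rehab = runif(n) < params$p_hip_rehab,
                         ltc = runif(n) < params$p_hip_ltc,
                         followup = runif(n) < params$p_hip_followup),
    wrist = tibble::tibble(surgery = runif(n) < params$p_wrist_surgery),
    vertebral = tibble::tibble(hospitalized = runif(n) < params$p_vertebral_hosp))
}

#' Post-fracture investigation and treatment cascade
#'
#' For women who fractured this cycle and are not already on
#' pharmacotherapy: osteoporosis investigation is drawn (p = 0.21); if
#' investigated, risedronate is initiated with probability 0.756 / 0.294 /
#' 0.09 for osteoporotic / low / normal BMD; investigated women not put on
#' pharmacotherapy are proposed vitamin D + calcium. Compliance is drawn once
#' at initiation (p = 0.49) and gates both the effect and the cost of
#' whichever treatment was initiated.
#'
#' @inheritParams annual_fracture_probability
#' @return A tibble with logical columns `investigated`,
#'   `started_risedronate`, `compliant`, `adopted_vitd`.
#' @export
post_fracture_cascade <- function(pop, params = default_parameters()) {
  n <- nrow(pop)
  on_rx <- if ("on_risedronate" %in% names(pop)) pop$on_risedronate else
    rep(FALSE, n)
  investigated <- !on_rx & runif(n) < params$p_investigation
  p_treat <- cascade_treat_prob(bmd_category(pop$t_score), params)
  started <- investigated & runif(n) < p_treat
  compliant <- runif(n) < params$p_compliance
  has_vitd <- if ("takes_vitd_calcium" %in% names(pop)) {
    pop$takes_vitd_calcium
  } else rep(FALSE, n)
  adopted_vitd <- investigated & !started & !has_vitd & compliant
  tibble::tibble(investigated = investigated, started_risedronate = started,
                 compliant = compliant, adopted_vitd = adopted_vitd)
}

cascade_treat_prob <- function(category, params) {
  unname(c(normal = params$p_treat_normal_bmd,
           low = params$p_treat_low_bmd,
           osteoporosis = params$p_treat_osteoporosis)[category])
}

# One annual cycle over the whole population. Returns list(pop, ledger).
step_cycle <- function(pop, cycle, params, tables, keep_ledger = FALSE) {
  n <- nrow(pop)
  u <- matrix(runif(n * N_DRAWS), nrow = n, ncol = N_DRAWS)
  alive <- pop$alive
  pop$t_score <- current_t_score(pop$z, pop$age, tables$bmd_model)

  # incident fractures on treatment-adjusted hazards
  frac <- list()
  fcol <- c(hip = "f_hip", vertebral = "f_vert", wrist = "f_wrist")
  for (s in SITES) {
    p <- annual_fracture_probability(pop, s, params, tables)
    frac[[s]] <- alive & u[, DRAW[[fcol[[s]]]]] < p
  }
  f_hip <- frac$hip; f_vert <- frac$vertebral; f_wrist <- frac$wrist

  # care pathways
  hip_rehab <- f_hip & u[, DRAW[["hip_rehab"]]] < params$p_hip_rehab
  hip_ltc <- f_hip & u[, DRAW[["hip_ltc"]]] < params$p_hip_ltc
  hip_fu <- f_hip & u[, DRAW[["hip_fu"]]] < params$p_hip_followup
  wrist_surg <- f_wrist & u[, DRAW[["wrist_surg"]]] < params$p_wrist_surgery
  vert_hosp <- f_vert & u[, DRAW[["vert_hosp"]]] < params$p_vertebral_hosp

  pop$n_hip <- pop$n_hip + f_hip
  pop$n_vert <- pop$n_vert + f_vert
  pop$n_wrist <- pop$n_wrist + f_wrist
  pop$last_hip_cycle[f_hip] <- cycle
  pop$last_vert_cycle[f_vert] <- cycle
  pop$care_ltc <- pop$care_ltc | hip_ltc
  stopifnot(all(pop$n_hip <= 2L))

  # post-fracture cascade (treatment initiated for subsequent cycles)
  any_frac <- f_hip | f_vert | f_wrist
  elig <- any_frac & !pop$on_risedronate
  invest <- elig & u[, DRAW[["invest"]]] < params$p_investigation
  p_treat <- cascade_treat_prob(bmd_category(pop$t_score), params)
  start_ris <- invest & u[, DRAW[["treat"]]] < p_treat
  comply <- u[, DRAW[["comply"]]] < params$p_compliance
  pop$on_risedronate[start_ris] <- TRUE
  pop$ris_compliant[start_ris] <- comply[start_ris]
  pop$ris_start[start_ris] <- cycle
  adopt_vitd <- invest & !start_ris & !pop$takes_vitd_calcium & comply
  pop$takes_vitd_calcium[adopt_vitd] <- TRUE
  pop$vitd_program[adopt_vitd] <- TRUE

  # death
  q <- annual_death_probability(pop, params, tables, cycle)
  died <- alive & u[, DRAW[["death"]]] < q

  # economics
  events <- tibble::tibble(
    frac_hip = f_hip, hip_rehab = hip_rehab, hip_ltc = hip_ltc,
    hip_followup = hip_fu, frac_vert = f_vert, vert_hosp = vert_hosp,
    frac_wrist = f_wrist, wrist_surg = wrist_surg)
  cost <- cycle_cost(events, pop, params, cycle)
  util <- cycle_utility(pop, events, params, died = died)
  lyr <- ifelse(died, 0.5, 1)
  df <- (1 + params$discount_rate)^(-cycle)
  live_cost <- ifelse(alive, cost$total, 0)
  pop$cum_cost <- pop$cum_cost + live_cost * df
  pop$cum_cost_undisc <- pop$cum_cost_undisc + live_cost
  for (cc in c("fracture", "treatment", "screening", "followup", "ltc")) {
    col <- paste0("cum_cost_", cc)
    pop[[col]] <- pop[[col]] + ifelse(alive, cost[[cc]], 0) * df
  }
  pop$cum_qaly <- pop$cum_qaly + ifelse(alive, util, 0) * df
  pop$cum_ly <- pop$cum_ly + ifelse(alive, lyr, 0) * df

  ledger <- NULL
  if (keep_ledger) {
    ledger <- dplyr::bind_cols(
      tibble::tibble(id = pop$id, cycle = cycle, age = pop$age),
      events,
      tibble::tibble(investigated = invest, started_treatment = start_ris,
                     died = died,
                     undiscounted_cost = cost$total,
                     utility_weighted_time = util))[alive, ]
  }

  # age, survival, treatment-duration policy
  pop$died_cycle[died] <- cycle
  pop$alive <- alive & !died
  pop$age <- pop$age + as.integer(pop$alive)
  dur <- treatment_duration_cycles(params)
  if (is.finite(dur)) {
    expired <- pop$on_risedronate & !is.na(pop$ris_start) &
      (cycle - pop$ris_start + 1L) >= dur
    pop$on_risedronate[expired] <- FALSE
  }
  list(pop = pop, ledger = ledger)
}

#' Advance the whole population by one annual cycle
#'
#' Runs one cycle of the natural-history engine: draw incident fractures per
#' site on treatment-adjusted hazards, resolve care pathways, run the
#' post-fracture cascade, draw death, and accrue discounted costs and
#' utility-weighted time. The population tibble is returned updated, with a
#' per-woman ledger of the cycle.
#'
#' @inheritParams annual_fracture_probability
#' @param cycle Cycle index (0-based; discounting exponent).
#' @return A list with elements `pop` (updated population) and `ledger`
#'   (one row per woman alive at the cycle start).
#' @export
simulate_cycle <- function(pop, cycle = 0L, params = default_parameters(),
                           tables = model_tables()) {
  if (!"n_hip" %in% names(pop)) pop <- init_state(pop)
  step_cycle(pop, cycle, params, tables, keep_ledger = TRUE)
}

#' Run the microsimulation until every woman has died
#'
#' Applies the policy (if any) at baseline, then loops annual cycles —
#' adding rolling entrants of 40-year-old women when the cohort spec asks
#' for them — until no woman is alive. Deterministic given `seed`; runs with
#' the same seed and cohort share fate streams across policies.
#'
#' @param population A cohort from [generate_cohort()].
#' @param policy A policy from [policy()] or `NULL` for bare natural history
#'   (no baseline intervention and no policy draws).
#' @param seed Integer seed for all within-run randomness.
#' @param params A `osteo_params` object.
#' @param tables Lookup tables from [model_tables()].
#' @param keep_ledger Keep the full per-woman per-cycle ledger? (memory-heavy
#'   for large cohorts; per-woman totals are always kept).
#' @param max_cycles Safety cap on the number of cycles.
#' @return A `osteo_sim` object: list with `population` (final state with
#'   per-woman discounted cost and QALY totals and fracture counts),
#'   `ledger` (if kept), `policy`, `seed`, `cycles`, `n_entrants`.
#' @export
run_lifetime <- function(population, policy = NULL, seed = 1L,
                         params = default_parameters(),
                         tables = model_tables(), keep_ledger = FALSE,
                         max_cycles = 200L) {
  if (nrow(population) == 0L) abort("population is empty")
  spec <- attr(population, "spec")
  set.seed(seed)
  pop <- init_state(population)
  if (!is.null(policy)) pop <- apply_policy(pop, policy, params, cycle = 0L)
  ledgers <- list()
  cycle <- 0L
  repeat {
    if (!is.null(spec) && spec$rolling_entry && cycle >= 1L &&
        cycle <= spec$entry_window && spec$annual_entry > 0L) {
      n0 <- nrow(pop)
      pop <- add_rolling_entrants(pop, cycle, spec)
      if (!is.null(policy) && nrow(pop) > n0) {
        idx <- (n0 + 1L):nrow(pop)
        pop[idx, ] <- apply_policy(pop[idx, ], policy, params, cycle = cycle)
      }
    }
    if (!any(pop$alive)) break
    stepped <- step_cycle(pop, cycle, params, tables, keep_ledger)
    pop <- stepped$pop
    if (keep_ledger) ledgers[[length(ledgers) + 1L]] <- stepped$ledger
    cycle <- cycle + 1L
    if (cycle > max_cycles) {
      abort("simulation did not terminate within max_cycles")
    }
  }
  structure(list(
    population = pop,
    ledger = if (keep_ledger) dplyr::bind_rows(ledgers) else NULL,
    policy = policy, seed = seed, cycles = cycle, n_entrants = nrow(pop)),
    class = "osteo_sim")
}

#' @export
print.osteo_sim <- function(x, ...) {
  cat("<osteo_sim> ", x$n_entrants, " women, ", x$cycles, " cycles",
      if (!is.null(x$policy)) paste0(", policy: ", x$policy$name), "\n",
      sep = "")
  invisible(x)
}
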