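#' Undiscounted cost of one cycle
#'
#' Sums the applicable unit costs (fiscal 2007-2008 $CAD, public-payer
#' perspective) given the cycle's resolved events and the woman's state.
#' Items conditional on a care pathway (rehabilitation, long-term care,
#' surgery, hospitalization, follow-up) are costed only when the pathway was
#' actually drawn — the catalogue's applicability probabilities are realised
#' by the pathway draws, never multiplied in at costing time.
#'
#' Categories: `fracture` (acute episode plus its follow-up items),
#' `treatment` (annual risedronate for compliant users, program vitamin D +
#' calcium, program physical-activity promotion), `screening` (baseline
#' visit + DXA in the screening cycle), `followup` (annual medical visit for
#' treated women and scheduled control DXA every 2 years — 5 if low risk —
#' for screened women), `ltc` (annual long-term-care cost while resident).
#'
#' @param events Tibble of logical event flags as produced by the engine
#'   (`frac_hip`, `hip_rehab`, `hip_ltc`, `hip_followup`, `frac_vert`,
#'   `vert_hosp`, `frac_wrist`, `wrist_surg`).
#' @param pop Population tibble with engine state.
#' @param params A `osteo_params` object.
#' @param cycle Cycle index (drives the screening / control-DXA schedule).
#' @return A tibble with per-woman cost columns `fracture`, `treatment`,
#'   `screening`, `followup`, `ltc`, `total`.
#' @export
cycle_cost <- function(events, pop, params = default_parameters(),
                       cycle = 0L) {
  n <- nrow(pop)
  zero <- rep(0, n)
  ev <- function(nm) if (nm %in% names(events)) events[[nm]] else rep(FALSE, n)
  st <- function(nm, default = FALSE) {
    if (nm %in% names(pop)) pop[[nm]] else rep(default, n)
  }
  fracture <-
    ev("frac_hip") * (params$c_hip_acute + params$c_hip_hosp +
                        params$c_hip_inpatient_visits) +
    ev("hip_rehab") * params$c_hip_rehab +
    ev("hip_followup") * params$c_hip_followup +
    ev("frac_vert") * (params$c_vert_acute + params$c_vert_inpatient_visits +
                         params$c_vert_followup) +
    ev("vert_hosp") * params$c_vert_hosp +
    ev("frac_wrist") * params$c_wrist_followup +
    (ev("frac_wrist") & ev("wrist_surg")) * params$c_wrist_surgery +
    (ev("frac_wrist") & !ev("wrist_surg")) * params$c_wrist_conservative

  on_rx <- st("on_risedronate") & st("ris_compliant")
  treatment <- on_rx * params$c_risedronate_annual +
    st("vitd_program") * params$c_vitd_annual +
    st("pa_program") * params$c_pa_annual

  scr <- st("screened")
  scr_cycle <- st("screen_cycle", NA_integer_)
  screening <- ifelse(scr & !is.na(scr_cycle) & scr_cycle == cycle,
                      params$c_screen_visit + params$c_dxa, 0)

  interval <- ifelse(!is.na(st("risk_category", NA_character_)) &
                       st("risk_category", NA_character_) == "low",
                     params$dxa_interval_low_risk, params$dxa_interval)
  due <- scr & !is.na(scr_cycle) & cycle > scr_cycle &
    ((cycle - scr_cycle) %% interval == 0)
  followup <- on_rx * params$c_followup_visit + due * params$c_control_dxa

  ltc_flag <- if (params$ltc_recurring) st("care_ltc") else ev("hip_ltc")
  ltc <- ltc_flag * params$c_ltc_year

  tibble::tibble(fracture = fracture, treatment = treatment,
                 screening = screening, followup = followup, ltc = ltc,
                 total = fracture + treatment + screening + followup + ltc)
}

#' Utility-weighted time for one cycle
#'
#' Time-weighted average utility over the cycle's within-year phases.
#' Fracture-free time accrues at the baseline utility. A fracture year is
#' split into published phase utilities: hip — 14 days hospitalization at
#' 0.30, 30 days rehabilitation at 0.56 when rehabilitation was drawn, the
#' remainder at 0.85; clinical vertebral — 9 days at 0.33 when hospitalized,
#' 30 days rehabilitation at 0.68, remainder at 0.85; wrist — an emergency
#' day at 0.61, 30 days at 0.88, remainder at 1.00. When fractures co-occur
#' the most severe (lowest) site value applies. Women who die during the
#' cycle accrue half the year.
#'
#' @inheritParams cycle_cost
#' @param died Logical vector; deaths prorate the cycle to half a year.
#' @return Numeric QALY-years in \[0, 1\] per woman.
#' @export
cycle_utility <- function(pop, events, params = default_parameters(),
                          died = FALSE) {
  n <- nrow(pop)
  ev <- function(nm) if (nm %in% names(events)) events[[nm]] else rep(FALSE, n)
  base <- rep(params$u_baseline, n)

  hip_days_rehab <- ifelse(ev("hip_rehab"), params$d_hip_rehab, 0)
  u_hip <- (params$d_hip_hosp * params$u_hip_hosp +
              hip_days_rehab * params$u_hip_rehab +
              (365 - params$d_hip_hosp - hip_days_rehab) * params$u_hip_post) / 365
  vert_days_hosp <- ifelse(ev("vert_hosp"), params$d_vert_hosp, 0)
  u_vert <- (vert_days_hosp * params$u_vert_hosp +
               params$d_vert_rehab * params$u_vert_rehab +
               (365 - vert_days_hosp - params$d_vert_rehab) * params$u_vert_post) / 365
  u_wrist <- (params$d_wrist_er * params$u_wrist_er +
                params$d_wrist_rehab * params$u_wrist_rehab +
                (365 - params$d_wrist_er - params$d_wrist_rehab) *
                  params$u_wrist_post) / 365

  val <- base
  val <- pmin(val, ifelse(ev("frac_hip"), u_hip, 1))
  val <- pmin(val, ifelse(ev("frac_vert"), u_vert, 1))
  val <- pmin(val, ifelse(ev("frac_wrist"), u_wrist, 1))
  out <- val * ifelse(died, 0.5, 1)
  if (any(out < 0 | out > 1)) {
    abort("cycle utility outside [0, 1]: utility parameters inconsistent")
  }
  out
}

#' Discount an amount
#'
#' `amount / (1 + rate)^years`; applied identically to costs and QALYs, with
#' year 0 undiscounted.
#'
#' @param amount Amount (vectorised).
#' @param years Years from the start of the simulation.
#' @param rate Annual discount rate (default 3%).
#' @return Discounted amount.
#' @export
#' @examples
#' discount(103, 1, 0.03)
discount <- function(amount, years, rate = 0.03) {
  stopifnot(all(years >= 0), rate >= 0)
  amount / (1 + rate)^years
}

#' Aggregate a run into strategy-level results
#'
#' Sums per-woman discounted costs and QALYs and undiscounted fracture
#' counts over the whole population and by entry-age stratum (40-64 vs 65
#' and over), with per-person means over entrants.
#'
#' @param sim A `osteo_sim` from [run_lifetime()].
#' @param strata Split results by entry age? (default TRUE; an `all` row is
#'   always included.)
#' @return A tibble with one row per stratum: population size, total and
#'   per-category discounted costs, fractures by site and in total, QALYs,
#'   life-years, and per-person means.
#' @export
aggregate_results <- function(sim, strata = TRUE) {
  pop <- sim$population
  pop$stratum <- ifelse(pop$entry_age < 65, "40-64", "65plus")
  summarise_block <- function(d, label) {
    tibble::tibble(
      stratum = label,
      policy = if (!is.null(sim$policy)) sim$policy$name else NA_character_,
      n = nrow(d),
      total_cost = sum(d$cum_cost),
      cost_fracture = sum(d$cum_cost_fracture),
      cost_treatment = sum(d$cum_cost_treatment),
      cost_screening = sum(d$cum_cost_screening),
      cost_followup = sum(d$cum_cost_followup),
      cost_ltc = sum(d$cum_cost_ltc),
      fractures_hip = sum(d$n_hip), fractures_vertebral = sum(d$n_vert),
      fractures_wrist = sum(d$n_wrist),
      total_fractures = sum(d$n_hip + d$n_vert + d$n_wrist),
      total_qalys = sum(d$cum_qaly), total_ly = sum(d$cum_ly),
      cost_per_person = sum(d$cum_cost) / nrow(d),
      qalys_per_person = sum(d$cum_qaly) / nrow(d))
  }
  out <- summarise_block(pop, "all")
  if (strata) {
    for (s in c("40-64", "65plus")) {
      d <- pop[pop$stratum == s, ]
      if (nrow(d)) out <- dplyr::bind_rows(out, summarise_block(d, s))
    }
  }
  out
}
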