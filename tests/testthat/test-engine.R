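p0 <- default_parameters()

test_that("treatment effects multiply baseline fracture probabilities", {
  expect_equal(apply_treatment_effect(0.10, "hip", "risedronate", TRUE, p0),
               0.072)
  expect_equal(apply_treatment_effect(0.05, "hip", "risedronate", TRUE, p0),
               0.036)
  expect_equal(apply_treatment_effect(0.10, "vertebral", "risedronate",
                                      TRUE, p0), 0.058)
  # physical activity protects the hip only
  expect_equal(apply_treatment_effect(0.10, "wrist", "physical_activity",
                                      TRUE, p0), 0.10)
  expect_equal(apply_treatment_effect(0.10, "hip", "physical_activity",
                                      TRUE, p0), 0.062)
  # combined prevention takes the strongest effect, never the product
  expect_equal(apply_treatment_effect(0.10, "hip", "combined", TRUE, p0),
               0.062)
  expect_equal(apply_treatment_effect(0.10, "wrist", "combined", TRUE, p0),
               0.088)
  # non-compliance voids the effect
  expect_equal(apply_treatment_effect(0.10, "hip", "risedronate", FALSE, p0),
               0.10)
  expect_error(apply_treatment_effect(0.1, "hip", "magic", TRUE, p0),
               "unknown treatment")
})

test_that("fracture probability lookups honour state and the hip cap", {
  tabs <- model_tables()
  w <- osteosim:::init_state(generate_cohort(single_age_spec(1, 70L,
                                                             seed = 2)))
  raw <- annual_fracture_probability(w, "hip", p0, tabs)
  hz <- tabs$hazards
  expected <- hz$probability[hz$site == "hip" & hz$age_low <= 70 &
                               hz$age_high >= 70 &
                               hz$bmd_category == bmd_category(w$t_score)]
  # untreated, not active: raw table entry
  w$physically_active <- FALSE
  w$takes_vitd_calcium <- FALSE
  expect_equal(annual_fracture_probability(w, "hip", p0, tabs), expected)
  # two prior hip fractures: zero
  w$n_hip <- 2L
  expect_equal(annual_fracture_probability(w, "hip", p0, tabs), 0)
  w$age <- 20L
  expect_error(annual_fracture_probability(w, "hip", p0, tabs), "age")
})

test_that("death probability applies the post-fracture multipliers", {
  tabs <- toy_tables(h = 0, q = 0.01)
  w <- osteosim:::init_state(generate_cohort(single_age_spec(3, 50L,
                                                             seed = 2)))
  w$last_hip_cycle <- c(5L, NA, NA)
  w$last_vert_cycle <- c(5L, 5L, NA)
  q <- annual_death_probability(w, p0, tabs, cycle = 5L)
  expect_equal(q, c(0.01 * 4.31, 0.01 * 2.85, 0.01))
  # window closes after the following cycle
  q7 <- annual_death_probability(w, p0, tabs, cycle = 7L)
  expect_equal(q7, rep(0.01, 3))
  # cap at 1
  tabs30 <- toy_tables(h = 0, q = 0.30)
  expect_equal(annual_death_probability(w, p0, tabs30, cycle = 5L)[1], 1)
})

test_that("care pathways realise the published probabilities", {
  co <- osteosim:::init_state(generate_cohort(single_age_spec(10000, 70L,
                                                              seed = 5)))
  set.seed(42)
  hip <- resolve_fracture(co, "hip", p0)
  expect_true(all(hip$surgery))
  se <- function(p) 3 * sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(hip$ltc) - 0.20), se(0.20))
  expect_lt(abs(mean(hip$rehab) - 0.48), se(0.48))
  wrist <- resolve_fracture(co, "wrist", p0)
  expect_lt(abs(mean(wrist$surgery) - 0.18), se(0.18))
  p_nohosp <- load_parameters(overrides = list(p_vertebral_hosp = 0))
  vert <- resolve_fracture(co, "vertebral", p_nohosp)
  expect_false(any(vert$hospitalized))
  co$n_hip <- 2L
  expect_error(resolve_fracture(co, "hip", p0), "two")
})

test_that("the post-fracture cascade initiates treatment as published", {
  co <- osteosim:::init_state(generate_cohort(single_age_spec(30000, 80L,
                                                              seed = 6)))
  co$t_score <- -3  # all osteoporotic
  set.seed(9)
  all_inv <- load_parameters(overrides = list(p_investigation = 1))
  cas <- post_fracture_cascade(co, all_inv)
  se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cas$started_risedronate) - 0.756), se(0.756, 30000))
  expect_lt(abs(mean(cas$compliant) - 0.49), se(0.49, 30000))
  # never investigated, never treated
  none <- load_parameters(overrides = list(p_investigation = 0))
  cas0 <- post_fracture_cascade(co, none)
  expect_false(any(cas0$investigated))
  expect_false(any(cas0$started_risedronate))
})

test_that("a cycle with no hazards accrues baseline utility and no events", {
  tabs <- toy_tables(h = 0, q = 0)
  co <- generate_cohort(single_age_spec(10, seed = 3))
  out <- simulate_cycle(co, cycle = 0L, params = p0, tables = tabs)
  expect_false(any(out$ledger$frac_hip | out$ledger$frac_vert |
                     out$ledger$frac_wrist))
  expect_equal(out$ledger$utility_weighted_time, rep(p0$u_baseline, 10))
  expect_equal(out$ledger$undiscounted_cost, rep(0, 10))
  expect_true(all(out$pop$alive))
})

test_that("event frequencies match input probabilities (binomial oracle)", {
  tabs <- toy_tables(h = 0.05, q = 0.02)
  co <- generate_cohort(single_age_spec(100000, seed = 4,
                                        behavior_table = null_behavior_table()))
  set.seed(10)
  out <- simulate_cycle(co, cycle = 0L, params = p0, tables = tabs)
  se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(out$ledger$frac_wrist) - 0.05), se(0.05, 1e5))
  expect_lt(abs(mean(out$ledger$died) - 0.02), se(0.02, 1e5))
  nwr <- sum(out$ledger$frac_wrist)
  expect_lt(abs(mean(out$ledger$wrist_surg[out$ledger$frac_wrist]) - 0.18),
            se(0.18, nwr))
})

test_that("lifetime runs terminate, are deterministic and conserve ledgers", {
  co <- generate_cohort(cohort_spec(800, seed = 12))
  s1 <- run_lifetime(co, policy("Status quo"), seed = 5, keep_ledger = TRUE)
  s2 <- run_lifetime(co, policy("Status quo"), seed = 5, keep_ledger = TRUE)
  expect_false(any(s1$population$alive))  # everyone eventually dies
  expect_identical(s1$population, s2$population)
  expect_identical(s1$ledger, s2$ledger)
  expect_true(all(s1$population$n_hip <= 2L))

  # each woman contributes one ledger row per cycle from entry to death
  led <- dplyr::summarise(dplyr::group_by(s1$ledger, id),
                          n_rows = dplyr::n(), last = max(cycle),
                          first = min(cycle))
  pop <- s1$population
  expect_equal(led$first[order(led$id)], pop$entry_cycle[order(pop$id)])
  expect_equal(led$last[order(led$id)], pop$died_cycle[order(pop$id)])
  expect_equal(led$n_rows, led$last - led$first + 1L)
})

test_that("with all relative risks at 1 every strategy shares one fate", {
  ones <- load_parameters(overrides = list(
    rr_risedronate_hip = 1, rr_risedronate_vertebral = 1,
    rr_risedronate_wrist = 1, rr_vitd_calcium = 1,
    rr_physical_activity_hip = 1))
  co <- generate_cohort(cohort_spec(1500, seed = 20))
  frac_count <- function(pname) {
    pop <- run_lifetime(co, policy(pname), seed = 8, params = ones)$population
    sum(pop$n_hip + pop$n_vert + pop$n_wrist)
  }
  counts <- vapply(c("Status quo", "Physical activity",
                     "BMD/CAROC + vitamin D and calcium + physical activity",
                     "ORAI/CAROC + physical activity"),
                   frac_count, numeric(1))
  expect_true(all(counts == counts[1]))
})
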