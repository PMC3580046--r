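# Shared fixtures, built in code. Calibrated tables are computed once per
# test run and reused (the simulation refinement is the expensive part).
.fixture_cache <- new.env(parent = emptyenv())

calibrated_tables <- function() {
  if (is.null(.fixture_cache$tables)) {
    cal <- calibrate_lifetime_risk(refine_n = 20000L, refine_iter = 2L,
                                   refine_seed = 2203L)
    .fixture_cache$cal <- cal
    .fixture_cache$tables <- model_tables(cal$hazards)
  }
  .fixture_cache$tables
}

calibration_result <- function() {
  calibrated_tables()
  .fixture_cache$cal
}

# Cohort of women all entering at the same age.
single_age_spec <- function(n, age = 40L, seed = 1L, ...) {
  cohort_spec(n, age_table = tibble::tibble(age_low = age, age_high = age,
                                            weight = 1),
              seed = seed, ...)
}

# Cohort spec restricted to entry ages 65+, weights renormalised.
spec_65plus <- function(n, seed = 1L) {
  at <- default_age_table()
  at <- at[at$age_low >= 65, ]
  at$weight <- at$weight / sum(at$weight)
  cohort_spec(n, age_table = at, seed = seed)
}

# Behaviour table with every prevalence zero (isolates the fracture process
# from prevalent preventive behaviours).
null_behavior_table <- function() {
  b <- osteosim:::default_behavior_table()
  b$p_physically_active <- 0
  b$p_vitd_calcium <- 0
  b$p_prior_fracture <- 0
  b$p_glucocorticoid <- 0
  b
}

# One-site toy world: constant wrist hazard h at every age and BMD category,
# zero hip/vertebral hazard, constant annual death probability q.
toy_tables <- function(h = 0.03, q = 0.05) {
  hz <- default_hazard_table()
  hz$probability <- ifelse(hz$site == "wrist", h, 0)
  lt <- default_life_table()
  lt$q_death <- q
  lt$q_death[lt$age == max(lt$age)] <- 1
  model_tables(hz, lt)
}

# Independent brute-force frontier oracle: a strategy is excluded iff some
# other strategy (strict dominance) or convex combination of two others
# (extended dominance) attains at least its effect at no greater cost, with
# one inequality strict. Assumes continuous (tie-free) inputs.
oracle_frontier <- function(cost, eff) {
  n <- length(cost)
  strictly <- vapply(seq_len(n), function(i) {
    any(cost <= cost[i] & eff >= eff[i] & (cost < cost[i] | eff > eff[i]))
  }, logical(1))
  excluded <- strictly
  for (i in seq_len(n)) {
    if (excluded[i]) next
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == i || b == i || a == b || eff[a] == eff[b]) next
        alpha <- (eff[i] - eff[b]) / (eff[a] - eff[b])
        if (alpha < 0 || alpha > 1) next
        mix_cost <- alpha * cost[a] + (1 - alpha) * cost[b]
        if (mix_cost < cost[i]) excluded[i] <- TRUE
      }
    }
  }
  list(frontier = which(!excluded), strict = which(strictly))
}
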