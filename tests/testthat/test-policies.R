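p0 <- default_parameters()

test_that("the catalogue holds the sixteen distinct strategies", {
  cat_ <- policy_catalog()
  expect_equal(nrow(cat_), 16)
  expect_equal(anyDuplicated(cat_$name), 0)
  expect_equal(sum(cat_$arm == "screening"), 12)
  expect_error(policy("Universal magnesium"), "Status quo")
})

test_that("participation is a Bernoulli draw at the published rate", {
  set.seed(3)
  part <- participate(50000, p0)
  expect_lt(abs(mean(part) - 0.531), 3 * sqrt(0.531 * 0.469 / 50000))
  expect_true(all(participate(100, load_parameters(
    overrides = list(p_participation = 1)))))
  expect_false(any(participate(100, load_parameters(
    overrides = list(p_participation = 0)))))
})

test_that("prescreening follows sensitivity and specificity", {
  co <- generate_cohort(cohort_spec(50000, seed = 8))
  perfect <- list(name = "PERFECT", sensitivity = 1, specificity = 1)
  expect_equal(prescreen(co, perfect), osteoporotic(co))

  orai <- screening_tool("ORAI", p0)
  expect_equal(orai$sensitivity, 0.933)
  osteo <- co[osteoporotic(co), ]
  set.seed(4)
  pos <- prescreen(osteo, orai)
  expect_lt(abs(mean(pos) - 0.933),
            3 * sqrt(0.933 * 0.067 / nrow(osteo)) + 0.01)

  # mixed cohort: closed-form expected positivity pi*sens + (1-pi)(1-spec)
  pi_ <- mean(osteoporotic(co))
  expected <- pi_ * orai$sensitivity + (1 - pi_) * (1 - orai$specificity)
  set.seed(5)
  posm <- prescreen(co, orai)
  expect_lt(abs(mean(posm) - expected), 3 * sqrt(expected * (1 - expected) /
                                                   nrow(co)))
})

test_that("the risk surface is monotone and escalates on clinical factors", {
  base <- tibble::tibble(age = c(55, 65, 75), t_score = -2.5,
                         prior_fragility_fracture = FALSE,
                         glucocorticoid_use = FALSE)
  r <- caroc_ten_year_risk(base)
  expect_true(all(diff(r) > 0))
  worse_bone <- dplyr::mutate(base, t_score = -3.5)
  expect_true(all(caroc_ten_year_risk(worse_bone) > r))

  both <- dplyr::mutate(base, prior_fragility_fracture = TRUE,
                        glucocorticoid_use = TRUE)
  expect_true(all(caroc_category(both) == "high"))
  one <- dplyr::mutate(base, prior_fragility_fracture = TRUE)
  lvl <- function(x) match(x, c("low", "moderate", "high"))
  expect_true(all(lvl(caroc_category(one)) >=
                    pmin(3, lvl(caroc_category(base)) + 1)))
  expect_error(caroc_ten_year_risk(dplyr::mutate(base, t_score = NA)),
               "t_score")
})

test_that("risk categories shift toward high with age; high risk sits in the
           osteoporotic and elderly stratum", {
  co <- generate_cohort(cohort_spec(20000, seed = 44))
  cat_ <- caroc_category(co)
  frac_high <- tapply(cat_ == "high", cut(co$age, c(40, 55, 70, 85, 100),
                                          right = FALSE), mean)
  expect_true(all(diff(frac_high) > 0))

  risk <- caroc_ten_year_risk(co)
  expect_gt(mean(co$age[risk >= 0.20]), mean(co$age))
  expect_lt(mean(co$t_score[risk >= 0.20]), mean(co$t_score))
})

test_that("risk categorisation uses the 10% and 20% boundaries", {
  expect_equal(caroc_categorize(c(0.05, 0.0999, 0.10, 0.1999, 0.20, 0.9)),
               c("low", "low", "moderate", "moderate", "high", "high"))
  expect_error(caroc_categorize(1.2), "risk")
})

test_that("management assignment follows the category rules", {
  co <- osteosim:::init_state(generate_cohort(cohort_spec(
    6, seed = 2, behavior_table = null_behavior_table())))
  co$prior_fragility_fracture <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  co$glucocorticoid_use <- FALSE
  pol <- policy("BMD/CAROC + physical activity")
  category <- c("high", "moderate", "moderate", "low", "low", "low")
  out <- assign_management(co, category, pol, p0,
                           u_comply = rep(0, 6))  # everyone compliant
  expect_true(out$on_risedronate[1])   # high risk
  expect_false(out$on_risedronate[2])  # moderate without other risk factors
  expect_true(out$physically_active[2])
  expect_true(out$on_risedronate[3])   # moderate with prior fracture
  expect_true(all(out$physically_active[4:6]))  # low risk: package
  expect_false(any(out$on_risedronate[4:6]))
  expect_true(all(out$pa_program[4:6]))
})

test_that("status quo applies no baseline program and vitD arms skip takers", {
  co <- generate_cohort(cohort_spec(2000, seed = 7))
  set.seed(1)
  sq <- apply_policy(co, policy("Status quo"), p0)
  expect_false(any(sq$screened))
  expect_false(any(sq$pa_program | sq$vitd_program))
  expect_equal(sum(cycle_cost(tibble::tibble(), sq, p0, 0)$screening), 0)

  set.seed(1)
  vd <- apply_policy(co, policy("Vitamin D and calcium"), p0)
  already <- co$takes_vitd_calcium
  expect_false(any(vd$vitd_program[already]))
  expect_gt(sum(vd$vitd_program[!already]), 0)
})

test_that("all sixteen policies run and produce distinct management mixes", {
  co <- generate_cohort(cohort_spec(800, seed = 15))
  mixes <- purrr::map_chr(policy_catalog()$name, function(pn) {
    set.seed(33)
    out <- apply_policy(co, policy(pn), p0)
    paste(sum(out$on_risedronate), sum(out$screened), sum(out$pa_program),
          sum(out$vitd_program))
  })
  expect_equal(length(unique(mixes)), 16)
})

test_that("zero participation collapses any strategy onto the status quo", {
  none <- load_parameters(overrides = list(p_participation = 0))
  co <- generate_cohort(cohort_spec(1200, seed = 19))
  a <- run_lifetime(co, policy("Status quo"), seed = 6, params = none)
  b <- run_lifetime(co, policy("OST/CAROC + vitamin D and calcium"),
                    seed = 6, params = none)
  expect_identical(a$population$cum_cost, b$population$cum_cost)
  expect_identical(a$population$n_hip, b$population$n_hip)
})

test_that("screening cannot increase fractures under shared fate streams", {
  tabs <- calibrated_tables()
  co <- generate_cohort(cohort_spec(5000, seed = 23))
  sq <- run_lifetime(co, policy("Status quo"), seed = 9, tables = tabs)
  scr <- run_lifetime(co,
                      policy("BMD/CAROC + vitamin D and calcium + physical activity"),
                      seed = 9, tables = tabs)
  tot <- function(s) sum(s$population$n_hip + s$population$n_vert +
                           s$population$n_wrist)
  expect_lte(tot(scr), tot(sq))
})

test_that("perfect prescreening routes exactly the osteoporotic women", {
  co <- generate_cohort(cohort_spec(3000, seed = 27))
  perfect <- load_parameters(overrides = list(
    sens_orai = 1, spec_orai = 1))
  set.seed(12)
  arm <- apply_policy(co, policy("ORAI/CAROC + physical activity"), perfect)
  # everyone screened is osteoporotic; no osteoporotic participant missed
  expect_true(all(arm$t_score[arm$screened] <= -2.5))
  set.seed(12)
  bmd <- apply_policy(co, policy("BMD/CAROC + physical activity"), p0)
  osteo_part <- bmd$screened & osteoporotic(bmd)
  expect_equal(arm$screened, osteo_part)
})
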