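POLICY_PACKAGES <- c("physical_activity", "vitd_calcium", "both", "none")

#' Prescreening questionnaire characteristics
#'
#' The three prescreening questionnaires are characterised solely by their
#' sensitivity and specificity for densitometric osteoporosis.
#'
#' @param name One of `"OST"`, `"SCORE"`, `"ORAI"`.
#' @param params A `osteo_params` object (holds the operating values).
#' @return A list with `name`, `sensitivity`, `specificity`.
#' @export
screening_tool <- function(name, params = default_parameters()) {
  name <- match.arg(toupper(name), c("OST", "SCORE", "ORAI"))
  key <- tolower(name)
  list(name = name,
       sensitivity = params[[paste0("sens_", key)]],
       specificity = params[[paste0("spec_", key)]])
}

#' Catalogue of the sixteen simulated strategies
#'
#' One status-quo arm, three universal primary-prevention arms, and twelve
#' screening arms (direct BMD testing or an OST / SCORE / ORAI prescreen
#' followed by BMD, each combined with one of three preventive packages for
#' women who do not need pharmacotherapy).
#'
#' @return A tibble with columns `name`, `arm`, `prescreen_tool`,
#'   `bmd_screening`, `package`.
#' @export
policy_catalog <- function() {
  pkg_label <- c(physical_activity = "physical activity",
                 vitd_calcium = "vitamin D and calcium",
                 both = "vitamin D and calcium + physical activity")
  screening <- tidyr::expand_grid(
    tool = c(NA, "ORAI", "OST", "SCORE"),
    package = c("physical_activity", "vitd_calcium", "both"))
  screening$name <- paste0(
    ifelse(is.na(screening$tool), "BMD/CAROC", paste0(screening$tool, "/CAROC")),
    " + ", pkg_label[screening$package])
  dplyr::bind_rows(
    tibble::tibble(name = "Status quo", arm = "status_quo",
                   prescreen_tool = NA_character_, bmd_screening = FALSE,
                   package = "none"),
    tibble::tibble(name = c("Physical activity", "Vitamin D and calcium",
                            "Vitamin D and calcium + physical activity"),
                   arm = "primary_prevention", prescreen_tool = NA_character_,
                   bmd_screening = FALSE,
                   package = c("physical_activity", "vitd_calcium", "both")),
    tibble::tibble(name = screening$name, arm = "screening",
                   prescreen_tool = screening$tool, bmd_screening = TRUE,
                   package = screening$package))
}

#' Look up a strategy by name
#'
#' @param name One of the sixteen names in [policy_catalog()].
#' @return A `osteo_policy` list (`name`, `arm`, `prescreen_tool`,
#'   `bmd_screening`, `package`).
#' @export
#' @examples
#' policy("Status quo")
policy <- function(name) {
  cat_ <- policy_catalog()
  i <- match(name, cat_$name)
  if (is.na(i)) {
    abort(paste0("unknown policy '", name, "'. Valid policies:\n  ",
                 paste(cat_$name, collapse = "\n  ")))
  }
  structure(as.list(cat_[i, ]), class = "osteo_policy")
}

#' @export
print.osteo_policy <- function(x, ...) {
  cat("<osteo_policy> ", x$name, " (", x$arm, ")\n", sep = "")
  invisible(x)
}

#' Participation draw
#'
#' Bernoulli uptake of an offered prevention or screening intervention at
#' the population participation rate; non-participants follow the status-quo
#' pathway.
#'
#' @param pop Population tibble (or an integer count).
#' @param params A `osteo_params` object.
#' @param u Optional uniforms to use instead of fresh draws.
#' @return Logical vector.
#' @export
participate <- function(pop, params = default_parameters(), u = NULL) {
  n <- if (is.data.frame(pop)) nrow(pop) else as.integer(pop)
  if (is.null(u)) u <- runif(n)
  u < params$p_participation
}

#' Prescreening questionnaire result
#'
#' Positive with probability equal to the tool's sensitivity for
#' (densitometrically) osteoporotic women and one minus its specificity
#' otherwise; positive women proceed to BMD testing.
#'
#' @param pop Population tibble with `t_score`.
#' @param tool A tool from [screening_tool()].
#' @param u Optional uniforms to use instead of fresh draws.
#' @return Logical vector.
#' @export
prescreen <- function(pop, tool, u = NULL) {
  if (is.null(u)) u <- runif(nrow(pop))
  ifelse(osteoporotic(pop), u < tool$sensitivity, u < 1 - tool$specificity)
}

#' CAROC-style 10-year absolute fracture risk
#'
#' The published risk tables behind the CAROC instrument are not part of the
#' model inputs; this default surface is a documented logistic stand-in,
#' increasing in age and decreasing in T-score, anchored to give a moderate
#' (10-20%) risk for an osteoporotic-threshold T-score at age 65 and a
#' plausible category mix over the simulated population. A replacement
#' lookup can be supplied via `surface`.
#'
#' @param pop Population tibble with `age` and a measured `t_score`.
#' @param surface Optional risk-surface tibble with columns `age_low`,
#'   `age_high`, `t_score_low`, `t_score_high`, `risk` (long-format lookup);
#'   `NULL` uses the parametric default.
#' @return Numeric 10-year fracture risk in \[0, 1\].
#' @export
caroc_ten_year_risk <- function(pop, surface = NULL) {
  if (is.null(pop$t_score) || anyNA(pop$t_score)) {
    abort("t_score must be measured (BMD screening) before CAROC")
  }
  if (!is.null(surface)) {
    i <- mapply(function(a, t) {
      which(surface$age_low <= a & a <= surface$age_high &
              surface$t_score_low <= t & t < surface$t_score_high)[1]
    }, pop$age, pop$t_score)
    if (anyNA(i)) abort("risk surface does not cover all (age, t_score)")
    return(surface$risk[i])
  }
  plogis(-1.73 + 0.0587 * (pop$age - 65) - 0.484 * (pop$t_score + 2.5))
}

#' Categorise a 10-year fracture risk
#'
#' Low risk below 10%, moderate from 10% to below 20%, high at 20% and
#' above (pharmacotherapy is indicated from a 20% 10-year absolute risk).
#'
#' @param risk Numeric 10-year risk in \[0, 1\].
#' @return Character vector: `"low"`, `"moderate"`, `"high"`.
#' @export
#' @examples
#' caroc_categorize(c(0.05, 0.10, 0.20))
caroc_categorize <- function(risk) {
  if (any(risk < 0 | risk > 1)) abort("risk must lie in [0, 1]")
  dplyr::case_when(risk >= 0.20 ~ "high",
                   risk >= 0.10 ~ "moderate",
                   TRUE ~ "low")
}

#' CAROC risk category with clinical escalation
#'
#' Densitometric risk category escalated one level for a prior fragility
#' fracture or glucocorticoid use, and to high when both are present
#' (the clinical inputs of the CAROC instrument).
#'
#' @param pop Population tibble with `age`, `t_score`,
#'   `prior_fragility_fracture`, `glucocorticoid_use`.
#' @param surface Optional replacement risk surface (see
#'   [caroc_ten_year_risk()]).
#' @return Character vector: `"low"`, `"moderate"`, `"high"`.
#' @export
caroc_category <- function(pop, surface = NULL) {
  base <- caroc_categorize(caroc_ten_year_risk(pop, surface))
  lvl <- match(base, c("low", "moderate", "high"))
  bump <- as.integer(pop$prior_fragility_fracture) +
    as.integer(pop$glucocorticoid_use)
  lvl <- pmin(3L, ifelse(bump >= 2L, 3L, lvl + bump))
  c("low", "moderate", "high")[lvl]
}

#' Assign management after screening
#'
#' High-risk women receive risedronate; moderate-risk women receive
#' risedronate when another clinical risk factor (prior fragility fracture
#' or glucocorticoid use) is present and the policy's preventive package
#' otherwise; low-risk women receive the preventive package. Compliance is
#' drawn once at initiation and gates both the effect and the cost of the
#' assigned treatment, which continues per the treatment-duration policy.
#'
#' @param pop Population tibble (engine state).
#' @param category Risk category per woman (`"low"`, `"moderate"`, `"high"`).
#' @param pol A `osteo_policy`.
#' @param params A `osteo_params` object.
#' @param u_comply Optional uniforms for the compliance draw.
#' @param cycle Cycle at which management starts.
#' @return The population with treatment state updated.
#' @export
assign_management <- function(pop, category, pol,
                              params = default_parameters(), u_comply = NULL,
                              cycle = 0L) {
  n <- nrow(pop)
  if (is.null(u_comply)) u_comply <- runif(n)
  comply <- u_comply < params$p_compliance
  other_rf <- pop$prior_fragility_fracture | pop$glucocorticoid_use
  rx <- category == "high" | (category == "moderate" & other_rf)
  start_rx <- rx & !pop$on_risedronate
  pop$on_risedronate[start_rx] <- TRUE
  pop$ris_compliant[start_rx] <- comply[start_rx]
  pop$ris_start[start_rx] <- cycle
  prevent <- !rx
  pop <- offer_package(pop, pol$package, prevent & comply)
  pop
}

# Adopt the preventive package components a woman does not already have.
offer_package <- function(pop, package, who) {
  if (package %in% c("physical_activity", "both")) {
    adopt <- who & !pop$physically_active
    pop$physically_active[adopt] <- TRUE
    pop$pa_program[adopt] <- TRUE
  }
  if (package %in% c("vitd_calcium", "both")) {
    adopt <- who & !pop$takes_vitd_calcium
    pop$takes_vitd_calcium[adopt] <- TRUE
    pop$vitd_program[adopt] <- TRUE
  }
  pop
}

#' Apply a strategy to a population at baseline
#'
#' Status quo leaves prevalent behaviours untouched. Primary prevention
#' offers the package to women lacking the behaviour(s), with a
#' participation draw. Screening arms draw participation, run the optional
#' prescreening questionnaire, send (questionnaire-positive) participants to
#' BMD testing, categorise their 10-year CAROC risk, and assign management;
#' screened women are scheduled for follow-up (annual visit while treated,
#' control DXA every 2 years — 5 if low risk). Every arm consumes the same
#' per-woman draw block, so fate streams stay aligned across policies.
#'
#' @param pop Population tibble (engine state from [run_lifetime()] or a raw
#'   cohort, which is initialised first).
#' @param pol A `osteo_policy` (or policy name).
#' @param params A `osteo_params` object.
#' @param cycle Cycle at which the policy is applied (0 at baseline; rolling
#'   entrants are screened at entry).
#' @return The population with policy context applied.
#' @export
apply_policy <- function(pop, pol, params = default_parameters(), cycle = 0L) {
  if (is.character(pol)) pol <- policy(pol)
  stopifnot(inherits(pol, "osteo_policy"))
  if (!"n_hip" %in% names(pop)) pop <- init_state(pop)
  n <- nrow(pop)
  u <- matrix(runif(n * 4L), nrow = n, ncol = 4L)  # participate, prescreen,
                                                   # comply, reserved
  if (pol$arm == "status_quo") return(pop)

  part <- participate(pop, params, u = u[, 1])
  if (pol$arm == "primary_prevention") {
    lacking <- switch(pol$package,
      physical_activity = !pop$physically_active,
      vitd_calcium = !pop$takes_vitd_calcium,
      both = !pop$physically_active & !pop$takes_vitd_calcium)
    comply <- u[, 3] < params$p_compliance
    pop <- offer_package(pop, pol$package, lacking & part & comply)
    return(pop)
  }

  # screening arm
  to_bmd <- part
  if (!is.na(pol$prescreen_tool)) {
    tool <- screening_tool(pol$prescreen_tool, params)
    pos <- prescreen(pop, tool, u = u[, 2])
    to_bmd <- part & pos
  }
  if (!any(to_bmd)) return(pop)
  pop$screened[to_bmd] <- TRUE
  pop$screen_cycle[to_bmd] <- cycle
  category <- rep(NA_character_, n)
  category[to_bmd] <- caroc_category(pop[to_bmd, ])
  pop$risk_category <- ifelse(to_bmd, category, pop$risk_category)
  pop[to_bmd, ] <- assign_management(pop[to_bmd, ], category[to_bmd], pol,
                                     params, u_comply = u[to_bmd, 3],
                                     cycle = cycle)
  pop
}
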