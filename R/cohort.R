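#' Default age distribution for the simulated population
#'
#' Five-year age bands from 40 to 99 with weights shaped like the female age
#' pyramid of an industrialized country, normalised so that deterministic
#' apportionment of 500,000 women yields exactly 363,042 aged 40-64 and
#' 136,958 aged 65 and over.
#'
#' @return A tibble with columns `age_low`, `age_high`, `weight` (weights sum
#'   to 1).
#' @export
default_age_table <- function() {
  counts <- c(78000, 76000, 74000, 70000, 65042,      # 40-64
              38000, 32000, 26000, 19958, 12500, 6000, 2500) # 65-99
  tibble::tibble(
    age_low = seq(40, 95, by = 5),
    age_high = seq(44, 99, by = 5),
    weight = counts / sum(counts)
  )
}

#' Default T-score model by age
#'
#' The bone-mineral-density distribution is summarised as a T-score that is
#' normal at every age with SD 1 and a mean that declines linearly with age.
#' Slope and intercept are solved from two published prevalence anchors for
#' densitometric osteoporosis (T <= -2.5): about 4% at ages 50-54 and about
#' 45% at ages 85-89.
#'
#' @return A list with `mean_at`, a function of age returning the mean
#'   T-score, plus `slope`, `intercept` and `sd`.
#' @export
default_bmd_model <- function() {
  # anchor band midpoints
  a1 <- 52; p1 <- 0.04
  a2 <- 87; p2 <- 0.45
  mu1 <- -2.5 - qnorm(p1)
  mu2 <- -2.5 - qnorm(p2)
  slope <- (mu2 - mu1) / (a2 - a1)
  intercept <- mu1 - slope * a1
  list(
    mean_at = function(age) intercept + slope * age,
    slope = slope, intercept = intercept, sd = 1
  )
}

# Default age-band prevalences for current behaviours and clinical risk
# factors. The published model states only that prevalent behaviours exist;
# these shapes (activity falling with age, supplement use, prior fragility
# fracture and glucocorticoid exposure rising) are synthetic defaults.
default_behavior_table <- function() {
  ages <- default_age_table()
  mid <- (ages$age_low + ages$age_high) / 2
  tibble::tibble(
    age_low = ages$age_low,
    age_high = ages$age_high,
    p_physically_active = pmax(0.20, 0.55 - 0.006 * (mid - 42)),
    p_vitd_calcium = pmin(0.45, 0.15 + 0.005 * (mid - 42)),
    p_prior_fracture = pmin(0.25, 0.02 + 0.004 * (mid - 42)),
    p_glucocorticoid = pmin(0.06, 0.03 + 0.0005 * (mid - 42))
  )
}

#' Specify a synthetic cohort
#'
#' @param n Number of women at baseline.
#' @param age_table Tibble of `age_low`, `age_high`, `weight`
#'   (default [default_age_table()]).
#' @param bmd_model T-score model as from [default_bmd_model()].
#' @param behavior_table Per-band behaviour and risk-factor prevalences.
#' @param rolling_entry Add a fresh cohort of 40-year-olds each year?
#' @param annual_entry Number of 40-year-old entrants per year when
#'   `rolling_entry` is on.
#' @param entry_window Years over which entrants are added (default 10).
#' @param seed Seed controlling all cohort draws.
#' @return A `osteo_cohort_spec` list.
#' @export
cohort_spec <- function(n, age_table = default_age_table(),
                        bmd_model = default_bmd_model(),
                        behavior_table = default_behavior_table(),
                        rolling_entry = FALSE, annual_entry = 0L,
                        entry_window = 10L, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    abort("n must be a single non-negative number")
  }
  if (nrow(age_table) == 0L) abort("age table is empty")
  if (abs(sum(age_table$weight) - 1) > 1e-8) {
    abort("age-table weights must sum to 1")
  }
  if (bmd_model$sd <= 0) abort("T-score SD must be positive")
  structure(list(n = as.integer(n), age_table = age_table,
                 bmd_model = bmd_model, behavior_table = behavior_table,
                 rolling_entry = isTRUE(rolling_entry),
                 annual_entry = as.integer(annual_entry),
                 entry_window = as.integer(entry_window),
                 seed = as.integer(seed)),
            class = "osteo_cohort_spec")
}

# Deterministic largest-remainder apportionment of n across weights.
apportion <- function(n, weights) {
  quota <- n * weights
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    idx <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

band_index <- function(age, table) {
  findInterval(age, c(table$age_low, max(table$age_high) + 1L))
}

make_women <- function(ids, ages, spec) {
  bm <- spec$bmd_model
  beh <- spec$behavior_table
  bi <- pmin(band_index(ages, beh), nrow(beh))
  z <- rnorm(length(ids))
  tibble::tibble(
    id = as.integer(ids),
    age = as.integer(ages),
    entry_age = as.integer(ages),
    z = z,
    t_score = bm$mean_at(ages) + bm$sd * z,
    prior_fragility_fracture = runif(length(ids)) < beh$p_prior_fracture[bi],
    glucocorticoid_use = runif(length(ids)) < beh$p_glucocorticoid[bi],
    physically_active = runif(length(ids)) < beh$p_physically_active[bi],
    takes_vitd_calcium = runif(length(ids)) < beh$p_vitd_calcium[bi],
    alive = TRUE
  )
}

#' Generate a synthetic cohort of women aged 40 and over
#'
#' Ages are allocated across bands by deterministic largest-remainder
#' apportionment (so printed stratum sizes are exact at the reference
#' population size), then jittered uniformly over the integer ages within
#' each band. T-scores are drawn from the age-dependent normal model; current
#' behaviours and clinical risk factors are independent Bernoulli draws from
#' the band prevalences. Fully reproducible from `spec$seed`.
#'
#' @param spec A `osteo_cohort_spec`.
#' @return A `osteo_cohort` tibble, one row per woman.
#' @export
#' @examples
#' generate_cohort(cohort_spec(100, seed = 7))
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "osteo_cohort_spec"))
  set.seed(spec$seed)
  tab <- spec$age_table
  counts <- apportion(spec$n, tab$weight)
  ages <- integer(0)
  for (b in seq_len(nrow(tab))) {
    if (counts[b] == 0L) next
    band_ages <- tab$age_low[b]:tab$age_high[b]
    drawn <- if (length(band_ages) == 1L) rep(band_ages, counts[b]) else
      sample(band_ages, counts[b], replace = TRUE)
    ages <- c(ages, drawn)
  }
  pop <- make_women(seq_along(ages), ages, spec)
  class(pop) <- c("osteo_cohort", class(pop))
  attr(pop, "spec") <- spec
  pop
}

#' Densitometric osteoporosis
#'
#' @param x A cohort tibble (uses its `t_score` column) or a numeric vector
#'   of T-scores.
#' @return Logical: T-score at or below -2.5 (WHO densitometric definition;
#'   the boundary itself counts as osteoporotic).
#' @export
osteoporotic <- function(x) {
  t <- if (is.data.frame(x)) x$t_score else x
  if (is.null(t) || anyNA(t)) abort("t_score must be set")
  t <= -2.5
}

#' BMD category from T-score
#'
#' @inheritParams osteoporotic
#' @return Character vector: "normal" (T > -1), "low" (-2.5 < T <= -1) or
#'   "osteoporosis" (T <= -2.5).
#' @export
bmd_category <- function(x) {
  t <- if (is.data.frame(x)) x$t_score else x
  dplyr::case_when(t <= -2.5 ~ "osteoporosis",
                   t <= -1 ~ "low",
                   TRUE ~ "normal")
}

# T-score at the current age for a woman whose population percentile is
# fixed: the mean declines with age, the z-score does not.
current_t_score <- function(z, age, bmd_model) {
  bmd_model$mean_at(age) + bmd_model$sd * z
}

#' Add rolling entrants of 40-year-old women
#'
#' Appends the configured annual entry of 40-year-old women for simulation
#' years 1 through `entry_window` (default 10); outside the window, or when
#' rolling entry is disabled, the population is returned unchanged (with a
#' warning in the disabled case).
#'
#' @param population A cohort tibble.
#' @param year Cycle index (1-based year of the simulation).
#' @param spec The `osteo_cohort_spec` used to generate the population.
#' @return The population with entrants appended (unique ids).
#' @export
add_rolling_entrants <- function(population, year, spec) {
  if (!spec$rolling_entry) {
    warn("rolling entry is disabled for this cohort spec; no entrants added")
    return(population)
  }
  if (year < 1 || year > spec$entry_window || spec$annual_entry == 0L) {
    return(population)
  }
  next_id <- max(population$id) + 1L
  entrants <- make_women(next_id:(next_id + spec$annual_entry - 1L),
                         rep(40L, spec$annual_entry), spec)
  extra <- setdiff(names(population), names(entrants))
  if (length(extra)) {
    entrants <- init_state(entrants, entry_cycle = year)
    entrants <- entrants[, names(population)]
  }
  dplyr::bind_rows(population, entrants)
}

#' @export
print.osteo_cohort <- function(x, ...) {
  cat("<osteo_cohort> ", nrow(x), " women, ages ",
      min(x$age), "-", max(x$age), "\n", sep = "")
  NextMethod()
}

#' Export / import a cohort as CSV
#'
#' @param cohort A cohort tibble.
#' @param path CSV file path.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  pop <- readr::read_csv(path, show_col_types = FALSE)
  class(pop) <- c("osteo_cohort", class(pop))
  pop
}
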