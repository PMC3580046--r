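SITES <- c("hip", "vertebral", "wrist")
BMD_CATEGORIES <- c("normal", "low", "osteoporosis")
MAX_AGE <- 110L

#' Default female life table
#'
#' A synthetic Gompertz-Makeham annual death probability for women aged 40 to
#' 110, `q(a) = A + B * exp(C * (a - 40))` capped at 1, with probability 1 at
#' the terminal age so every simulated woman eventually dies. The parameters
#' give roughly 0.1% annual mortality at 40 rising to about 11% at 90 —
#' a plausible stand-in for a modern industrialized-country female life
#' table, which is not part of the published inputs.
#'
#' @return A tibble with columns `age`, `q_death`.
#' @export
default_life_table <- function() {
  age <- 40:MAX_AGE
  q <- pmin(1, 2e-4 + 6e-4 * exp(0.105 * (age - 40)))
  q[age == MAX_AGE] <- 1
  tibble::tibble(age = age, q_death = q)
}

#' Default baseline fracture hazard table
#'
#' Annual first-event fracture probabilities by site, 5-year age band and BMD
#' category. The published model derives these from registry data that are
#' not printed; the default is a smooth synthetic surface: a site-specific
#' exponential-in-age baseline times a BMD-category multiplier (relative risk
#' per category step of about 2.0 for hip, 1.8 for clinical vertebral and
#' 1.5 for wrist). The absolute scale is meant to be set by
#' [calibrate_lifetime_risk()] against lifetime-risk targets.
#'
#' @param multipliers Named numeric site multipliers applied to the whole
#'   surface (default 1 for each site).
#' @return A `osteo_hazard` tibble in long format: `site`, `age_low`,
#'   `age_high`, `bmd_category`, `probability`.
#' @export
default_hazard_table <- function(multipliers = c(hip = 1, vertebral = 1, wrist = 1)) {
  age_low <- seq(40, 105, by = 5)
  base <- tidyr::expand_grid(
    site = SITES,
    tibble::tibble(age_low = age_low, age_high = age_low + 4L),
    bmd_category = BMD_CATEGORIES
  )
  mid <- (base$age_low + base$age_high) / 2
  slope <- c(hip = 0.085, vertebral = 0.055, wrist = 0.028)[base$site]
  h0 <- c(hip = 4e-4, vertebral = 1.2e-3, wrist = 2.2e-3)[base$site]
  grad <- c(hip = 2.0, vertebral = 1.8, wrist = 1.5)[base$site]
  step <- match(base$bmd_category, BMD_CATEGORIES) - 1L
  p <- h0 * exp(slope * (mid - 40)) * grad^step *
    unname(multipliers[base$site])
  base$probability <- unname(pmin(p, 1))
  new_hazard_table(base)
}

new_hazard_table <- function(x) {
  stopifnot(all(c("site", "age_low", "age_high", "bmd_category",
                  "probability") %in% names(x)))
  if (any(x$probability < 0 | x$probability > 1)) {
    abort("hazard probabilities must lie in [0, 1]")
  }
  x <- tibble::as_tibble(x)
  class(x) <- unique(c("osteo_hazard", class(x)))
  x
}

#' Read / write hazard and life tables as CSV
#'
#' Long-format CSV mirrors the in-memory layout (`site`, `age_low`,
#' `age_high`, `bmd_category`, `probability`; life table: `age`, `q_death`).
#'
#' @param x Table to write.
#' @param path CSV path.
#' @return The table (readers) or `path` invisibly (writers).
#' @export
write_hazard_table <- function(x, path) {
  readr::write_csv(x, path); invisible(path)
}

#' @rdname write_hazard_table
#' @export
read_hazard_table <- function(path) {
  new_hazard_table(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname write_hazard_table
#' @export
write_life_table <- function(x, path) {
  readr::write_csv(x, path); invisible(path)
}

#' @rdname write_hazard_table
#' @export
read_life_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

# Dense lookup structures for the engine: hazard as an array
# [age 40..110, category, site]; life table as a vector indexed by age - 39.
hazard_array <- function(hazards) {
  ages <- 40:MAX_AGE
  arr <- array(NA_real_, dim = c(length(ages), length(BMD_CATEGORIES),
                                 length(SITES)),
               dimnames = list(NULL, BMD_CATEGORIES, SITES))
  for (s in SITES) {
    hs <- hazards[hazards$site == s, ]
    for (cat in BMD_CATEGORIES) {
      hc <- hs[hs$bmd_category == cat, ]
      idx <- findInterval(ages, hc$age_low)
      if (any(idx == 0)) abort("hazard table does not cover all ages from 40")
      idx <- pmin(idx, nrow(hc))
      arr[, cat, s] <- hc$probability[idx]
    }
  }
  arr
}

life_vector <- function(life_table) {
  ages <- 40:MAX_AGE
  idx <- match(ages, life_table$age)
  if (anyNA(idx)) abort("life table must cover ages 40 through 110")
  q <- life_table$q_death[idx]
  q[length(q)] <- 1
  q
}

#' Bundle the engine's lookup tables
#'
#' @param hazards Hazard table as from [default_hazard_table()].
#' @param life_table Life table as from [default_life_table()].
#' @param bmd_model T-score model as from [default_bmd_model()].
#' @return A list used by the simulation engine.
#' @export
model_tables <- function(hazards = default_hazard_table(),
                         life_table = default_life_table(),
                         bmd_model = default_bmd_model()) {
  list(hazards = hazards, hazard_arr = hazard_array(hazards),
       life_table = life_table, q_death = life_vector(life_table),
       bmd_model = bmd_model)
}
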