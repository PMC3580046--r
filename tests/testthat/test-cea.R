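res_row <- function(policy, cost, fractures = 0, qalys = 0) {
  tibble::tibble(policy = policy, total_cost = cost,
                 total_fractures = fractures, total_qalys = qalys)
}

test_that("incremental ratios divide cost by effect differences", {
  a <- res_row("A", 100, fractures = 110)
  b <- res_row("B", 150, fractures = 100)
  expect_equal(icer(a, b, "fractures_averted"), 5)
  expect_equal(icer(a, dplyr::mutate(b, total_cost = 100),
                    "fractures_averted"), 0)
  expect_warning(val <- icer(a, dplyr::mutate(b, total_fractures = 110),
                             "fractures_averted"), "undefined")
  expect_true(is.na(val))
})

test_that("strict and extended dominance match the textbook cases", {
  # B costs more and has less effect: strictly dominated
  r <- dplyr::bind_rows(res_row("A", 100, qalys = 10),
                        res_row("B", 120, qalys = 8))
  fr <- rank_and_frontier(r, "qalys")
  expect_equal(fr$status[fr$policy == "B"], "dominated")

  # classic extended dominance: B's ratio (50) exceeds the next (5)
  r2 <- dplyr::bind_rows(res_row("A", 0, qalys = 0),
                         res_row("B", 50, qalys = 1),
                         res_row("C", 60, qalys = 3))
  fr2 <- rank_and_frontier(r2, "qalys")
  expect_equal(fr2$status[fr2$policy == "B"], "extended")
  expect_equal(fr2$icer[fr2$policy == "C"], 20)
})

test_that("the frontier agrees with a brute-force convex-hull oracle", {
  set.seed(61)
  for (i in 1:150) {
    n <- 5
    cost <- runif(n, 0, 100)
    qalys <- runif(n, 0, 10)
    r <- tibble::tibble(policy = LETTERS[1:n], total_cost = cost,
                        total_qalys = qalys, total_fractures = 0)
    fr <- rank_and_frontier(r, "qalys")
    want <- oracle_frontier(cost, qalys)
    got_frontier <- sort(match(fr$policy[fr$status == "frontier"],
                               LETTERS[1:n]))
    expect_equal(got_frontier, sort(want$frontier))
    got_strict <- sort(match(fr$policy[fr$status == "dominated"],
                             LETTERS[1:n]))
    expect_equal(got_strict, sort(want$strict))
    # ratios strictly increase along the frontier
    ic <- fr$icer[!is.na(fr$icer)]
    expect_false(is.unsorted(ic, strictly = TRUE))
  }
})

toy_psa <- function(costs_a, effs_a, costs_b, effs_b) {
  n <- length(costs_a)
  structure(dplyr::bind_rows(
    tibble::tibble(rep = 1:n, stratum = "all", policy = "A",
                   total_cost = costs_a, total_fractures = -effs_a,
                   total_qalys = effs_a),
    tibble::tibble(rep = 1:n, stratum = "all", policy = "B",
                   total_cost = costs_b, total_fractures = -effs_b,
                   total_qalys = effs_b)),
    class = c("osteo_psa", class(tibble::tibble())))
}

test_that("acceptability curves match hand enumeration on a toy PSA", {
  # three replicates, strategy A vs B on QALYs
  psa <- toy_psa(costs_a = c(100, 100, 100), effs_a = c(2, 2, 2),
                 costs_b = c(50, 150, 90), effs_b = c(1, 1, 3))
  # A vs B: d_cost = (50, -50, 10); d_eff = (1, 1, -1)
  # lambda 0:   NMB = -d_cost = (-50, 50, -10)        -> 1/3
  # lambda 60:  NMB = (10, 110, -70)                  -> 2/3
  # lambda 1e6: sign of d_eff                         -> 2/3
  cc <- acceptability(psa, "A", "B", lambda = c(0, 60, 1e6),
                      effect = "qalys")
  expect_equal(cc$probability, c(1 / 3, 2 / 3, 2 / 3))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))

  # complementarity of a two-strategy comparison
  rev <- acceptability(psa, "B", "A", lambda = c(0, 60, 1e6),
                       effect = "qalys")
  expect_equal(cc$probability + rev$probability, rep(1, 3))
})

test_that("identical strategies give probability one half (tie rule)", {
  psa <- toy_psa(costs_a = c(10, 10), effs_a = c(1, 1),
                 costs_b = c(10, 10), effs_b = c(1, 1))
  cc <- acceptability(psa, "A", "B", lambda = c(0, 50000), effect = "qalys")
  expect_equal(cc$probability, c(0.5, 0.5))
})

test_that("PSA replicates differ, are reproducible, and stack correctly", {
  spec <- cohort_spec(300, seed = 3)
  psa <- run_psa(c("Status quo", "Physical activity"), 3, spec, seed = 21)
  expect_equal(nrow(psa[psa$stratum == "all", ]), 6)
  costs <- psa$total_cost[psa$stratum == "all" & psa$policy == "Status quo"]
  expect_equal(length(unique(costs)), 3)  # parameters re-drawn per replicate
  psa2 <- run_psa(c("Status quo", "Physical activity"), 3, spec, seed = 21)
  expect_identical(tibble::as_tibble(psa), tibble::as_tibble(psa2))

  one <- run_psa("Status quo", 1, spec, seed = 22)
  expect_equal(unique(one$rep), 1)
})

test_that("one-way sensitivity analysis reports the range endpoints", {
  spec <- cohort_spec(250, seed = 5)
  sa <- one_way_sa("p_participation", "BMD/CAROC + physical activity",
                   "Status quo", spec, seed = 6)
  expect_equal(sa$level, c("low", "base", "high"))
  expect_equal(sa$value, c(0.30, 0.531, 0.70))
  expect_true(all(is.finite(sa$icer) | is.na(sa$icer)))
  expect_error(one_way_sa("c_dxa", "Status quo", "Physical activity", spec),
               "range")
})
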