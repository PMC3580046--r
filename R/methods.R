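#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   labs scale_y_continuous theme_minimal
#' @export
ggplot2::autoplot

#' Tidy / summarise simulation objects
#'
#' `tidy()` on a simulation returns the per-woman outcome table; `glance()`
#' a one-row summary. On a frontier, `tidy()` returns the ranked strategy
#' table. On a PSA, `tidy()` returns the replicate-level results.
#'
#' @param x A `osteo_sim`, `osteo_frontier`, `osteo_psa` or `osteo_ceac`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.osteo_sim <- function(x, ...) {
  dplyr::select(x$population, "id", "entry_age", "age", "died_cycle",
                "n_hip", "n_vert", "n_wrist",
                dplyr::starts_with("cum_"))
}

#' @rdname tidy.osteo_sim
#' @export
glance.osteo_sim <- function(x, ...) {
  aggregate_results(x, strata = FALSE)
}

#' @rdname tidy.osteo_sim
#' @export
tidy.osteo_frontier <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.osteo_sim
#' @export
tidy.osteo_psa <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.osteo_sim
#' @export
tidy.osteo_ceac <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot an acceptability curve
#'
#' @param object A `osteo_ceac`.
#' @param ... Unused.
#' @return A ggplot: probability cost-effective against the ceiling ratio.
#' @export
autoplot.osteo_ceac <- function(object, ...) {
  eff <- attr(object, "effect_measure")
  ggplot(tibble::as_tibble(object), aes(x = .data$lambda,
                                        y = .data$probability)) +
    geom_line() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = paste0("Ceiling ratio ($CAD per ",
                    if (identical(eff, "qalys")) "QALY gained"
                    else "fracture averted", ")"),
         y = "Probability cost-effective",
         title = paste0(attr(object, "strategy"), " vs ",
                        attr(object, "comparator"))) +
    theme_minimal()
}

#' Plot the cost-effectiveness plane and frontier
#'
#' @param object A `osteo_frontier`.
#' @param ... Unused.
#' @return A ggplot: every strategy on the cost-effect plane, the frontier
#'   drawn through the non-dominated ones.
#' @export
autoplot.osteo_frontier <- function(object, ...) {
  d <- tibble::as_tibble(object)
  front <- d[d$status == "frontier", ]
  ggplot(d, aes(x = .data$effect, y = .data$cost)) +
    geom_line(data = front, colour = "grey40") +
    geom_point(aes(colour = .data$status)) +
    labs(x = paste0("Effect (",
                    if (identical(attr(object, "effect_measure"), "qalys"))
                      "QALYs" else "-fractures", ")"),
         y = "Total cost ($CAD)", colour = NULL) +
    theme_minimal()
}

#' @rdname autoplot.osteo_ceac
#' @param x A `osteo_ceac`.
#' @export
plot.osteo_ceac <- function(x, ...) print(autoplot(x, ...))

#' @rdname autoplot.osteo_frontier
#' @param x A `osteo_frontier`.
#' @export
plot.osteo_frontier <- function(x, ...) print(autoplot(x, ...))
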