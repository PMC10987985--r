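#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sensitivity report as a grouped bar chart
#'
#' One bar per surgical parameter and output time point, signed: positive
#' bars mean the CI change grows with the parameter.
#'
#' @param object A `sensitivity_report` from [local_sensitivity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$output <- factor(df$output, levels = unique(df$output))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter,
                                   y = .data$sensitivity_pct,
                                   fill = .data$output)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "signed sensitivity of ΔCI (%)",
                  fill = "time point") +
    ggplot2::theme_minimal()
}

#' Plot a spring-position response map
#'
#' CI change over the (A%, B%) plane at mid-range osteotomy distance and
#' stiffness, with the optimum marked.
#'
#' @param object An `optimum_map` from [optimum_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optimum_map <- function(object, ...) {
  opt <- attr(object, "optimum")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$a_pct, y = .data$b_pct,
                               fill = .data$dci)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = opt, shape = 21, size = 3, fill = "white") +
    ggplot2::scale_fill_viridis_c(name = "ΔCI (points)") +
    ggplot2::labs(x = "A% (anterior spring position)",
                  y = "B% (spring separation)",
                  title = attr(object, "output")) +
    ggplot2::theme_minimal()
}

#' Plot spring opening and force histories
#'
#' @param object An `expansion_result`.
#' @param ... Unused.
#' @return A ggplot (opening and force vs time, one line per spring).
#' @export
autoplot.expansion_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$springs, c("opening_mm", "force_N"),
                            names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 86400,
                                   y = .data$value,
                                   colour = .data$spring)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Top-view plot of the calvarium regions
#'
#' Element centroids in the transverse plane coloured by region label; a
#' quick visual check of suture placement and osteotomy cuts.
#'
#' @param object A `skull_mesh`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.skull_mesh <- function(object, ...) {
  el <- object$elems
  cent <- (object$nodes[el[, 1], ] + object$nodes[el[, 2], ] +
             object$nodes[el[, 3], ] + object$nodes[el[, 4], ]) / 4
  df <- tibble::tibble(x = cent[, 1], y = cent[, 2],
                       region = object$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$region)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (anterior →)", y = "y (left →)") +
    ggplot2::theme_minimal()
}

#' Overlay simulated and cohort CI-change trends
#'
#' Scatter of CI change against one predictor for the simulated design
#' points and a synthetic cohort, each with its least-squares line.
#'
#' @param sim_table A `doe_results` tibble.
#' @param cohort_records A `patient_cohort` tibble.
#' @param predictor,response Column names (see [fit_trend()]).
#' @return A ggplot.
#' @export
plot_trend_overlay <- function(sim_table, cohort_records, predictor,
                               response = "dci_followup") {
  sim <- tibble::as_tibble(sim_table)
  if (!"k_tot" %in% names(sim) && all(c("k_ant", "k_post") %in% names(sim)))
    sim$k_tot <- sim$k_ant + sim$k_post
  if (!"a_plus_b_pct" %in% names(sim) &&
      all(c("a_pct", "b_pct") %in% names(sim)))
    sim$a_plus_b_pct <- sim$a_pct + sim$b_pct
  df <- dplyr::bind_rows(
    tibble::tibble(x = sim[[predictor]], y = sim[[response]],
                   source = "simulated"),
    tibble::tibble(x = cohort_records[[predictor]],
                   y = cohort_records[[response]], source = "cohort")
  )
  df <- df[stats::complete.cases(df), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$source)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = predictor, y = response) +
    ggplot2::theme_minimal()
}
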