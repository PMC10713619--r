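#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hunting-performance series
#'
#' Lines of `h(t)` per strategy/category (when present); ensembles are
#' averaged over runs first.
#'
#' @param perf Output of [hunting_performance()].
#' @return A ggplot object.
#' @export
plot_performance <- function(perf) {
  df <- perf
  groups <- intersect(c("strategy", "category"), names(df))
  if ("run" %in% names(df)) {
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "t")))) |>
      dplyr::summarise(h = mean(.data$h, na.rm = TRUE), .groups = "drop")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$h))
  if (length(groups) == 2L) {
    p <- p + ggplot2::aes(colour = .data$strategy,
                          linetype = .data$category)
  } else if ("strategy" %in% groups) {
    p <- p + ggplot2::aes(colour = .data$strategy)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "t", y = "h(t) [captures per chaser per window]") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chase_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$series, c("n_gcs", "n_dcs"),
                            names_to = "strategy", values_to = "n")
  df$strategy <- ifelse(df$strategy == "n_gcs", "GCS", "DCS")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$n,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t", y = "chasers", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chase_fitness_table <- function(object, max_n = 9L, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$n_G <= max_n, .data$n_D <= max_n) |>
    tidyr::pivot_longer(c("f_G", "f_D"), names_to = "strategy",
                        values_to = "fitness") |>
    dplyr::filter(!is.na(.data$fitness))
  df$strategy <- ifelse(df$strategy == "f_G", "GCS", "DCS")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_G, y = .data$n_D,
                                   fill = .data$fitness)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$fitness)),
                       size = 2.5) +
    ggplot2::facet_wrap(~strategy) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "n_G", y = "n_D") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chase_ensemble <- function(object, ...) {
  fx <- fixation_probability(object)
  ggplot2::ggplot(fx, ggplot2::aes(x = .data$outcome, y = .data$p_fix)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$p_fix - .data$se, 0),
                                        ymax = pmin(.data$p_fix + .data$se, 1)),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "fixation probability") +
    ggplot2::theme_minimal()
}
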