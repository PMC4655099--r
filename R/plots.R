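#' Plot posterior annual occupancy of a fitted species
#'
#' Ribbon of the 95% credible interval of annual occupancy with the
#' posterior mean, plus the posterior-mean linear trend line.
#'
#' @param object An `occu_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occu_fit <- function(object, ...) {
  occ <- annual_occupancy(object)
  slope_m <- mean(object$slope)
  icpt <- mean(colMeans(object$psi)) - slope_m * mean(object$years)
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$prior_only)) +
    ggplot2::geom_abline(intercept = icpt, slope = slope_m,
                         linetype = "dashed") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Year", y = "Annual occupancy",
                  title = object$species,
                  subtitle = sprintf("trend slope %.4f per year", slope_m)) +
    ggplot2::theme_minimal()
}

#' Plot species trend estimates with credible intervals
#'
#' Point-and-interval display of posterior trend slopes, coloured by the
#' bridging-zero classification.
#'
#' @param object A `trend_summary` from [summarize_trends()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_summary <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(species = stats::reorder(.data$species, .data$mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$species,
                                   colour = .data$classification)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::scale_colour_manual(values = c(declining = "firebrick",
                                            increasing = "forestgreen",
                                            uncertain = "grey40")) +
    ggplot2::labs(x = "Occupancy trend (per year)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot trait coefficients from the resampling analysis
#'
#' Mean and 95 percentile interval of each trait coefficient across the
#' resampling iterations (reference categories of categorical traits are
#' fixed at zero and not shown).
#'
#' @param object A `comparative_summary` from [resample_pgls()].
#' @param include_intercept Show the intercept row (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparative_summary <- function(object, include_intercept = FALSE,
                                         ...) {
  df <- object$summary %>%
    filter(.data$term != "lambda")
  if (!include_intercept) df <- filter(df, .data$term != "(Intercept)")
  df <- mutate(df, term = stats::reorder(.data$term, .data$mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "Coefficient (trend units per trait unit)", y = NULL) +
    ggplot2::theme_minimal()
}
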