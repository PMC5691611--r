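#' Plot a TALE run trajectory
#'
#' Fitness trajectory of a feedback-controlled tolerance evolution: the
#' fitted per-flask growth rate and the applied stressor concentration
#' against flask number, with crashed flasks marked. This is the standard
#' view for judging whether escalations tracked fitness recovery.
#'
#' @param object A `tale_run` from [run_tale()].
#' @param ... Unused.
#' @return A ggplot object (two stacked facets: rate and concentration).
#' @method autoplot tale_run
#' @export
autoplot.tale_run <- function(object, ...) {
  log <- object$log
  long <- dplyr::bind_rows(
    tibble(flask_index = log$flask_index, value = log$rate,
           what = "growth rate (/h)", crashed = log$crashed),
    tibble(flask_index = log$flask_index, value = log$concentration,
           what = "concentration (% w/v)", crashed = log$crashed)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$flask_index, y = .data$value)) +
    ggplot2::geom_step(data = ~ dplyr::filter(.x, .data$what == "concentration (% w/v)"),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$crashed), size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                name = "crashed") +
    ggplot2::facet_wrap(~ what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "flask", y = NULL,
                  title = "TALE trajectory: fitness and applied stress") +
    ggplot2::theme_minimal()
}

#' Plot a growth-curve fit
#'
#' Semi-log view of the OD series with the fitted exponential window.
#'
#' @param object A `growth_fit` from [fit_rate()].
#' @param series The OD series the fit came from (tibble `time_h`, `od`);
#'   stored model frame is used when omitted.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, series = NULL, ...) {
  used <- object$model$model
  used <- tibble(time_h = used$time_h, od = exp(used$`log(od)`))
  pts <- if (is.null(series)) used else series
  icpt <- unname(coef(object$model)[1])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_h, y = .data$od)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_function(fun = function(t) exp(icpt + object$rate * t),
                           xlim = object$window, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "OD600 (log scale)",
                  subtitle = sprintf("rate %.3f /h, lag %.1f h",
                                     object$rate, object$lag)) +
    ggplot2::theme_minimal()
}

#' Plot key-mutation recurrence
#'
#' Isolate counts per recurrently mutated region, coloured by category
#' (combined vs strain-specific), mirroring how convergent evolution evidence
#' is usually summarised.
#'
#' @param summaries Output of [identify_key_mutations()].
#' @return A ggplot object.
#' @export
plot_key_mutations <- function(summaries) {
  d <- summaries %>% filter(.data$key)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$region, .data$isolate_count),
    y = .data$isolate_count, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "isolates carrying a mutation",
                  title = "Convergently mutated regions") +
    ggplot2::theme_minimal()
}
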