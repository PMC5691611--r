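#' Tidy a TALE run
#'
#' @param x A `tale_run` from [run_tale()].
#' @param ... Unused.
#' @return The per-flask decision log as a tibble: `flask_index`,
#'   `concentration` (% w/v in that flask), fitted `rate` (/h), `crashed`,
#'   `final_od`, `od_start`, `od_end`, `duration_h`.
#' @method tidy tale_run
#' @export
tidy.tale_run <- function(x, ...) {
  x$log
}

#' @rdname tidy.tale_run
#' @return `glance()` returns a one-row run summary: `n_flasks`,
#'   `start_conc`, `final_conc`, `n_increases`, `n_crashes`, `mean_rate`,
#'   `ccd` (cumulative cell divisions over non-crashed flasks).
#' @method glance tale_run
#' @export
glance.tale_run <- function(x, ...) {
  grown <- x$log %>% filter(!.data$crashed, .data$od_end >= .data$od_start)
  ccd <- if (nrow(grown) > 0) {
    compute_ccd(grown %>% select(od_start = "od_start", od_end = "od_end"))$ccd
  } else 0
  tibble(
    n_flasks = nrow(x$log),
    start_conc = x$start_conc,
    final_conc = x$state$current_conc,
    n_increases = x$state$n_increases,
    n_crashes = x$state$n_crashes,
    mean_rate = mean(x$log$rate, na.rm = TRUE),
    ccd = ccd
  )
}

#' Tidy a growth-curve fit
#'
#' @param x A `growth_fit` from [fit_rate()].
#' @param ... Unused.
#' @return `tidy()` gives the regression terms (intercept and rate with
#'   standard errors); `glance()` a one-row metric summary (`rate`,
#'   `rate_se`, `lag`, `final_od`, `r.squared`, `n`).
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))$coefficients
  tibble(
    term = c("log_od_intercept", "rate"),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"])
  )
}

#' @rdname tidy.growth_fit
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    rate = x$rate, rate_se = x$rate_se, lag = x$lag, final_od = x$final_od,
    r.squared = suppressWarnings(summary(x$model))$r.squared, n = x$n
  )
}

#' Tidy a cumulative-cell-division result
#'
#' @param x A `ccd_result` from [compute_ccd()].
#' @param ... Unused.
#' @return One row per flask with its division count and the running total.
#' @method tidy ccd_result
#' @export
tidy.ccd_result <- function(x, ...) {
  tibble(
    flask = seq_along(x$per_flask),
    divisions = x$per_flask,
    cumulative = cumsum(x$per_flask)
  )
}

#' @rdname tidy.ccd_result
#' @method glance ccd_result
#' @export
glance.ccd_result <- function(x, ...) {
  tibble(ccd = x$ccd, n_flasks = length(x$per_flask))
}
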