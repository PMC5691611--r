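#' Configure the TALE feedback controller
#'
#' The controller decides, flask by flask, when to passage a culture, when to
#' raise the stressor concentration, and how to back off after an
#' over-stressed crash. Defaults follow the automated ionic-liquid tolerance
#' platform this package models: passage at plate OD600 0.3, 1:100 transfers,
#' escalation once the fitted growth rate has held >= 0.15/h, and 0.75 % w/v
#' concentration steps.
#'
#' @param passage_od Plate-reader OD600 threshold triggering a passage.
#' @param dilution Transfer ratio at each passage (0.01 = 1:100).
#' @param rate_threshold Fitted growth rate (/h) a flask must reach to count
#'   towards an escalation.
#' @param window_flasks Consecutive qualifying flasks (at the current
#'   concentration) required before the concentration is raised. The source
#'   platform only specifies "a defined period of time"; 3 flasks matches how
#'   its endpoint rates are reported (first/last 3 flasks of each population).
#' @param step_pct Concentration increment per escalation (% w/v).
#' @param step_reduction Multiplicative factor applied to the step after a
#'   crash (in (0, 1)); "a smaller step change" is unquantified at source, so
#'   halving is the package default.
#' @param crash_timeout_h Hours without reaching `passage_od` that define a
#'   crash (growth "ceased").
#' @param max_flasks Run-length cap.
#' @param od_min,od_max Plate-OD window handed to [fit_rate()].
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(passage_od = 0.3,
                              dilution = 0.01,
                              rate_threshold = 0.15,
                              window_flasks = 3L,
                              step_pct = 0.75,
                              step_reduction = 0.5,
                              crash_timeout_h = 72,
                              max_flasks = 70L,
                              od_min = 0.01,
                              od_max = passage_od) {
  stopifnot(passage_od > 0, dilution > 0, dilution < 1,
            rate_threshold >= 0, window_flasks >= 1,
            step_pct > 0, step_reduction > 0, step_reduction < 1,
            crash_timeout_h > 0, max_flasks >= 1)
  structure(
    list(passage_od = passage_od, dilution = dilution,
         rate_threshold = rate_threshold,
         window_flasks = as.integer(window_flasks),
         step_pct = step_pct, step_reduction = step_reduction,
         crash_timeout_h = crash_timeout_h,
         max_flasks = as.integer(max_flasks),
         od_min = od_min, od_max = od_max),
    class = "controller_config"
  )
}

new_controller_state <- function(start_conc) {
  stopifnot(start_conc >= 0)
  structure(
    list(current_conc = start_conc, previous_conc = start_conc,
         current_step = NA_real_,  # filled from config on first use
         n_increases = 0L, n_crashes = 0L,
         flask_log = tibble(flask_index = integer(), concentration = numeric(),
                            rate = numeric(), crashed = logical())),
    class = "controller_state"
  )
}

#' Should this culture be passaged?
#'
#' TRUE once the latest plate-reader OD600 has reached the passage threshold.
#'
#' @param series Data frame with strictly increasing `time_h` and `od`
#'   (plate-reader units).
#' @param config A [controller_config()].
#' @return Logical scalar.
#' @examples
#' should_pass(tibble::tibble(time_h = 0:2, od = c(0.1, 0.2, 0.31)),
#'             controller_config())
#' @export
should_pass <- function(series, config) {
  stopifnot(is.data.frame(series), all(c("time_h", "od") %in% names(series)))
  if (nrow(series) == 0 || any(diff(series$time_h) <= 0)) {
    abort("time_h must be non-empty and strictly increasing",
          class = "talesim_domain_error")
  }
  tail(series$od, 1) >= config$passage_od
}

#' One feedback decision of the TALE controller
#'
#' Pure state update applied after every flask. A crash reverts the
#' concentration to the last concentration at which growth succeeded and
#' shrinks the step; otherwise, if the last `window_flasks` fitted rates (all
#' obtained at the current concentration) meet the rate threshold, the
#' concentration is raised by the current step; otherwise nothing changes.
#'
#' @param state A controller state (as produced by [run_tale()] or internally).
#' @param latest_rates Fitted growth rates (/h) of the consecutive flasks at
#'   the current concentration, oldest first.
#' @param crashed Did the latest flask crash?
#' @param config A [controller_config()].
#' @return The updated state.
#' @examples
#' st <- talesim:::new_controller_state(1.5)
#' cfg <- controller_config(window_flasks = 2)
#' next_concentration(st, c(0.20, 0.31), FALSE, cfg)$current_conc  # 2.25
#' @export
next_concentration <- function(state, latest_rates, crashed, config) {
  stopifnot(inherits(state, "controller_state"))
  if (is.na(state$current_step)) state$current_step <- config$step_pct
  if (isTRUE(crashed)) {
    state$current_conc <- state$previous_conc
    state$current_step <- state$current_step * config$step_reduction
    state$n_crashes <- state$n_crashes + 1L
  } else if (length(latest_rates) >= config$window_flasks &&
             all(!is.na(tail(latest_rates, config$window_flasks))) &&
             all(tail(latest_rates, config$window_flasks) >=
                 config$rate_threshold)) {
    state$previous_conc <- state$current_conc
    state$current_conc <- state$current_conc + state$current_step
    state$n_increases <- state$n_increases + 1L
  }
  state
}

#' Run a closed-loop TALE experiment
#'
#' Iterates flask -> passage/crash detection -> semi-log rate fit ->
#' concentration decision -> bottleneck until the flask cap. The culture is
#' either the stochastic simulator ([sim_culture()]) or a recorded OD stream
#' ([recorded_culture()]); replaying a recorded stream reproduces the decision
#' log exactly.
#'
#' @param culture A [sim_culture()] or [recorded_culture()].
#' @param config A [controller_config()].
#' @param start_conc Starting stressor concentration (% w/v, >= 0).
#' @param seed Root seed for the run; each flask draws from a child stream
#'   derived by counter, so results do not depend on evaluation order.
#'   Defaults to the simulator config's own seed for a [sim_culture()]
#'   (identical configs then give byte-identical runs) and 1 otherwise.
#' @return An object of class `tale_run`: `state` (final controller state),
#'   `log` (tibble: flask_index, concentration, rate, crashed, final_od,
#'   od_start, od_end, duration_h), `flasks` (list of per-flask OD series),
#'   `final_lineages` (simulator cultures only), plus the configs. Use
#'   [tidy()], [glance()] and [autoplot()] on it.
#' @details After a crash the population is restarted from the pre-crash
#'   snapshot (the frozen stock of the previous flask), the concentration is
#'   reverted, and the escalation window starts afresh. Escalations apply to
#'   the next flask's medium, never mid-flask.
#' @examples
#' culture <- recorded_culture(rep(list(
#'   tibble::tibble(time_h = seq(0, 16, 0.5),
#'                  od = 0.003 * exp(0.3 * seq(0, 16, 0.5)))), 10))
#' run <- run_tale(culture, controller_config(window_flasks = 2, max_flasks = 10),
#'                 start_conc = 1.5)
#' glance(run)
#' @export
run_tale <- function(culture, config = controller_config(),
                     start_conc = 1.5, seed = NULL) {
  stopifnot(inherits(culture, "tale_culture"))
  if (is.null(seed)) {
    seed <- if (inherits(culture, "sim_culture")) culture$config$seed else 1L
  }
  state <- new_controller_state(start_conc)
  state$current_step <- config$step_pct
  rates_window <- numeric(0)
  flasks <- vector("list", config$max_flasks)
  log_rows <- vector("list", config$max_flasks)

  for (i in seq_len(config$max_flasks)) {
    set.seed(child_seed(seed, i))
    fl <- next_flask(culture, state$current_conc, config, i)
    culture <- fl$culture

    rate <- tryCatch(
      fit_rate(fl$od_series, config$od_min, config$od_max)$rate,
      talesim_insufficient_data = function(e) NA_real_
    )
    conc_before <- state$current_conc
    rates_window <- c(rates_window, rate)
    state <- next_concentration(state, rates_window, fl$crashed, config)
    if (fl$crashed || state$current_conc != conc_before) {
      rates_window <- numeric(0)
      if (fl$crashed) culture <- revert_culture(culture)
    }

    log_rows[[i]] <- tibble(
      flask_index = i, concentration = conc_before, rate = rate,
      crashed = fl$crashed, final_od = max(fl$od_series$od),
      od_start = fl$od_series$od[1], od_end = tail(fl$od_series$od, 1),
      duration_h = tail(fl$od_series$time_h, 1)
    )
    flasks[[i]] <- fl$od_series
  }

  state$flask_log <- bind_rows(log_rows)
  structure(
    list(state = state, log = state$flask_log, flasks = flasks,
         final_lineages = culture_lineages(culture),
         config = config, start_conc = start_conc, seed = seed),
    class = "tale_run"
  )
}

#' @export
print.tale_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<tale_run> %d flasks: %.3g -> %.3g %% w/v (%d increases, %d crashes)\n",
    g$n_flasks, g$start_conc, g$final_conc, g$n_increases, g$n_crashes))
  invisible(x)
}

# ---- culture abstraction ----------------------------------------------------

#' Cultures driven by the TALE controller
#'
#' `sim_culture()` wraps the stochastic lineage simulator; `recorded_culture()`
#' replays a fixed list of OD series (one per flask), e.g. exported from a
#' real experiment. Both can be handed to [run_tale()].
#'
#' @param config A [sim_config()].
#' @param lineages Optional starting lineage tibble; defaults to
#'   [founding_population()].
#' @return A culture object (class `tale_culture`).
#' @export
sim_culture <- function(config, lineages = founding_population(config)) {
  structure(list(config = config, lineages = lineages, snapshot = lineages),
            class = c("sim_culture", "tale_culture"))
}

#' @rdname sim_culture
#' @param series_list List of OD series (tibbles with `time_h`, `od` in
#'   plate-reader units), consumed one per flask.
#' @export
recorded_culture <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1)
  structure(list(series_list = series_list, cursor = 0L),
            class = c("recorded_culture", "tale_culture"))
}

next_flask <- function(culture, concentration, config, flask_index) {
  UseMethod("next_flask")
}

#' @export
next_flask.sim_culture <- function(culture, concentration, config, flask_index) {
  fl <- simulate_flask(culture$lineages, concentration, culture$config,
                       passage_od = config$passage_od,
                       timeout_h = config$crash_timeout_h,
                       flask_index = flask_index)
  culture$snapshot <- culture$lineages  # pre-flask frozen stock
  culture$lineages <- if (fl$crashed) fl$lineages else
    bottleneck(fl$lineages, config$dilution, culture$config)
  if (nrow(culture$lineages) == 0) culture$lineages <- culture$snapshot
  list(od_series = fl$od_series, crashed = fl$crashed, culture = culture)
}

#' @export
next_flask.recorded_culture <- function(culture, concentration, config,
                                        flask_index) {
  culture$cursor <- culture$cursor + 1L
  if (culture$cursor > length(culture$series_list)) {
    abort("recorded culture stream ended mid-run",
          class = "talesim_partial_log",
          cursor = culture$cursor - 1L)
  }
  series <- culture$series_list[[culture$cursor]]
  crashed <- !should_pass(series, config) &&
    tail(series$time_h, 1) >= config$crash_timeout_h
  list(od_series = series, crashed = crashed, culture = culture)
}

revert_culture <- function(culture) UseMethod("revert_culture")
#' @export
revert_culture.sim_culture <- function(culture) {
  culture$lineages <- culture$snapshot
  culture
}
#' @export
revert_culture.recorded_culture <- function(culture) culture

culture_lineages <- function(culture) {
  if (inherits(culture, "sim_culture")) culture$lineages else NULL
}
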