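#' Stress-dependent growth rate of a lineage
#'
#' Dose-response stand-in for stressor toxicity: the rate declines from
#' `r_max` at zero stress to zero at the lineage's tolerance,
#' `r = r_max * max(0, 1 - (C / tolerance)^hill)`. Above tolerance growth
#' ceases entirely.
#'
#' @param lineages A lineage tibble (see [founding_population()]) or a numeric
#'   vector of tolerances.
#' @param concentration Stressor concentration (% w/v, >= 0, scalar).
#' @param config A [sim_config()].
#' @return Growth rate(s), per hour, one per lineage.
#' @examples
#' growth_rate_of(3.0, 1.5, sim_config())  # half of r_max at hill = 1
#' @export
growth_rate_of <- function(lineages, concentration, config) {
  if (length(concentration) != 1 || is.na(concentration) || concentration < 0) {
    abort("concentration must be a single non-negative number",
          class = "talesim_domain_error")
  }
  tol <- if (is.data.frame(lineages)) lineages$tolerance else lineages
  config$r_max * pmax(0, 1 - (concentration / tol)^config$hill)
}

# inverse-CDF draw of division-weighted arrival times within (0, t_end):
# divisions up to t are proportional to exp(r t) - 1
draw_arrival_times <- function(n, r, t_end) {
  u <- runif(n)
  if (r <= 0) return(u * t_end)
  log(1 + u * (exp(r * t_end) - 1)) / r
}

# spawn child lineages for one parent: each arrival becomes a new lineage
# carrying the parent's mutations plus one new uniquely-labelled allele,
# grown deterministically from its arrival time to the end of the flask
spawn_mutants <- function(parent, n, regions, tol_factors, concentration,
                          config, flask_index, offset) {
  if (n == 0) return(NULL)
  t_end <- attr(n, "t_end")
  r_parent <- attr(n, "rate")
  arrivals <- draw_arrival_times(n, r_parent, t_end)
  types <- sample(names(config$mutation_type_probs), n, replace = TRUE,
                  prob = config$mutation_type_probs)
  # random tag keeps alleles distinct across independently evolved
  # populations, which reuse flask indices under different root seeds
  alleles <- sprintf("%s|f%d.%d.%06d|%s", regions, flask_index,
                     offset + seq_len(n),
                     sample.int(999999L, n, replace = TRUE), types)
  tol <- parent$tolerance * tol_factors
  rates <- growth_rate_of(tol, concentration, config)
  tibble(
    id = sprintf("%s.f%d.%d", parent$id, flask_index, offset + seq_len(n)),
    tolerance = tol,
    size = exp(rates * (t_end - arrivals)),
    mutations = purrr::map(alleles, ~ c(parent$mutations[[1]], .x))
  )
}

#' Simulate one exponential batch culture between passages
#'
#' Each lineage grows deterministically at its stress-dependent rate;
#' beneficial and neutral mutations arrive as Poisson processes proportional
#' to the new divisions in each lineage, spawning child lineages. The flask
#' ends when the whole-culture plate-reader OD reaches the passage threshold,
#' or crashes if the threshold is not reached within the timeout.
#'
#' @param lineages Lineage tibble (non-empty, positive total size).
#' @param concentration Stressor concentration in this flask (% w/v).
#' @param config A [sim_config()].
#' @param passage_od Plate-reader OD600 triggering a passage (default 0.3).
#' @param timeout_h Hours without reaching `passage_od` that define a crash.
#' @param flask_index Ordinal used to label new alleles and OD rows.
#' @param sample_every_h Interval between simulated OD reads (h).
#' @return A list of class `flask_result`: `flask_index`, `concentration`,
#'   `od_series` (tibble `time_h`, `od`; plate units, with measurement noise
#'   per `config$od_noise_sd`), `lineages` (end-of-flask snapshot, before any
#'   bottleneck), `crashed`, `duration_h`.
#' @details Beneficial arrivals are Poisson with mean `mu_b` x divisions and
#'   land in a uniformly drawn causal region, multiplying tolerance by a
#'   shifted-exponential draw with mean `effect_mean`; neutral arrivals use
#'   `mu_n` and the neutral regions, leaving tolerance unchanged. Mutant
#'   counts use a normal approximation above Poisson mean 1e6.
#' @export
simulate_flask <- function(lineages, concentration, config,
                           passage_od = 0.3, timeout_h = 72,
                           flask_index = 1L, sample_every_h = 0.5) {
  if (!is.data.frame(lineages) || nrow(lineages) == 0) {
    abort("lineages must be a non-empty lineage tibble",
          class = "talesim_domain_error")
  }
  if (sum(lineages$size) <= 0) {
    abort("total initial cell count must be positive",
          class = "talesim_domain_error")
  }
  rates <- growth_rate_of(lineages, concentration, config)
  sizes0 <- lineages$size
  od_unit_cells <- plate_to_benchtop(1) * config$cells_per_od * config$volume_ml
  target_cells <- passage_od * od_unit_cells

  total_at <- function(t) sum(sizes0 * exp(rates * t))
  crashed <- total_at(timeout_h) < target_cells
  duration <- if (crashed) timeout_h else {
    if (total_at(0) >= target_cells) 0 else
      uniroot(function(t) total_at(t) - target_cells,
              lower = 0, upper = timeout_h, tol = 1e-9)$root
  }

  times <- unique(c(seq(0, duration, by = sample_every_h), duration))
  od_true <- vapply(times, total_at, numeric(1)) / od_unit_cells
  od_read <- od_true
  if (config$od_noise_sd > 0) {
    od_read <- pmax(0, od_true + rnorm(length(times), 0, config$od_noise_sd))
  }

  sizes_end <- sizes0 * exp(rates * duration)
  divisions <- sizes_end - sizes0

  new_lineages <- list()
  offset <- 0L
  for (k in seq_len(nrow(lineages))) {
    if (divisions[k] <= 0) next
    parent <- lineages[k, ]
    for (kind in c("b", "n")) {
      mu <- if (kind == "b") config$mu_b else config$mu_n
      lambda <- mu * divisions[k]
      if (lambda == 0) next
      n <- if (lambda > 1e6) {
        max(0L, round(rnorm(1, lambda, sqrt(lambda))))
      } else rpois(1, lambda)
      if (n == 0) next
      attr(n, "t_end") <- duration
      attr(n, "rate") <- rates[k]
      if (kind == "b") {
        regions <- sample(config$causal_regions, n, replace = TRUE)
        tol_factors <- 1 + rexp(n, rate = 1 / (config$effect_mean - 1))
      } else {
        regions <- sample(config$neutral_regions, n, replace = TRUE)
        tol_factors <- rep(1, n)
      }
      new_lineages[[length(new_lineages) + 1L]] <-
        spawn_mutants(parent, n, regions, tol_factors, concentration,
                      config, flask_index, offset)
      offset <- offset + n
    }
  }

  end_state <- lineages
  end_state$size <- sizes_end
  if (length(new_lineages) > 0) {
    end_state <- bind_rows(end_state, bind_rows(new_lineages))
  }

  structure(
    list(flask_index = flask_index,
         concentration = concentration,
         od_series = tibble(time_h = times, od = od_read),
         lineages = end_state,
         crashed = crashed,
         duration_h = duration),
    class = "flask_result"
  )
}

#' @export
print.flask_result <- function(x, ...) {
  cat(sprintf("<flask_result #%d> %.3g %% w/v, %s after %.1f h, %d lineages\n",
              x$flask_index, x$concentration,
              if (x$crashed) "crashed" else "passaged",
              x$duration_h, nrow(x$lineages)))
  invisible(x)
}

#' Serial-passage bottleneck
#'
#' Transfers each lineage through a dilution bottleneck: the transferred cell
#' count is binomial with success probability equal to the dilution ratio
#' (normal approximation above variance 1e6). Lineages reduced to zero cells
#' are dropped -- this is the drift that small beneficial lineages must
#' survive to establish.
#'
#' @param lineages Lineage tibble.
#' @param dilution Transfer ratio in (0, 1]; 0.01 models a 1:100 passage.
#' @param config A [sim_config()] (unused sizes are taken from `lineages`).
#' @return The post-bottleneck lineage tibble.
#' @export
bottleneck <- function(lineages, dilution, config = NULL) {
  if (length(dilution) != 1 || dilution <= 0 || dilution > 1) {
    abort("dilution must be a single ratio in (0, 1]",
          class = "talesim_domain_error")
  }
  if (dilution == 1) return(lineages)
  n0 <- round(lineages$size)
  v <- n0 * dilution * (1 - dilution)
  big <- v > 1e6  # normal approximation where exact binomial overflows
  transferred <- numeric(length(n0))
  if (any(big)) {
    transferred[big] <- pmax(0, round(rnorm(sum(big), n0[big] * dilution,
                                            sqrt(v[big]))))
  }
  if (any(!big)) {
    transferred[!big] <- rbinom(sum(!big), n0[!big], dilution)
  }
  out <- lineages
  out$size <- as.numeric(transferred)
  out[out$size > 0, , drop = FALSE]
}

#' Sample endpoint isolates and emit their mutation tables
#'
#' Emulates plating an endpoint population and picking colonies: `n` isolates
#' are drawn with probability proportional to lineage size (with
#' replacement), and every mutation carried by the drawn lineage becomes one
#' record in a breseq-style mutation table.
#'
#' @param final_lineages Lineage tibble with positive total size.
#' @param n Number of isolates to draw (>= 1).
#' @param seed RNG seed for the draw.
#' @param strain,population Labels stamped on the emitted records.
#' @return A tibble of mutation records with columns `strain`, `population`,
#'   `isolate`, `region`, `position`, `mutation_type`, `description`.
#'   Wild-type isolates (no mutations) contribute zero rows but still consume
#'   an isolate label.
#' @export
sample_isolates <- function(final_lineages, n, seed = 1L,
                            strain = "SIM", population = "pop1") {
  if (n < 1) abort("n must be >= 1", class = "talesim_domain_error")
  if (!is.data.frame(final_lineages) || nrow(final_lineages) == 0 ||
      sum(final_lineages$size) <= 0) {
    abort("final lineages must have positive total size",
          class = "talesim_domain_error")
  }
  set.seed(seed)
  idx <- sample.int(nrow(final_lineages), n, replace = TRUE,
                    prob = final_lineages$size)
  template <- tibble(strain = character(), population = character(),
                     isolate = character(), region = character(),
                     position = numeric(), mutation_type = character(),
                     description = character())
  rows <- purrr::map_dfr(seq_len(n), function(j) {
    muts <- final_lineages$mutations[[idx[j]]]
    if (length(muts) == 0) return(template)
    parts <- strsplit(muts, "|", fixed = TRUE)
    tibble(
      strain = strain,
      population = population,
      isolate = sprintf("%s.%s.i%02d", strain, population, j),
      region = vapply(parts, `[[`, "", 1),
      # synthetic coordinate derived from the allele label: stable, 1-based
      position = vapply(parts, function(p)
        sum(utf8ToInt(p[[2]])) %% 99991L + 1L, numeric(1)),
      mutation_type = vapply(parts, `[[`, "", 3),
      description = vapply(parts, `[[`, "", 2)
    )
  })
  if (nrow(rows) == 0) template else rows
}
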