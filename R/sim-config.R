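#' Configure the serial-passage evolution simulator
#'
#' The simulator is a lineage-level stand-in for a wet-lab tolerance evolution:
#' cultures grow exponentially between passages with a stress-dependent rate,
#' beneficial mutations arrive during cell divisions and raise the tolerance of
#' the lineage that acquires them, and 1:100 bottlenecks at each passage impose
#' drift. Scales (starting concentrations, growth rates) are anchored to the
#' benchtop ranges of the ionic-liquid tolerance experiments the package's
#' fixtures transcribe.
#'
#' @param r_max Maximal (unstressed) growth rate, per hour.
#' @param ic50_wt Wild-type zero-growth stressor concentration (% w/v): the
#'   dose at which growth ceases entirely for an unevolved lineage.
#' @param hill Shape exponent of the dose-response; 1 gives a linear decline
#'   of rate with concentration up to the zero-growth point.
#' @param mu_b Beneficial mutation rate per cell division. Beneficial hits land
#'   in causal regions and multiply the lineage's tolerance. The default
#'   (2e-11) puts a ~2e10-division flask in the supply-limited regime
#'   (~0.4 candidate tolerance mutations per flask), which reproduces the
#'   stepwise fitness trajectories and occasional crash-and-retreat of real
#'   tolerance evolutions rather than a mutational free-for-all.
#' @param effect_mean Mean multiplicative tolerance increase per beneficial
#'   mutation (> 1). Effects are drawn from a shifted exponential with this
#'   mean, giving diminishing-returns stepwise trajectories.
#' @param mu_n Neutral mutation rate per cell division; neutral hits land in
#'   decoy regions and leave tolerance unchanged.
#' @param causal_regions,neutral_regions Disjoint, non-empty character vectors
#'   of region labels. Defaults: 5 causal, 45 neutral, sized so the
#'   key-mutation detector faces both signal and decoys.
#' @param cells_per_od Cells per mL per benchtop OD600 unit. The study this
#'   package emulates reports no calibration; 1e9 is a standard E. coli figure
#'   and is exposed as a knob rather than asserted.
#' @param volume_ml Culture working volume (mL).
#' @param start_od_plate Plate-reader OD600 immediately after inoculation
#'   (a 1:100 transfer of a culture at the 0.3 passage threshold).
#' @param od_noise_sd Gaussian measurement noise on simulated plate OD reads.
#' @param mutation_type_probs Named probabilities over the SNP/DEL/INS/MOB
#'   vocabulary used to label simulated alleles.
#' @param seed Root RNG seed (integer). Identical configurations (including
#'   the seed) give bit-identical simulations.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$ic50_wt
#' @export
sim_config <- function(r_max = 0.7,
                       ic50_wt = 3.0,
                       hill = 1,
                       mu_b = 2e-11,
                       effect_mean = 1.3,
                       mu_n = 1e-8,
                       causal_regions = sprintf("causal%02d", 1:5),
                       neutral_regions = sprintf("neutral%02d", 1:45),
                       cells_per_od = 1e9,
                       volume_ml = 15,
                       start_od_plate = 0.003,
                       od_noise_sd = 0.002,
                       mutation_type_probs = c(SNP = 0.5, DEL = 0.25,
                                               INS = 0.15, MOB = 0.1),
                       seed = 1L) {
  cfg <- list(
    r_max = r_max, ic50_wt = ic50_wt, hill = hill,
    mu_b = mu_b, effect_mean = effect_mean, mu_n = mu_n,
    causal_regions = causal_regions, neutral_regions = neutral_regions,
    cells_per_od = cells_per_od, volume_ml = volume_ml,
    start_od_plate = start_od_plate, od_noise_sd = od_noise_sd,
    mutation_type_probs = mutation_type_probs,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$r_max > 0, cfg$ic50_wt > 0, cfg$hill > 0,
    cfg$mu_b >= 0, cfg$mu_b < 1, cfg$mu_n >= 0, cfg$mu_n < 1,
    cfg$effect_mean > 1,
    cfg$cells_per_od > 0, cfg$volume_ml > 0, cfg$start_od_plate > 0,
    cfg$od_noise_sd >= 0
  )
  if (length(cfg$causal_regions) == 0 || length(cfg$neutral_regions) == 0) {
    abort("causal and neutral region sets must both be non-empty",
          class = "talesim_config_error")
  }
  if (length(intersect(cfg$causal_regions, cfg$neutral_regions)) > 0) {
    abort("causal and neutral region sets must be disjoint",
          class = "talesim_config_error")
  }
  if (abs(sum(cfg$mutation_type_probs) - 1) > 1e-8 ||
      !setequal(names(cfg$mutation_type_probs), c("SNP", "DEL", "INS", "MOB"))) {
    abort("mutation_type_probs must be named SNP/DEL/INS/MOB and sum to 1",
          class = "talesim_config_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  r_max %.3g /h, wild-type zero-growth at %.3g %% w/v (hill %g)\n",
              x$r_max, x$ic50_wt, x$hill))
  cat(sprintf("  mu_b %.3g, mu_n %.3g per division; effect mean %.3g\n",
              x$mu_b, x$mu_n, x$effect_mean))
  cat(sprintf("  %d causal / %d neutral regions; %.3g cells/mL/OD in %g mL; seed %d\n",
              length(x$causal_regions), length(x$neutral_regions),
              x$cells_per_od, x$volume_ml, x$seed))
  invisible(x)
}

#' Founding lineage population
#'
#' One wild-type lineage at the inoculation density implied by the
#' configuration: a 1:100 transfer of a culture at plate OD 0.3 into
#' `volume_ml` mL.
#'
#' @param config A [sim_config()].
#' @return A lineage tibble with columns `id`, `tolerance` (% w/v zero-growth
#'   concentration), `size` (cells) and `mutations` (list-column of
#'   `region|allele|type` tokens).
#' @examples
#' founding_population(sim_config())
#' @export
founding_population <- function(config) {
  tibble(
    id = "L0",
    tolerance = config$ic50_wt,
    size = config$start_od_plate * plate_to_benchtop(1) *
      config$cells_per_od * config$volume_ml,
    mutations = list(character(0))
  )
}
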