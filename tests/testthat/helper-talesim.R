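# shared builders for the suite

# exact or noisy exponential OD series
exp_series <- function(rate, od0 = 0.003, t_max = 16, by = 0.5, noise_sd = 0) {
  t <- seq(0, t_max, by = by)
  od <- od0 * exp(rate * t)
  if (noise_sd > 0) od <- od + rnorm(length(t), 0, noise_sd)
  tibble::tibble(time_h = t, od = od)
}

# a lineage tibble from tolerances/sizes (wild-type mutation sets by default)
make_lineages <- function(tolerance, size,
                          mutations = replicate(length(size), character(0),
                                                simplify = FALSE)) {
  tibble::tibble(
    id = sprintf("L%d", seq_along(size)),
    tolerance = tolerance, size = size, mutations = mutations
  )
}

# noiseless, mutation-free simulator config for deterministic growth checks
quiet_config <- function(..., od_noise_sd = 0) {
  sim_config(mu_b = 0, mu_n = 0, od_noise_sd = od_noise_sd, ...)
}

# mutation record tibble from compact per-isolate genotype strings
records_from_genotypes <- function(genotypes, strain = "S", population = "P") {
  purrr::imap_dfr(genotypes, function(muts, iso) {
    if (length(muts) == 0) return(tibble::tibble())
    tibble::tibble(
      strain = strain, population = population, isolate = iso,
      region = sub("\\..*$", "", muts), position = seq_along(muts),
      mutation_type = "SNP", description = muts
    )
  })
}
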