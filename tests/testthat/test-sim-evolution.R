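test_that("dose-response rate declines from r_max to zero at tolerance", {
  cfg <- quiet_config(r_max = 0.7, hill = 1)
  lin <- make_lineages(tolerance = 3.0, size = 1e6)

  expect_equal(growth_rate_of(lin, 0, cfg), 0.7)
  expect_equal(growth_rate_of(lin, 3.0, cfg), 0)
  expect_equal(growth_rate_of(lin, 6.0, cfg), 0)    # clamped above tolerance
  expect_equal(growth_rate_of(lin, 1.5, cfg), 0.35) # linear midpoint

  # monotone non-increasing in concentration for any hill exponent
  for (h in c(0.5, 1, 2, 4)) {
    cfg_h <- quiet_config(hill = h)
    rates <- vapply(seq(0, 5, 0.25), function(cc)
      growth_rate_of(lin, cc, cfg_h), numeric(1))
    expect_true(all(diff(rates) <= 1e-12))
  }

  expect_error(growth_rate_of(lin, -0.1, cfg), class = "talesim_domain_error")
})

test_that("mutation-free flask grows deterministically and exactly", {
  cfg <- quiet_config(r_max = log(2), cells_per_od = 1e9, volume_ml = 15)
  lin <- make_lineages(tolerance = 3.0, size = 1e6)

  # one hour at rate ln 2 with no passage: size doubles exactly
  fl <- simulate_flask(lin, 0, cfg, passage_od = 10, timeout_h = 1)
  expect_true(fl$crashed)  # threshold unreachable in 1 h
  expect_equal(fl$lineages$size, 2e6, tolerance = 1e-12)

  # concentration above tolerance: flat OD, crash
  fl2 <- simulate_flask(lin, 5.0, cfg, passage_od = 0.3, timeout_h = 24)
  expect_true(fl2$crashed)
  expect_equal(diff(range(fl2$od_series$od)), 0)

  # passage triggers at the OD threshold (exact root)
  big <- make_lineages(3.0, size = 0.003 * 4.2 * 1e9 * 15)
  fl3 <- simulate_flask(big, 0, cfg, passage_od = 0.3, timeout_h = 72)
  expect_false(fl3$crashed)
  expect_equal(tail(fl3$od_series$od, 1), 0.3, tolerance = 1e-6)
  expect_equal(fl3$duration_h, log(100) / log(2), tolerance = 1e-6)

  expect_error(simulate_flask(lin[0, ], 0, cfg), class = "talesim_domain_error")
})

test_that("beneficial mutation arrivals follow the Poisson law", {
  # 1e7 divisions at mu_b = 1e-3 -> lambda = 1e4 new lineages
  cfg <- sim_config(mu_b = 1e-3, mu_n = 0, r_max = log(2), od_noise_sd = 0,
                    causal_regions = "causal01", seed = 1)
  lin <- make_lineages(tolerance = 3.0, size = 1e7)
  counts <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    fl <- simulate_flask(lin, 0, cfg, passage_od = 10, timeout_h = 1)
    nrow(fl$lineages) - 1L
  }, numeric(1))
  expect_true(all(abs(counts - 1e4) <= 3 * sqrt(1e4)))
  # mean of 20 runs pins the rate much tighter
  expect_lt(abs(mean(counts) - 1e4), 3 * sqrt(1e4 / 20))
})

test_that("children carry the parent's mutations plus one new causal allele", {
  cfg <- sim_config(mu_b = 1e-4, mu_n = 0, r_max = log(2), od_noise_sd = 0,
                    seed = 1)
  parent <- make_lineages(3.0, size = 1e6, mutations = list(c("causal01|a0|SNP")))
  set.seed(42)
  fl <- simulate_flask(parent, 0, cfg, passage_od = 10, timeout_h = 1)
  kids <- fl$lineages[-1, ]
  expect_gt(nrow(kids), 0)
  for (m in kids$mutations) {
    expect_equal(m[1], "causal01|a0|SNP")
    expect_length(m, 2)
    expect_match(m[2], "^causal[0-9]+\\|")
  }
  # beneficial effects strictly raise tolerance
  expect_true(all(kids$tolerance > 3.0))
})

test_that("bottleneck transfer counts are binomial", {
  lin <- make_lineages(3.0, size = 1e9)

  expect_identical(bottleneck(lin, 1), lin)

  set.seed(7)
  draws <- vapply(1:20, function(i) bottleneck(lin, 0.01)$size, numeric(1))
  sigma <- sqrt(1e9 * 0.01 * 0.99)
  expect_true(all(abs(draws - 1e7) <= 3 * sigma))
  expect_true(all(draws <= 1e9))  # conservation at passage

  # a single cell survives a 1:100 bottleneck about 1% of the time
  single <- make_lineages(3.0, size = 1)
  set.seed(11)
  survived <- vapply(1:1000, function(i) nrow(bottleneck(single, 0.01)),
                     numeric(1))
  p_hat <- mean(survived)
  expect_lt(abs(p_hat - 0.01), 3 * sqrt(0.01 * 0.99 / 1000))

  expect_error(bottleneck(lin, 0), class = "talesim_domain_error")
  expect_error(bottleneck(lin, 1.5), class = "talesim_domain_error")
})

test_that("isolate sampling is frequency-weighted with faithful genotypes", {
  # degenerate sweep: every isolate shows the winner's exact mutation set
  lone <- make_lineages(4.0, size = 1e8,
                        mutations = list(c("causal01|a1|SNP", "causal02|a2|DEL")))
  iso <- sample_isolates(lone, 5, seed = 3)
  expect_equal(nrow(iso), 10)  # 5 isolates x 2 records
  expect_setequal(unique(iso$region), c("causal01", "causal02"))
  expect_equal(dplyr::n_distinct(iso$isolate), 5)

  # 90/10 mixture: majority genotype drawn ~900/1000 times
  mix <- make_lineages(c(4, 3), size = c(9e8, 1e8),
                       mutations = list("causal01|a1|SNP", character(0)))
  iso2 <- sample_isolates(mix, 1000, seed = 5)
  n_major <- dplyr::n_distinct(iso2$isolate)  # only mutants emit records
  expect_lt(abs(n_major - 900), 3 * sqrt(1000 * 0.9 * 0.1))

  expect_error(sample_isolates(lone, 0), class = "talesim_domain_error")
  zero <- make_lineages(3, size = 0)
  expect_error(sample_isolates(zero, 1), class = "talesim_domain_error")
})

test_that("neutral limit: fitted flask rates match the closed form", {
  cfg <- quiet_config(r_max = 0.6, ic50_wt = 3.0, od_noise_sd = 0.002,
                      seed = 2)
  conc <- 1.0  # below the wild-type zero-growth point
  true_rate <- growth_rate_of(3.0, conc, cfg)
  rates <- vapply(1:6, function(i) {
    set.seed(20 + i)
    fl <- simulate_flask(founding_population(cfg), conc, cfg,
                         passage_od = 0.3, timeout_h = 72)
    fit_rate(fl$od_series, 0.01, 0.3)$rate
  }, numeric(1))
  expect_lt(abs(mean(rates) - true_rate), 0.01)
})
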