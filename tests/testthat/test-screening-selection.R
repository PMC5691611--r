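test_that("percent RSD matches hand arithmetic and is scale invariant", {
  expect_equal(rsd(c(0.25, 0.25, 0.25)), 0)
  expect_equal(rsd(c(0.20, 0.25, 0.30)), 20)
  expect_true(rsd(c(0.20, 0.25, 0.29)) <= 20)  # passes the 20% gate
  for (k in c(0.1, 3, 42)) {
    expect_equal(rsd(k * c(0.2, 0.25, 0.3)), 20)
  }
  expect_error(rsd(0.3), class = "talesim_insufficient_data")
  expect_error(rsd(c(-1, 1)), class = "talesim_domain_error")
})

test_that("clone metrics summarise replicates with means and RSDs", {
  reps <- tibble::tibble(
    isolate = rep(c("A", "B"), each = 3),
    rate = c(0.20, 0.25, 0.30, 0.31, 0.31, 0.31),
    final_od = c(0.9, 1.0, 1.1, 0.94, 0.94, 0.94),
    lag = c(2, 2, 2, 1, 1, 1)
  )
  m <- clone_metrics(reps)
  expect_equal(m$mean_rate, c(0.25, 0.31))
  expect_equal(m$rsd_rate[1], 20)
  expect_equal(m$rsd_rate[2], 0)
  expect_true(all(m$mean_rate >= 0.2 & m$mean_rate <= 0.31))
})

test_that("genotype clustering separates identical, similar and singleton", {
  # disjoint sets: all singletons
  cl <- cluster_genotypes(list(a = "m1", b = "m2", c = "m3"))
  expect_true(all(cl$relation == "singleton"))
  expect_equal(dplyr::n_distinct(cl$cluster_id), 3)

  # Jaccard 0.5 joins at the default threshold
  cl2 <- cluster_genotypes(list(a = c("A", "B", "C"), b = c("A", "B", "D")))
  expect_equal(dplyr::n_distinct(cl2$cluster_id), 1)
  expect_true(all(cl2$relation == "similar"))

  # exact equality is identical, and order of input does not matter
  g <- list(x = c("m1", "m2"), y = c("m2", "m1"), z = "m9")
  cl3 <- cluster_genotypes(g)
  expect_equal(cl3$relation[cl3$isolate %in% c("x", "y")], rep("identical", 2))
  expect_identical(cluster_genotypes(rev(g)), cl3)

  # empty genotype warns and becomes a singleton
  expect_warning(cl4 <- cluster_genotypes(list(a = character(0), b = "m1")),
                 "singleton")
  expect_equal(cl4$relation[cl4$isolate == "a"], "singleton")
})

test_that("single linkage chains similar genotypes through intermediates", {
  g <- list(a = c("1", "2", "3", "4"),
            b = c("1", "2", "3", "9"),   # J(a,b) = 0.6
            c = c("1", "2", "9", "8"))   # J(b,c) = 0.6, J(a,c) = 1/3
  cl <- cluster_genotypes(g, jaccard_min = 0.5)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
})

test_that("best-clone selection ranks rate, final OD, then reproducibility", {
  mk <- function(...) tibble::tibble(...)
  one <- mk(isolate = "only", mean_rate = 0.2, mean_final_od = 0.5,
            rsd_rate = 5, rsd_final_od = 5)
  expect_equal(select_best_clone(one), "only")

  # faster clone wins within a reproducible cluster
  pair <- mk(isolate = c("MG 4.7", "MG 3.10"),
             mean_rate = c(0.26, 0.31), mean_final_od = c(0.87, 0.94),
             rsd_rate = c(9.2, 2.9), rsd_final_od = c(4.5, 4.4))
  expect_equal(select_best_clone(pair), "MG 3.10")

  # dead heat on means: lower rate RSD breaks the tie
  tie <- mk(isolate = c("p", "q"), mean_rate = c(0.3, 0.3),
            mean_final_od = c(1, 1), rsd_rate = c(15, 5),
            rsd_final_od = c(5, 5))
  expect_equal(select_best_clone(tie), "q")

  # irreproducible cluster falls back to rate/od ranking only
  wild <- mk(isolate = c("r", "s"), mean_rate = c(0.32, 0.30),
             mean_final_od = c(0.8, 1.4), rsd_rate = c(45, 3),
             rsd_final_od = c(30, 2))
  expect_equal(select_best_clone(wild), "r")
})

test_that("condition aggregation reproduces the printed worked-example cells", {
  t1 <- ale_table1()

  s <- summarize_conditions(t1)
  mg_cl <- s[s$strain == "MG1655" & s$il == "[C4C1Im]Cl", ]
  mg_oac <- s[s$strain == "MG1655" & s$il == "[C2C1Im][OAc]", ]
  expect_equal(mg_cl$mean_end, 5.7)
  expect_equal(mg_cl$sd_end, 0.6)
  expect_equal(mg_oac$mean_end, 6.1)
  expect_equal(mg_oac$sd_end, 0.3)

  # per-stressor flask means pool both strains
  by_il <- summarize_conditions(t1, by = "il")
  expect_equal(by_il$mean_flasks[by_il$il == "[C4C1Im]Cl"], 67L)
  expect_equal(by_il$mean_flasks[by_il$il == "[C2C1Im][OAc]"], 87L)

  # single-population condition: fold 1, sd absent
  single <- aggregate_condition(tibble::tibble(start_conc = 2, end_conc = 2,
                                               n_flasks = 10))
  expect_equal(single$fold_increase, 1)
  expect_true(is.na(single$sd_end))

  expect_error(
    aggregate_condition(tibble::tibble(strain = c("A", "B"), start_conc = 1,
                                       end_conc = 2, n_flasks = 3)),
    class = "talesim_grouping_error"
  )
})

test_that("every evolved condition at least tripled its tolerated concentration", {
  s <- summarize_conditions(ale_table1())
  expect_equal(fold_increase_report(s), 6.05 / 2, tolerance = 1e-12)
  expect_gte(fold_increase_report(s), 3)
  flatline <- aggregate_condition(tibble::tibble(start_conc = 1.5,
                                                 end_conc = 1.5, n_flasks = 5))
  expect_equal(fold_increase_report(flatline), 1)
})
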