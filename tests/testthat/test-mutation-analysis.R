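test_that("mutation tables parse with vocabulary enforcement", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c(
    "strain\tpopulation\tisolate\tregion\tposition\tmutation_type\tdescription",
    "MG\tALE1\tMG4.7\tyhdP\t647\tINS\t(TGGAGCC)1->2",
    "MG\tALE1\tMG4.7\trpoC\t359\tSNP\tP359L",
    "MG\tALE1\tMG4.8\tyjjY\t100\tAMP\tamplification"
  ), collapse = "\n"), path)
  rec <- parse_mutation_table(path)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$mutation_type[1], "INS")
  errs <- attr(rec, "errors")
  expect_equal(nrow(errs), 1)
  expect_match(errs$reason, "unknown mutation_type")

  # empty file with header parses to an empty record set
  writeLines("strain\tpopulation\tisolate\tregion\tposition\tmutation_type\tdescription",
             path)
  expect_equal(nrow(parse_mutation_table(path)), 0)

  # missing required column is a format error naming it
  bad <- tibble::tibble(strain = "MG", isolate = "x")
  expect_error(parse_mutation_table(bad), "population",
               class = "talesim_format_error")
})

test_that("a minimal GenomeDiff dialect parses into records", {
  path <- withr::local_tempfile(fileext = ".gd")
  writeLines(c(
    "#=GENOME_DIFF 1.0",
    "SNP\t1\t10\tNC_000913\t1234\tA\tgene_name=rpoC",
    "DEL\t2\t11\tNC_000913\t5000\t120",
    "RA\t10\t.\tNC_000913\t1234\t0\tG\tA"
  ), path)
  rec <- parse_genomediff(path, "MG", "ALE1", "MG4.7")
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$mutation_type, c("SNP", "DEL"))
  expect_true("rpoC" %in% rec$region)
  expect_true("NC_000913:5000" %in% rec$region)
})

test_that("region canonicalisation sorts intergenic pairs and is idempotent", {
  expect_equal(canonical_region("tqsA/mdtJ"), "mdtJ/tqsA")
  expect_equal(canonical_region("mdtJ/tqsA"), "mdtJ/tqsA")
  expect_equal(canonical_region("yhdP"), "yhdP")
  raw <- c("b/a", "z", "pyrE/rph", "rph/pyrE")
  once <- canonical_region(raw)
  expect_identical(canonical_region(once), once)
  expect_equal(dplyr::n_distinct(once[c(3, 4)]), 1)
  expect_error(canonical_region(""), class = "talesim_domain_error")
})

test_that("hypermutators are flagged by the multiplier-of-median rule", {
  mk <- function(counts) {
    purrr::imap_dfr(counts, function(k, iso)
      tibble::tibble(strain = "S", population = "P", isolate = iso,
                     region = sprintf("g%03d", seq_len(k)),
                     position = seq_len(k), mutation_type = "SNP",
                     description = sprintf("m%03d", seq_len(k))))
  }
  # 267-mutation isolate vs a 5 +/- 4 cohort
  calls <- flag_hypermutators(mk(c(a = 5, b = 6, c = 267)))
  expect_identical(calls$isolate[calls$flagged], "c")

  # homogeneous cohort: nobody flagged
  expect_false(any(flag_hypermutators(mk(c(a = 5, b = 5, c = 5)))$flagged))

  # median 6, multiplier 4 -> threshold 24 catches the 39-mutation clone
  calls3 <- flag_hypermutators(mk(c(a = 4, b = 6, c = 39)), multiplier = 4)
  expect_equal(unique(calls3$threshold_used), 24)
  expect_identical(calls3$isolate[calls3$flagged], "c")

  # the floor of 20 protects tight low-count cohorts
  calls4 <- flag_hypermutators(mk(c(a = 1, b = 2, c = 8)))
  expect_equal(unique(calls4$threshold_used), 20)
  expect_false(any(calls4$flagged))

  kept <- exclude_hypermutators(mk(c(a = 5, b = 6, c = 267)))
  expect_false("c" %in% kept$isolate)
})

test_that("worked-example fixture reproduces the printed key-mutation structure", {
  rec <- table2_records()
  keys <- identify_key_mutations(rec)

  expect_equal(keys$unique_alleles[keys$region == "yhdP"], 5)
  expect_setequal(keys$region[keys$category == "combined"],
                  c("mdtJ/tqsA", "yhdP"))
  expect_equal(sum(keys$category == "combined"), 2)
  expect_true(all(keys$key))  # every printed region is recurrent

  cnt <- summarize_counts(keys, rec)
  expect_equal(unique(cnt$region_total[cnt$region == "rho"]), 13)
  # conservation: region totals are the sum of their allele counts
  tot <- dplyr::summarise(dplyr::group_by(cnt, region),
                          s = sum(n_isolates), t = unique(region_total))
  expect_equal(tot$s, tot$t)

  expect_equal(resequencing_cohort(16, 1, 3), 45L)
})

test_that("key-mutation rule needs recurrence and respects categories", {
  # one private mutation: not key
  solo <- records_from_genotypes(list(i1 = "geneX.a"))
  expect_false(identify_key_mutations(solo)$key[1])

  # same region hit in two independent populations: key even with one allele
  two_pop <- dplyr::bind_rows(
    records_from_genotypes(list(i1 = "geneX.a"), population = "P1"),
    records_from_genotypes(list(i2 = "geneX.a"), population = "P2")
  )
  k2 <- identify_key_mutations(two_pop)
  expect_true(k2$key[1])
  expect_equal(k2$category[1], "strain-specific")

  # two alleles in one isolate's region: key by multiplicity
  multi <- records_from_genotypes(list(i1 = c("geneY.a", "geneY.b")))
  expect_true(identify_key_mutations(multi)$key[1])

  # seen in two strains: combined
  two_strain <- dplyr::bind_rows(
    records_from_genotypes(list(i1 = "geneZ.a"), strain = "A", population = "P1"),
    records_from_genotypes(list(i2 = "geneZ.b"), strain = "B", population = "P2")
  )
  expect_equal(identify_key_mutations(two_strain)$category[1], "combined")
})

test_that("key-mutation output is invariant to row order and isolate labels", {
  rec <- table2_records()
  base <- identify_key_mutations(rec)

  set.seed(17)
  shuffled <- rec[sample.int(nrow(rec)), ]
  expect_identical(identify_key_mutations(shuffled), base)

  relabeled <- dplyr::mutate(rec, isolate = paste0("x_", isolate))
  again <- identify_key_mutations(relabeled)
  expect_identical(dplyr::select(again, -populations),
                   dplyr::select(base, -populations))
})

test_that("empty inputs give empty, well-typed outputs", {
  empty <- identify_key_mutations(table2_records()[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("region", "unique_alleles", "category") %in% names(empty)))
  expect_equal(nrow(summarize_counts(empty, table2_records()[0, ])), 0)
})
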