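MUTATION_TYPES <- c("SNP", "DEL", "INS", "MOB")

#' Parse a breseq-style per-isolate mutation table
#'
#' Reads tab-separated mutation calls (one row per called mutation per
#' isolate) into a validated record tibble. Rows with a mutation type outside
#' the SNP/DEL/INS/MOB vocabulary, or with missing required fields, are
#' collected in an error report attached as the `"errors"` attribute rather
#' than silently dropped.
#'
#' @param source Path to a TSV file, or a data frame already in memory.
#' @return A tibble of mutation records with columns `strain`, `population`,
#'   `isolate`, `region`, `position`, `mutation_type`, `description` (plus
#'   any extra columns present, e.g. `coding`, `gene`, `allele`). Attribute
#'   `"errors"` holds the rejected rows with a `reason` column.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(paste(
#'   c("strain\tpopulation\tisolate\tregion\tposition\tmutation_type\tdescription",
#'     "MG\tALE1\tMG4.7\tyhdP\t647\tINS\t(TGGAGCC)1->2"), collapse = "\n"), f)
#' parse_mutation_table(f)
#' @export
parse_mutation_table <- function(source) {
  tbl <- if (is.data.frame(source)) {
    as_tibble(source)
  } else {
    readr::read_tsv(source, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  required <- c("strain", "population", "isolate", "region", "position",
                "mutation_type", "description")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "talesim_format_error")
  }
  if (nrow(tbl) == 0) {
    out <- tbl
    attr(out, "errors") <- tbl
    return(out)
  }
  bad_type <- !(tbl$mutation_type %in% MUTATION_TYPES)
  bad_field <- is.na(tbl$strain) | tbl$strain == "" |
    is.na(tbl$population) | tbl$population == "" |
    is.na(tbl$isolate) | tbl$isolate == "" |
    is.na(tbl$region) | tbl$region == ""
  bad <- bad_type | bad_field
  errors <- tbl[bad, , drop = FALSE]
  if (nrow(errors) > 0) {
    errors$reason <- ifelse(bad_type[bad], "unknown mutation_type",
                            "missing required field")
  }
  out <- tbl[!bad, , drop = FALSE]
  attr(out, "errors") <- errors
  out
}

#' Parse a minimal GenomeDiff dialect
#'
#' Accepts the SNP/DEL/INS/MOB entry lines of a GenomeDiff export
#' (`TYPE<TAB>id<TAB>evidence<TAB>seq_id<TAB>position<TAB>...`), using a
#' trailing `gene_name=` field as the region when present and
#' `seq_id:position` otherwise. Other entry types (evidence lines, metadata)
#' are ignored.
#'
#' @param path Path to a GenomeDiff-like file.
#' @param strain,population,isolate Labels stamped on the records.
#' @return A mutation record tibble as from [parse_mutation_table()].
#' @export
parse_genomediff <- function(path, strain, population, isolate) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) f[[1]] %in% MUTATION_TYPES, logical(1))
  fields <- fields[keep]
  rows <- purrr::map_dfr(fields, function(f) {
    named <- grep("=", f, value = TRUE, fixed = TRUE)
    kv <- strsplit(named, "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, "", 1)
    gene <- if ("gene_name" %in% keys) {
      kv[[match("gene_name", keys)]][[2]]
    } else paste0(f[[4]], ":", f[[5]])
    tibble(
      strain = strain, population = population, isolate = isolate,
      region = gene, position = f[[5]], mutation_type = f[[1]],
      description = paste(f[-seq_len(5)][!grepl("=", f[-seq_len(5)],
                                                fixed = TRUE)],
                          collapse = " ")
    )
  })
  parse_mutation_table(rows)
}

#' Canonicalise a region name
#'
#' Intergenic regions written as `"a/b"` are returned with the gene pair
#' sorted lexicographically, so the same region reported against different
#' reference orientations (e.g. `mdtJ/tqsA` vs `tqsA/mdtJ`) groups together.
#' Plain gene names pass through unchanged. Idempotent.
#'
#' @param region Character vector of raw region names.
#' @return Canonical names, same length.
#' @examples
#' canonical_region(c("tqsA/mdtJ", "yhdP"))
#' @export
canonical_region <- function(region) {
  if (any(is.na(region) | region == "")) {
    abort("region names must be non-empty", class = "talesim_domain_error")
  }
  vapply(strsplit(region, "/", fixed = TRUE), function(p) {
    paste(sort(p), collapse = "/")
  }, character(1))
}

allele_key <- function(records) {
  if ("allele" %in% names(records) && !all(is.na(records$allele))) {
    ifelse(is.na(records$allele) | records$allele == "",
           paste(records$position, records$description, records$mutation_type),
           records$allele)
  } else {
    paste(records$position, records$description, records$mutation_type)
  }
}

#' Flag hypermutator isolates by mutation count
#'
#' Hypermutators (isolates with an elevated genome-wide mutation count,
#' typically from DNA-repair defects) distort convergence analysis and are
#' excluded. The threshold is a heuristic: `multiplier` times the cohort
#' median count, floored at `min_threshold`; an isolate is flagged when its
#' count exceeds the threshold.
#'
#' @param records Mutation record tibble.
#' @param multiplier Threshold multiplier on the cohort median (default 4).
#' @param min_threshold Minimum threshold (default 20), so small tight
#'   cohorts are never decimated.
#' @return A tibble with one row per isolate: `isolate`, `n_mutations`,
#'   `cohort_median`, `threshold_used`, `flagged`.
#' @examples
#' rec <- table2_records()
#' flag_hypermutators(rec)   # the packaged fixture is already hypermutator-free
#' @export
flag_hypermutators <- function(records, multiplier = 4, min_threshold = 20) {
  if (nrow(records) == 0 || dplyr::n_distinct(records$isolate) < 1) {
    abort("need at least one isolate", class = "talesim_domain_error")
  }
  counts <- records %>%
    group_by(.data$isolate) %>%
    summarise(n_mutations = n(), .groups = "drop")
  med <- median(counts$n_mutations)
  thr <- max(multiplier * med, min_threshold)
  counts %>%
    mutate(cohort_median = med, threshold_used = thr,
           flagged = .data$n_mutations > thr) %>%
    arrange(desc(.data$n_mutations))
}

#' @rdname flag_hypermutators
#' @return `exclude_hypermutators()` returns `records` with flagged isolates
#'   removed.
#' @export
exclude_hypermutators <- function(records, multiplier = 4, min_threshold = 20) {
  calls <- flag_hypermutators(records, multiplier, min_threshold)
  records %>% filter(!.data$isolate %in% calls$isolate[calls$flagged])
}

#' Identify convergent key mutations
#'
#' A gene or intergenic region is a "key mutation" candidate when it shows
#' recurrence: multiple unique mutations (distinct alleles), or mutations in
#' isolates from independent populations. Regions observed in two or more
#' strains are categorised `combined`; recurrent regions seen in one strain
#' are `strain-specific`; the rest are `not-key`. Hypermutators must already
#' be excluded (see [exclude_hypermutators()]).
#'
#' @param records Mutation record tibble. Allele identity is the distinct
#'   (position, description, type) triple, unless an `allele` column supplies
#'   a normalised token (used by the packaged worked-example fixture so that
#'   an identical deletion called against two reference genomes counts once).
#' @return A tibble with one row per canonical region: `region`,
#'   `unique_alleles`, `isolate_count`, `n_populations`, `populations`,
#'   `strains`, `key`, `category`; sorted by category (combined first) then
#'   descending isolate count.
#' @examples
#' keys <- identify_key_mutations(table2_records())
#' keys[keys$category == "combined", ]
#' @export
identify_key_mutations <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(region = character(), unique_alleles = integer(),
                  isolate_count = integer(), n_populations = integer(),
                  populations = character(), strains = character(),
                  key = logical(), category = character()))
  }
  records %>%
    mutate(.region = canonical_region(.data$region),
           .allele = allele_key(records)) %>%
    group_by(region = .data$.region) %>%
    summarise(
      unique_alleles = n_distinct(.data$.allele),
      isolate_count = n_distinct(.data$isolate),
      n_populations = n_distinct(.data$population),
      populations = paste(sort(unique(.data$population)), collapse = ","),
      strains = paste(sort(unique(.data$strain)), collapse = ","),
      n_strains = n_distinct(.data$strain),
      .groups = "drop"
    ) %>%
    mutate(
      key = .data$unique_alleles >= 2 | .data$n_populations >= 2,
      category = dplyr::case_when(
        !key ~ "not-key",
        n_strains >= 2 ~ "combined",
        TRUE ~ "strain-specific"
      )
    ) %>%
    select(-"n_strains") %>%
    arrange(factor(.data$category,
                   levels = c("combined", "strain-specific", "not-key")),
            desc(.data$isolate_count))
}

#' Per-allele and per-region isolate counts
#'
#' Worked-example-style count table: for every (region, allele) pair the
#' number of isolates carrying it, plus per-region totals. Region totals are
#' the sum of their allele counts by construction.
#'
#' @param summaries Output of [identify_key_mutations()]; only regions listed
#'   there are reported (pass `key_only = FALSE` output to report all).
#' @param records The mutation record tibble the summaries came from.
#' @return A tibble with columns `region`, `allele`, `mutation_type`,
#'   `n_isolates` and `region_total`.
#' @export
summarize_counts <- function(summaries, records) {
  if (nrow(summaries) == 0 || nrow(records) == 0) {
    return(tibble(region = character(), allele = character(),
                  mutation_type = character(), n_isolates = integer(),
                  region_total = integer()))
  }
  records %>%
    mutate(region = canonical_region(.data$region),
           allele = allele_key(records)) %>%
    filter(.data$region %in% summaries$region) %>%
    group_by(.data$region, .data$allele, .data$mutation_type) %>%
    summarise(n_isolates = n_distinct(.data$isolate), .groups = "drop") %>%
    group_by(.data$region) %>%
    mutate(region_total = sum(.data$n_isolates)) %>%
    ungroup() %>%
    arrange(desc(.data$region_total), .data$region, desc(.data$n_isolates))
}

#' Resequencing cohort bookkeeping
#'
#' Number of isolates entering whole-genome resequencing: a fixed number per
#' surviving population. The worked example sequenced 3 isolates from each of
#' 16 populations minus one dropped population (its clones did not grow),
#' i.e. 45 isolates.
#'
#' @param n_populations Populations evolved.
#' @param n_dropped Populations dropped before sequencing.
#' @param isolates_per_population Isolates sequenced per population.
#' @return Integer isolate count.
#' @examples
#' resequencing_cohort()  # 45
#' @export
resequencing_cohort <- function(n_populations = 16, n_dropped = 1,
                                isolates_per_population = 3) {
  stopifnot(n_populations >= n_dropped, n_dropped >= 0,
            isolates_per_population >= 1)
  as.integer((n_populations - n_dropped) * isolates_per_population)
}
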