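#' Worked-example fixture: evolved population endpoints
#'
#' Transcription of the endpoint phenotype table of the ionic-liquid
#' tolerance evolution the package models: 16 replicate populations (two
#' E. coli strains x two ionic liquids x 4 replicates), each with its
#' starting and endpoint stressor concentration (% w/v), initial and final
#' population growth rates (/h, fitted from the first/last 3 flasks) and the
#' total number of serial-passage flasks.
#'
#' @return A tibble with one row per evolved population: `il`, `strain`,
#'   `replicate`, `start_conc`, `initial_rate`, `end_conc`, `final_rate`,
#'   `final_rate_sd`, `change_conc`, `n_flasks`.
#' @examples
#' summarize_conditions(ale_table1())
#' @export
ale_table1 <- function() {
  readr::read_tsv(
    system.file("extdata", "il_tolerance_endpoints.tsv", package = "talesim"),
    col_types = readr::cols(
      il = "c", strain = "c", replicate = "c",
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Worked-example fixture: key mutations of the tolerant isolates
#'
#' Transcription of the key-mutation table: every gene or intergenic region
#' recurrently mutated in the sequenced tolerant isolates, with the printed
#' allele description, mutation type, strain, ionic liquid (B/E for the
#' chloride and acetate stressors) and the number of isolates carrying each
#' allele.
#'
#' The `gene` column carries the printed gene label; `region` carries the
#' locus group the printed table aggregates under (the tqsA-allele variants
#' under the combined mdtJ/tqsA transport locus, and the rph pseudogene
#' insertion with the neighbouring pyrE/rph intergenic deletion). `allele` is
#' a normalised token so the identical 120 bp promoter-region deletion called
#' against the two different reference genomes counts as one unique allele.
#'
#' @return A tibble with columns `category`, `strain`, `gene`, `region`,
#'   `position`, `description`, `allele`, `mutation_type`, `coding`, `il`,
#'   `count`.
#' @examples
#' ale_table2()
#' @export
ale_table2 <- function() {
  readr::read_tsv(
    system.file("extdata", "key_mutations.tsv", package = "talesim"),
    col_types = readr::cols(count = "i", .default = "c"),
    progress = FALSE
  )
}

#' Expand the key-mutation fixture to per-isolate records
#'
#' Turns each fixture row (an allele carried by `count` isolates) into
#' `count` mutation records, giving the long per-isolate form that
#' [identify_key_mutations()] and [summarize_counts()] consume. The printed
#' table does not name populations, so each strain gets a single "unknown"
#' population label and recurrence on this fixture rests on allele
#' multiplicity; isolate labels are synthetic row-wise stand-ins, not the
#' study's clone names.
#'
#' @return A mutation record tibble (`strain`, `population`, `isolate`,
#'   `region`, `position`, `mutation_type`, `description`, `allele`, `gene`,
#'   `il`).
#' @examples
#' nrow(table2_records())  # sum of the fixture's count column
#' @export
table2_records <- function() {
  t2 <- ale_table2()
  t2 %>%
    mutate(row = row_number()) %>%
    tidyr::uncount(.data$count, .id = "k") %>%
    mutate(
      population = paste0(.data$strain, "-unknown"),
      isolate = sprintf("%s-r%02d-i%02d", .data$strain, .data$row, .data$k)
    ) %>%
    select("strain", "population", "isolate", "region", "position",
           "mutation_type", "description", "allele", "gene", "il")
}
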