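#' Percent relative standard deviation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Used as the
#' replicate-consistency gate in clone selection (<= 20 % variability in
#' growth rate and final OD).
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return Percent RSD (scalar).
#' @examples
#' rsd(c(0.20, 0.25, 0.30))  # 20
#' @export
rsd <- function(values) {
  if (length(values) < 2) {
    abort("need >= 2 replicates for an RSD",
          class = "talesim_insufficient_data")
  }
  m <- mean(values)
  if (m == 0) {
    abort("RSD undefined for zero mean", class = "talesim_domain_error")
  }
  100 * sd(values) / m
}

#' Summarise replicate growth metrics per isolate
#'
#' Collapses replicate-level growth metrics (from [fit_rates()] or a
#' secondary screen) to one row per isolate with means and percent RSDs, the
#' inputs [select_best_clone()] ranks on.
#'
#' @param replicates Data frame with columns `isolate`, `rate`, `final_od`
#'   and optionally `lag`.
#' @return A tibble with `isolate`, `n_replicates`, `mean_rate`,
#'   `mean_final_od`, `mean_lag`, `rsd_rate`, `rsd_final_od`.
#' @export
clone_metrics <- function(replicates) {
  stopifnot(all(c("isolate", "rate", "final_od") %in% names(replicates)))
  if (!"lag" %in% names(replicates)) replicates$lag <- NA_real_
  replicates %>%
    group_by(.data$isolate) %>%
    summarise(
      n_replicates = n(),
      mean_rate = mean(.data$rate),
      mean_final_od = mean(.data$final_od),
      mean_lag = mean(.data$lag),
      rsd_rate = if (n() >= 2) rsd(.data$rate) else NA_real_,
      rsd_final_od = if (n() >= 2) rsd(.data$final_od) else NA_real_,
      .groups = "drop"
    )
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Cluster isolate genotypes
#'
#' Groups isolates by their mutation sets: exact set equality defines
#' genetically-identical groups, then single-linkage on Jaccard similarity
#' (>= `jaccard_min`) joins groups into genetically-similar clusters -- the
#' expected structure when multiple clones are picked from one population.
#' Cluster labels are deterministic (the lexicographically first member).
#'
#' @param genotypes Named list: isolate -> character vector of mutation
#'   identifiers. Hypermutators should be excluded beforehand.
#' @param jaccard_min Similarity threshold for "genetically-similar"
#'   (default 0.5; the source study gives no quantitative definition).
#' @return A tibble with `isolate`, `cluster_id`, `relation`
#'   (identical / similar / singleton).
#' @examples
#' cluster_genotypes(list(a = c("m1", "m2", "m3"), b = c("m1", "m2", "m4"),
#'                        c = "m9"))
#' @export
cluster_genotypes <- function(genotypes, jaccard_min = 0.5) {
  stopifnot(is.list(genotypes), length(genotypes) >= 1,
            !is.null(names(genotypes)))
  iso <- sort(names(genotypes))
  genotypes <- genotypes[iso]
  empty <- vapply(genotypes, length, integer(1)) == 0
  if (any(empty)) {
    warn(paste("isolates with empty genotypes become singletons:",
               paste(iso[empty], collapse = ", ")))
  }
  n <- length(iso)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (empty[i] || empty[j]) next
        if (jaccard(genotypes[[i]], genotypes[[j]]) >= jaccard_min) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cluster_id <- vapply(root, function(r) iso[min(which(root == r))],
                       character(1))
  sets <- lapply(genotypes, sort)
  relation <- vapply(seq_len(n), function(i) {
    members <- which(root == root[i])
    if (length(members) == 1) return("singleton")
    twins <- any(vapply(setdiff(members, i),
                        function(j) identical(sets[[i]], sets[[j]]),
                        logical(1)))
    if (twins) "identical" else "similar"
  }, character(1))
  tibble(isolate = iso, cluster_id = cluster_id, relation = relation)
}

#' Select the best-performing clone of a cluster
#'
#' Decision rule for picking a cluster representative from replicate screen
#' metrics: when every member reproduces well (rate and final-OD RSD both
#' <= `rsd_gate` %), rank by mean growth rate, then mean final OD, then
#' lowest rate RSD; otherwise fall back to rate then final OD alone. Ties
#' break on the isolate label.
#'
#' @param cluster A [clone_metrics()]-style tibble (one row per member).
#' @param rsd_gate Replicate-variability gate, percent (default 20).
#' @return The selected isolate label (scalar character).
#' @examples
#' m <- tibble::tibble(isolate = c("MG 4.7", "MG 3.10"),
#'                     mean_rate = c(0.26, 0.31),
#'                     mean_final_od = c(0.87, 0.94),
#'                     rsd_rate = c(9.2, 2.9), rsd_final_od = c(4.5, 4.4))
#' select_best_clone(m)  # "MG 3.10"
#' @export
select_best_clone <- function(cluster, rsd_gate = 20) {
  stopifnot(nrow(cluster) >= 1,
            all(c("isolate", "mean_rate", "mean_final_od") %in% names(cluster)))
  has_rsd <- all(c("rsd_rate", "rsd_final_od") %in% names(cluster)) &&
    !anyNA(cluster$rsd_rate) && !anyNA(cluster$rsd_final_od)
  all_reproducible <- has_rsd &&
    all(cluster$rsd_rate <= rsd_gate & cluster$rsd_final_od <= rsd_gate)
  ranked <- if (all_reproducible) {
    cluster %>% arrange(desc(.data$mean_rate), desc(.data$mean_final_od),
                        .data$rsd_rate, .data$isolate)
  } else {
    cluster %>% arrange(desc(.data$mean_rate), desc(.data$mean_final_od),
                        .data$isolate)
  }
  ranked$isolate[1]
}

#' Aggregate endpoint concentrations for one evolution condition
#'
#' Collapses the replicate populations of one (strain, stressor) condition to
#' the printed-table form: mean and sample SD of the endpoint concentrations
#' (rounded half away from zero to 1 decimal for display), mean flask count
#' (rounded to integer), and the unrounded fold increase over the start.
#'
#' @param rows Data frame with columns `start_conc`, `end_conc`, `n_flasks`
#'   and optionally `strain`/`il` labels (which must then be constant).
#' @return A one-row tibble: `strain`, `il`, `start_conc`, `mean_end`,
#'   `sd_end`, `mean_flasks`, `n_populations`, `fold_increase`.
#' @examples
#' aggregate_condition(tibble::tibble(start_conc = 1.5,
#'                                    end_conc = c(6.2, 6.2, 4.9, 5.6),
#'                                    n_flasks = c(62, 67, 63, 84)))
#' @export
aggregate_condition <- function(rows) {
  stopifnot(nrow(rows) >= 1,
            all(c("start_conc", "end_conc", "n_flasks") %in% names(rows)))
  for (lab in c("strain", "il")) {
    if (lab %in% names(rows) && dplyr::n_distinct(rows[[lab]]) > 1) {
      abort(sprintf("rows span multiple %s labels; aggregate one condition at a time",
                    lab), class = "talesim_grouping_error")
    }
  }
  # pooled groups (e.g. per-stressor flask counts) may mix starting
  # concentrations; fold change is then undefined rather than misleading
  shared_start <- if (dplyr::n_distinct(rows$start_conc) == 1) {
    rows$start_conc[1]
  } else NA_real_
  mean_end_raw <- mean(rows$end_conc)
  tibble(
    strain = if ("strain" %in% names(rows)) rows$strain[1] else NA_character_,
    il = if ("il" %in% names(rows)) rows$il[1] else NA_character_,
    start_conc = shared_start,
    mean_end = round_half_up(mean_end_raw, 1),
    sd_end = if (nrow(rows) >= 2) round_half_up(sd(rows$end_conc), 1) else NA_real_,
    mean_flasks = as.integer(round_half_up(mean(rows$n_flasks))),
    n_populations = nrow(rows),
    fold_increase = mean_end_raw / shared_start
  )
}

#' Summarise every evolution condition in a table
#'
#' Grouped wrapper around [aggregate_condition()]: one summary row per group.
#' Grouping by `il` alone reproduces the per-stressor mean flask counts
#' quoted for the worked example (67 and 87 flasks); note that fold increases
#' are then computed against a pooled start and only meaningful when the
#' grouped populations share one.
#'
#' @param table Data frame of per-population rows (see [ale_table1()]).
#' @param by Grouping columns (default strain and stressor).
#' @return A tibble of condition summaries.
#' @examples
#' summarize_conditions(ale_table1())
#' @export
summarize_conditions <- function(table, by = c("strain", "il")) {
  stopifnot(all(by %in% names(table)))
  table %>%
    dplyr::group_split(across(dplyr::all_of(by))) %>%
    purrr::map(function(d) {
      out <- aggregate_condition(d %>% select(-dplyr::any_of(setdiff(c("strain", "il"), by))))
      for (lab in by) out[[lab]] <- d[[lab]][1]
      out
    }) %>%
    bind_rows()
}

#' Minimum fold increase in tolerated concentration
#'
#' Across condition summaries, the smallest ratio of mean endpoint to
#' starting concentration -- the conservative version of "populations grew at
#' N-fold or more of the initial concentration".
#'
#' @param summaries Output of [summarize_conditions()] /
#'   [aggregate_condition()].
#' @return Scalar minimum fold increase (unrounded).
#' @examples
#' fold_increase_report(summarize_conditions(ale_table1()))
#' @export
fold_increase_report <- function(summaries) {
  stopifnot(nrow(summaries) >= 1, "fold_increase" %in% names(summaries))
  min(summaries$fold_increase)
}
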