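#' Read and write OD time-series tables
#'
#' The on-disk contract for OD series is a plain CSV with columns
#' `flask_index`, `time_h`, `od_plate` and `concentration_pct`, one row per
#' plate-reader read. `write_od_csv()` accepts either a `tale_run` (whose
#' per-flask series are concatenated) or an already-long data frame.
#'
#' @param x A `tale_run` or a data frame with the four contract columns.
#' @param path File path.
#' @return `write_od_csv()` returns `path` invisibly; `read_od_csv()` returns
#'   a tibble with the contract columns.
#' @export
write_od_csv <- function(x, path) {
  long <- if (inherits(x, "tale_run")) {
    purrr::map2_dfr(x$flasks, seq_along(x$flasks), function(s, i) {
      tibble(flask_index = i, time_h = s$time_h, od_plate = s$od,
             concentration_pct = x$log$concentration[i])
    })
  } else {
    stopifnot(all(c("flask_index", "time_h", "od_plate",
                    "concentration_pct") %in% names(x)))
    as_tibble(x)
  }
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_od_csv
#' @export
read_od_csv <- function(path) {
  readr::read_csv(path,
                  col_types = readr::cols(flask_index = "i",
                                          .default = readr::col_double()),
                  progress = FALSE)
}

#' Read and write per-isolate mutation tables
#'
#' TSV mirror of the breseq-style record layout consumed by
#' [parse_mutation_table()] (columns `strain`, `population`, `isolate`,
#' `region`, `position`, `mutation_type`, `description`, plus any extras).
#'
#' @param records A mutation record tibble.
#' @param path File path.
#' @return `write_mutation_tsv()` returns `path` invisibly;
#'   `read_mutation_tsv()` is [parse_mutation_table()] on a file path.
#' @export
write_mutation_tsv <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_mutation_tsv
#' @export
read_mutation_tsv <- function(path) {
  parse_mutation_table(path)
}

#' Write a run log and summary for a TALE run
#'
#' The flask-by-flask decision log goes to CSV (`flask_index`,
#' `concentration_pct`, `rate_h`, `crashed`) and the run summary
#' (`n_increases`, `n_crashes`, `final_conc`, ...) to a JSON-style file
#' written without external dependencies.
#'
#' @param run A `tale_run`.
#' @param log_path,summary_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the [glance()] summary tibble.
#' @export
write_run_log <- function(run, log_path = NULL, summary_path = NULL) {
  stopifnot(inherits(run, "tale_run"))
  if (!is.null(log_path)) {
    readr::write_csv(
      run$log %>%
        select(flask_index = "flask_index", concentration_pct = "concentration",
               rate_h = "rate", crashed = "crashed"),
      log_path
    )
  }
  g <- glance(run)
  if (!is.null(summary_path)) {
    fields <- vapply(names(g), function(nm) {
      sprintf("  \"%s\": %s", nm, format(g[[nm]], digits = 15, scientific = FALSE))
    }, character(1))
    writeLines(c("{", paste(fields, collapse = ",\n"), "}"), summary_path)
  }
  invisible(g)
}
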