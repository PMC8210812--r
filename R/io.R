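#' Read a long-format prediction table
#'
#' Reads tool predictions as TSV. Two shapes are accepted:
#' * a per-stratum file with columns `fragment_id` and any of `score`,
#'   `pvalue`, `category` (raw scores; apply a rule with [apply_cutoff()]);
#' * a long-format file additionally carrying `tool`, `cutoff`, `dataset`,
#'   `length_class`, `replicate` columns of positive calls, ready for
#'   [evaluate_run()].
#'
#' @param path file path (TSV, `#` comments ignored)
#' @return a tibble
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, na = c("", "NA"))
}

#' Write an evaluation report as TSV
#'
#' @param report a tibble (e.g. from [evaluate_run()] or
#'   [compare_to_reference()])
#' @param path output path
#' @param header optional character vector of `#`-prefixed provenance lines
#' @return `path`, invisibly
#' @export
write_report_tsv <- function(report, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", sub("^#\\s*", "", header)), path)
    readr::write_tsv(report, path, append = TRUE, col_names = TRUE, na = "NA")
  } else {
    readr::write_tsv(report, path, na = "NA")
  }
  invisible(path)
}
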