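#' Write an enrichment report as tab-delimited text
#'
#' Emits one line per protein with its detection count, log2 fold change
#' (infinite fold changes are rendered `"inf"`, mirroring the unbounded
#' entries that arise when a protein is absent from every control trial),
#' mean normalized peak area and, when available, the cross-bait overlap
#' flag.
#'
#' @param results An `enrichment_table` from [score_enrichment()] or
#'   [rank_and_select()], or any data frame with columns
#'   `protein_accession`, `times_detected`, `log2_fold_change` and
#'   `mean_norm_peak_area` (an optional `in_other_bait` column is carried
#'   through).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_report <- function(results, path) {
  results <- as_tibble(results)
  if (nrow(results) == 0) abort("`results` must be non-empty.")
  needed <- c("protein_accession", "times_detected", "log2_fold_change",
              "mean_norm_peak_area")
  missing <- setdiff(needed, names(results))
  if (length(missing) > 0) {
    abort(paste0("Report input lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble(
    protein_accession = results$protein_accession,
    times_detected = as.integer(results$times_detected),
    log2_fold_change = ifelse(
      is.infinite(results$log2_fold_change), "inf",
      formatC(results$log2_fold_change, digits = 15, format = "g")
    ),
    mean_norm_peak_area = formatC(results$mean_norm_peak_area,
                                  digits = 15, format = "g"),
    in_other_bait = if ("in_other_bait" %in% names(results)) {
      results$in_other_bait
    } else {
      NA
    }
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a protein report written by [write_protein_report()]
#'
#' @param path Path to the report.
#' @return A tibble with numeric `log2_fold_change` (`"inf"` parsed to
#'   `Inf`) and `mean_norm_peak_area`.
#' @export
read_protein_report <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    protein_accession = readr::col_character(),
    times_detected = readr::col_integer(),
    log2_fold_change = readr::col_character(),
    mean_norm_peak_area = readr::col_double(),
    in_other_bait = readr::col_logical()
  ), progress = FALSE)
  raw$log2_fold_change <- ifelse(raw$log2_fold_change == "inf", Inf,
                                 as.numeric(raw$log2_fold_change))
  raw
}
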