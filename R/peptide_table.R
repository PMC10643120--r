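canonical_peptide_columns <- c(
  "run_id", "bait_label", "replicate_index", "protein_accession",
  "organism", "peptide_sequence", "modifications", "peak_area"
)

#' Assemble a validated peptide-level quantification table
#'
#' One row is one quantified peptide observation in one run: the protein it
#' was assigned to, its host/phage partition, its sequence, its variable
#' modifications and its chromatographic peak area. Validation failures are
#' reported with the offending row numbers.
#'
#' @param peptides A data frame with columns `run_id`, `bait_label`,
#'   `replicate_index`, `protein_accession`, `organism` (`"host"` or
#'   `"phage"`), `peptide_sequence` (uppercase amino acids), `modifications`
#'   (encoded `"pos:mass;pos:mass"`, `""` for none) and `peak_area` (>= 0).
#' @param design An [experiment_design()]; every `run_id` must appear in it.
#'
#' @return A `peptide_table`: a list with elements `peptides` (tibble) and
#'   `design`.
#' @export
peptide_table <- function(peptides, design) {
  assert_design(design)
  peptides <- as_tibble(peptides)
  missing <- setdiff(canonical_peptide_columns, names(peptides))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  peptides <- peptides[canonical_peptide_columns]
  peptides$run_id <- as.character(peptides$run_id)
  peptides$bait_label <- as.character(peptides$bait_label)
  peptides$replicate_index <- as.integer(peptides$replicate_index)
  peptides$protein_accession <- as.character(peptides$protein_accession)
  peptides$organism <- as.character(peptides$organism)
  peptides$peptide_sequence <- as.character(peptides$peptide_sequence)
  peptides$modifications <- as.character(peptides$modifications)
  peptides$modifications[is.na(peptides$modifications)] <- ""
  peptides$peak_area <- as.numeric(peptides$peak_area)

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      abort(paste0("Invalid peptide rows (", what, "): row ",
                   paste(head(rows, 10L), collapse = ", "),
                   if (length(rows) > 10) " ..." else ""))
    }
  }
  bad(is.na(peptides$peak_area) | peptides$peak_area < 0,
      "peak_area must be a number >= 0")
  bad(!peptides$organism %in% c("host", "phage"),
      "organism must be 'host' or 'phage'")
  bad(is.na(peptides$replicate_index) | peptides$replicate_index < 1L,
      "replicate_index must be an integer >= 1")
  bad(!grepl("^[A-Z]+$", peptides$peptide_sequence),
      "peptide_sequence must be uppercase amino-acid text")
  bad(!peptides$run_id %in% design_runs(design),
      "run_id not present in the experiment design")

  bad(max_modification_position(peptides$modifications) >
        nchar(peptides$peptide_sequence),
      "modification position beyond peptide length")

  structure(list(peptides = peptides, design = design),
            class = "peptide_table")
}

#' @export
print.peptide_table <- function(x, ...) {
  cat("<peptide_table> ", nrow(x$peptides), " peptide observation(s), ",
      length(unique(x$peptides$protein_accession)), " protein(s), ",
      length(design_runs(x$design)), " run(s)\n", sep = "")
  print(x$design)
  invisible(x)
}

#' Parse the compact modification encoding
#'
#' Modifications ride along as `"pos:mass;pos:mass"` strings (1-based peptide
#' position, delta mass in Da); `""` means unmodified.
#'
#' @param x Character vector of encoded modification strings.
#' @return A list of tibbles with columns `position` and `delta_mass`.
#' @export
parse_modifications <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble(position = integer(), delta_mass = numeric()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    ok <- vapply(parts, length, integer(1)) == 2L
    if (!all(ok)) abort(paste0("Malformed modification string: '", s, "'"))
    tibble(
      position = as.integer(vapply(parts, `[[`, character(1), 1L)),
      delta_mass = as.numeric(vapply(parts, `[[`, character(1), 2L))
    )
  })
}

# Vectorized helpers over the "pos:mass;pos:mass" encoding; these avoid the
# per-row overhead of parse_modifications() on large tables.
split_modifications <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

max_modification_position <- function(x) {
  vapply(split_modifications(x), function(p) {
    if (length(p) == 0) return(0L)
    max(as.integer(sub(":.*$", "", p)))
  }, integer(1))
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a peptide-level quantification table from delimited text
#'
#' Reads a PEAKS-style label-free export (tab- or comma-delimited,
#' auto-detected from the header). Column names are mapped through `dialect`
#' so exports with different headers can be ingested without rewriting them.
#'
#' @param path Path to the delimited file.
#' @param dialect Named character vector mapping the canonical column names
#'   (`run_id`, `bait_label`, `replicate_index`, `protein_accession`,
#'   `organism`, `peptide_sequence`, `modifications`, `peak_area`) to the
#'   column names used in the file. Defaults to the identity mapping.
#' @param design Optional [experiment_design()]. When `NULL`, runs whose
#'   `bait_label` matches `control_pattern` become control runs and all other
#'   runs become bait runs.
#' @param control_pattern Regular expression identifying control-run bait
#'   labels when `design` is inferred (default matches the GFP-miniTurboID
#'   control labels).
#'
#' @return A [peptide_table()].
#' @export
read_peptide_table <- function(path, dialect = NULL, design = NULL,
                               control_pattern = "GFP") {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  full <- setNames(canonical_peptide_columns, canonical_peptide_columns)
  if (!is.null(dialect)) full[names(dialect)] <- dialect
  # the "pos:mass" encoding must not be guessed as a time of day
  col_spec <- list(
    readr::col_character(), readr::col_character(), readr::col_integer(),
    readr::col_character(), readr::col_character(), readr::col_character(),
    readr::col_character(), readr::col_double()
  )
  names(col_spec) <- unname(full)
  delim <- detect_delimiter(path)
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  missing <- setdiff(unname(full), header)
  if (length(missing) > 0) {
    abort(paste0("Input file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = do.call(readr::cols, col_spec),
    progress = FALSE, show_col_types = FALSE
  )
  peptides <- raw[unname(full)]
  names(peptides) <- names(full)
  if (is.null(design)) {
    run_bait <- unique(peptides[c("run_id", "bait_label")])
    is_ctrl <- grepl(control_pattern, run_bait$bait_label)
    if (!any(is_ctrl) || all(is_ctrl)) {
      abort("Cannot infer the design: supply `design` explicitly.")
    }
    design <- experiment_design(run_bait$run_id[!is_ctrl],
                                run_bait$run_id[is_ctrl])
  }
  peptide_table(peptides, design)
}

#' Write a peptide table as tab-delimited text
#'
#' The written file round-trips through [read_peptide_table()] with all
#' fields preserved (peak areas are written with full double precision).
#'
#' @param table A [peptide_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peptide_table <- function(table, path) {
  assert_peptide_table(table)
  readr::write_tsv(table$peptides, path, progress = FALSE)
  invisible(path)
}

assert_peptide_table <- function(table) {
  if (!inherits(table, "peptide_table")) {
    abort("Expected a `peptide_table` (see `peptide_table()`).")
  }
  invisible(table)
}

#' Keep only biotinylated peptides
#'
#' Proximity labeling marks lysines with a +226.08 Da biotin adduct; this
#' filter retains peptide observations carrying at least one modification of
#' that mass (within `tolerance`) at a lysine residue. Applying the filter
#' twice equals applying it once, and the output rows are always a subset of
#' the input rows.
#'
#' @param table A [peptide_table()].
#' @param delta_mass Modification mass in Da (default 226.08).
#' @param tolerance Matching tolerance in Da (default 0.01).
#' @return A filtered [peptide_table()] (possibly with zero rows).
#' @export
filter_biotinylated <- function(table, delta_mass = 226.08,
                                tolerance = 0.01) {
  assert_peptide_table(table)
  pep <- table$peptides
  mods <- split_modifications(pep$modifications)
  seqs <- pep$peptide_sequence
  keep <- vapply(seq_along(mods), function(i) {
    p <- mods[[i]]
    if (length(p) == 0) return(FALSE)
    pos <- as.integer(sub(":.*$", "", p))
    mass <- as.numeric(sub("^[^:]*:", "", p))
    hit <- abs(mass - delta_mass) <= tolerance
    if (!any(hit)) return(FALSE)
    any(substring(seqs[i], pos[hit], pos[hit]) == "K")
  }, logical(1))
  out <- table
  out$peptides <- pep[keep, , drop = FALSE]
  out
}
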