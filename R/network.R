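evidence_types <- c("proximity_labeling", "gfp_pulldown",
                    "coexpression_pulldown")
localization_categories <- c("nucleus", "shell", "bouquet", "cytoplasm",
                             "unassigned")

#' Build bait-prey evidence edges
#'
#' @param source,target Protein identifiers (bait or hub in `source`).
#' @param evidence Evidence type for each edge: `"proximity_labeling"`
#'   (miniTurboID labeling), `"gfp_pulldown"` (GFP affinity purification) or
#'   `"coexpression_pulldown"` (heterologous coexpression pulldown).
#' @param dataset_id Free-text identifier of the originating dataset.
#' @return A tibble of validated evidence edges.
#' @export
evidence_edges <- function(source, target, evidence,
                           dataset_id = NA_character_) {
  edges <- tibble(
    source = as.character(source),
    target = as.character(target),
    evidence = as.character(evidence),
    dataset_id = as.character(dataset_id)
  )
  bad <- !edges$evidence %in% evidence_types
  if (any(bad)) {
    abort(paste0("Unknown evidence type(s): ",
                 paste(unique(edges$evidence[bad]), collapse = ", ")))
  }
  edges
}

#' Read evidence edges from a delimited file
#'
#' @param path TSV/CSV with columns `source`, `target`, `evidence` and
#'   optionally `dataset_id`.
#' @return A tibble of evidence edges.
#' @export
read_evidence_edges <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_delim(path, delim = detect_delimiter(path),
                           col_types = readr::cols(), progress = FALSE,
                           show_col_types = FALSE)
  evidence_edges(raw$source, raw$target, raw$evidence,
                 if ("dataset_id" %in% names(raw)) raw$dataset_id else NA)
}

#' Union of top-ranked candidates across baits, with overlap flags
#'
#' Pools the top `top_n` proteins from each bait's ranked enrichment list
#' (after removing the baits themselves, which trivially top their own
#' lists) and flags, for every candidate, which lists it appears in — the
#' "found in the other bait's dataset?" annotation of the published
#' candidate tables. With the two published top-25 lists this yields the 42
#' candidate proteins, 8 of which appear in both.
#'
#' @param tables Named list of ranked tables: `enrichment_table`s or data
#'   frames with a `protein` or `protein_accession` column ordered by rank.
#' @param top_n Number of proteins taken from each table after exclusion
#'   (default 25).
#' @param exclude Protein identifiers to drop before truncation (typically
#'   the baits).
#' @return A tibble with one row per candidate: `protein`, one logical
#'   `in_<table name>` column per input table, and `n_baits`, the number of
#'   lists containing the candidate.
#' @export
build_candidate_set <- function(tables, top_n = 25, exclude = character()) {
  if (!is.list(tables) || length(tables) == 0 ||
      inherits(tables, "data.frame")) {
    abort("`tables` must be a non-empty list of ranked candidate tables.")
  }
  if (top_n < 1) abort("`top_n` must be >= 1.")
  nms <- names(tables)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- paste0("bait", seq_along(tables))
  }
  tops <- lapply(tables, function(tab) {
    tab <- as_tibble(tab)
    col <- intersect(c("protein", "protein_accession"), names(tab))[1]
    if (is.na(col)) {
      abort("Each table needs a `protein` or `protein_accession` column.")
    }
    ids <- as.character(tab[[col]])
    ids <- ids[!ids %in% exclude]
    head(unique(ids), n = top_n)
  })
  proteins <- sort(unique(unlist(tops)))
  flags <- lapply(tops, function(ids) proteins %in% ids)
  names(flags) <- paste0("in_", nms)
  out <- tibble(protein = proteins)
  for (nm in names(flags)) out[[nm]] <- flags[[nm]]
  out$n_baits <- rowSums(as.matrix(as.data.frame(flags)))
  out
}

#' Assemble an evidence-typed interaction network
#'
#' Merges duplicate bait-prey pairs into single edges carrying the union of
#' their evidence types, and attaches localization categories to the nodes.
#' Self-edges are rejected with a warning. The result is independent of the
#' input edge order.
#'
#' @param edges Evidence edges (see [evidence_edges()]).
#' @param annotations Optional localization annotations: a data frame with
#'   columns `protein` and `category`; unlisted nodes get `"unassigned"`.
#' @return An `interaction_network`: a list with tibbles `nodes` (`protein`,
#'   `localization`) and `edges` (`source`, `target`, list-columns
#'   `evidence` and `datasets`).
#' @export
assemble_network <- function(edges, annotations = NULL) {
  edges <- as_tibble(edges)
  self <- edges$source == edges$target
  if (any(self)) {
    warn(paste0("Dropping ", sum(self), " self-edge(s)."))
    edges <- edges[!self, , drop = FALSE]
  }
  merged <- edges |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      evidence = list(sort(unique(.data$evidence))),
      datasets = list(sort(unique(stats::na.omit(.data$dataset_id)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$source, .data$target)
  proteins <- sort(unique(c(merged$source, merged$target)))
  loc <- setNames(rep("unassigned", length(proteins)), proteins)
  if (!is.null(annotations) && nrow(as_tibble(annotations)) > 0) {
    annotations <- validate_annotations(annotations)
    known <- intersect(proteins, annotations$protein)
    loc[known] <- annotations$category[match(known, annotations$protein)]
  }
  structure(
    list(
      nodes = tibble(protein = proteins, localization = unname(loc)),
      edges = merged
    ),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  n_ev <- sum(lengths(x$edges$evidence))
  cat("<interaction_network> ", nrow(x$nodes), " node(s), ",
      nrow(x$edges), " merged edge(s) carrying ", n_ev,
      " evidence record(s)\n", sep = "")
  invisible(x)
}

validate_annotations <- function(annotations) {
  annotations <- as_tibble(annotations)
  if (!all(c("protein", "category") %in% names(annotations))) {
    abort("Annotations need columns `protein` and `category`.")
  }
  annotations$protein <- as.character(annotations$protein)
  annotations$category <- as.character(annotations$category)
  bad <- !annotations$category %in% localization_categories
  if (any(bad)) {
    abort(paste0("Unknown localization categor(ies): ",
                 paste(unique(annotations$category[bad]), collapse = ", ")))
  }
  annotations <- unique(annotations)
  dup <- annotations$protein[duplicated(annotations$protein)]
  if (length(dup) > 0) {
    abort(paste0("Conflicting localization for: ",
                 paste(unique(dup), collapse = ", ")))
  }
  annotations
}

#' Read localization annotations from a delimited file
#'
#' @param path TSV/CSV with columns `protein` and `category` (one of
#'   nucleus, shell, bouquet, cytoplasm, unassigned).
#' @return A validated tibble of annotations.
#' @export
read_localization <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_delim(path, delim = detect_delimiter(path),
                           col_types = readr::cols(), progress = FALSE,
                           show_col_types = FALSE)
  validate_annotations(raw)
}

#' Count proteins per subcellular localization category
#'
#' Summarizes a localization mapping experiment: how many proteins fell
#' inside the phage nucleus, on the nuclear shell, at the phage bouquets, in
#' the cytoplasm, or remained unassigned. Categories absent from the input
#' report 0; duplicated proteins with conflicting categories are an error.
#'
#' @param annotations A data frame with columns `protein` and `category`.
#' @return A named integer vector over all five categories.
#' @export
localization_summary <- function(annotations) {
  annotations <- validate_annotations(annotations)
  counts <- table(factor(annotations$category,
                         levels = localization_categories))
  setNames(as.integer(counts), localization_categories)
}

#' Export an interaction network to standard graph formats
#'
#' Edges are stored directed (bait to prey) but written undirected by
#' default, since pulldown evidence is symmetric.
#'
#' @param network An `interaction_network` from [assemble_network()].
#' @param path Output path.
#' @param format `"sif"` (one line per evidence type,
#'   `source<TAB>evidence<TAB>target`), `"graphml"` (node attribute
#'   `localization`, edge attribute `evidence` with types joined by `|`), or
#'   `"tsv"` (edge list with a joined `evidence` column).
#' @param directed Write a directed graph (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("sif", "graphml",
                                                     "tsv"),
                           directed = FALSE) {
  format <- match.arg(format)
  if (!inherits(network, "interaction_network")) {
    abort("`network` must come from `assemble_network()`.")
  }
  edges <- network$edges
  joined <- vapply(edges$evidence, paste, character(1), collapse = "|")
  if (format == "sif") {
    lines <- unlist(purrr::pmap(
      list(edges$source, edges$target, edges$evidence),
      function(s, t, ev) paste(s, ev, t, sep = "\t")
    ))
    writeLines(as.character(lines), path)
  } else if (format == "tsv") {
    readr::write_tsv(
      tibble(source = edges$source, target = edges$target,
             evidence = joined),
      path, progress = FALSE
    )
  } else {
    g <- igraph::graph_from_data_frame(
      tibble(from = edges$source, to = edges$target, evidence = joined),
      directed = directed,
      vertices = tibble(name = network$nodes$protein,
                        localization = network$nodes$localization)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a GraphML network written by [export_network()]
#'
#' @param path Path to the GraphML file.
#' @return An `interaction_network` equivalent to the exported one.
#' @export
import_network_graphml <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  vs <- igraph::as_data_frame(g, what = "vertices")
  edges <- evidence_edges(
    source = rep(el$from, lengths(strsplit(el$evidence, "|", fixed = TRUE))),
    target = rep(el$to, lengths(strsplit(el$evidence, "|", fixed = TRUE))),
    evidence = unlist(strsplit(el$evidence, "|", fixed = TRUE))
  )
  annotations <- tibble(protein = vs$name, category = vs$localization)
  assemble_network(edges, annotations)
}
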