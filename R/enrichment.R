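#' Per-run normalization factors from shared host peptides
#'
#' Host peptides quantified in every run anchor the between-run scale: host
#' protein abundance is unaffected by which bait was labeled, so systematic
#' differences in their signal reflect run-level loading and instrument
#' response. The default estimator is median-of-ratios: for each shared host
#' peptide (identified by sequence plus modification set) the per-run area is
#' divided by that peptide's geometric mean across runs, and a run's factor
#' is the median of those ratios. A total-sum variant (ratio of each run's
#' summed shared-host-peptide area to the geometric mean of the run sums) is
#' available for comparison.
#'
#' @param table A [peptide_table()].
#' @param method `"median_of_ratios"` (default, robust to individual outlier
#'   peptides) or `"total_sum"`.
#' @return A named numeric vector of factors, one per run in the design.
#'   Dividing a run's areas by its factor puts all runs on a common scale.
#' @export
compute_normalization_factors <- function(table,
                                          method = c("median_of_ratios",
                                                     "total_sum")) {
  assert_peptide_table(table)
  method <- match.arg(method)
  runs <- design_runs(table$design)
  host <- dplyr::filter(table$peptides,
                        .data$organism == "host", .data$peak_area > 0)
  host$key <- paste(host$peptide_sequence, host$modifications, sep = "|")
  wide <- host |>
    dplyr::group_by(.data$key, .data$run_id) |>
    dplyr::summarise(area = sum(.data$peak_area), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "run_id", values_from = "area")
  present <- intersect(runs, names(wide))
  if (length(present) < length(runs)) {
    abort(paste0(
      "No host peptide was observed in run(s) ",
      paste(setdiff(runs, present), collapse = ", "),
      "; cannot normalize. Relax the peptide filter or add a spike-in."
    ))
  }
  mat <- as.matrix(wide[runs])
  shared <- stats::complete.cases(mat)
  if (!any(shared)) {
    abort(paste0(
      "No host peptide is shared by all ", length(runs), " runs; ",
      "cannot normalize. Relax the peptide filter or add a spike-in."
    ))
  }
  mat <- mat[shared, , drop = FALSE]
  geomean <- exp(rowMeans(log(mat)))
  ratios <- mat / geomean
  factors <- switch(
    method,
    median_of_ratios = apply(ratios, 2L, median),
    total_sum = {
      sums <- colSums(mat)
      sums / exp(mean(log(sums)))
    }
  )
  setNames(as.numeric(factors), runs)
}

#' Apply per-run normalization factors to phage signals
#'
#' Divides every phage peptide's peak area by its run's factor; host rows are
#' returned unchanged (they are the anchors, not the signal of interest).
#'
#' @param table A [peptide_table()].
#' @param factors Named numeric vector covering every run in the table, as
#'   returned by [compute_normalization_factors()].
#' @return A [peptide_table()] with normalized phage peak areas.
#' @export
apply_normalization <- function(table, factors) {
  assert_peptide_table(table)
  runs <- unique(table$peptides$run_id)
  missing <- setdiff(runs, names(factors))
  if (length(missing) > 0) {
    abort(paste0("No normalization factor for run(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(factors) | factors <= 0)) {
    abort("Normalization factors must be finite and > 0.")
  }
  out <- table
  phage <- out$peptides$organism == "phage"
  out$peptides$peak_area[phage] <-
    out$peptides$peak_area[phage] /
    unname(factors[out$peptides$run_id[phage]])
  out
}

#' Sum peptide peak areas into per-protein, per-run totals
#'
#' A protein's signal in a run is the sum of the peak areas of the peptides
#' assigned to it. The output is a complete protein-by-run grid over the
#' design's runs: a protein with no observed peptide in a run gets area 0.
#'
#' @param table A [peptide_table()].
#' @param organism Restrict to `"phage"` (default), `"host"`, or `"all"`.
#' @return A tibble with columns `protein_accession`, `run_id`, `area`.
#' @export
aggregate_protein_areas <- function(table, organism = "phage") {
  assert_peptide_table(table)
  pep <- table$peptides
  if (organism != "all") {
    pep <- dplyr::filter(pep, .data$organism == !!organism)
  }
  runs <- design_runs(table$design)
  proteins <- sort(unique(pep$protein_accession))
  grid <- tidyr::expand_grid(protein_accession = proteins, run_id = runs)
  sums <- pep |>
    dplyr::group_by(.data$protein_accession, .data$run_id) |>
    dplyr::summarise(area = sum(.data$peak_area), .groups = "drop")
  grid |>
    dplyr::left_join(sums, by = c("protein_accession", "run_id")) |>
    dplyr::mutate(area = dplyr::coalesce(.data$area, 0))
}

#' Normalized peak area: each protein's fraction of the phage total
#'
#' Within each run, a protein's normalized peak area is its summed peak area
#' divided by the total peak area of all phage proteins in that run, so the
#' fractions in a run sum to 1. A run whose total area is zero has no defined
#' fractions; such runs are flagged (fraction `NA`, with a warning) rather
#' than silently zeroed.
#'
#' @param areas A tibble from [aggregate_protein_areas()] restricted to
#'   phage proteins.
#' @param runs Optional run subset defining the scope; defaults to all runs
#'   present in `areas`.
#' @return A tibble with columns `protein_accession`, `run_id`, `fraction`,
#'   carrying an attribute `undefined_runs` naming any all-zero runs.
#' @export
normalized_peak_area <- function(areas, runs = NULL) {
  areas <- as_tibble(areas)
  if (!is.null(runs)) {
    areas <- dplyr::filter(areas, .data$run_id %in% runs)
  }
  out <- areas |>
    dplyr::group_by(.data$run_id) |>
    dplyr::mutate(total = sum(.data$area)) |>
    dplyr::ungroup() |>
    dplyr::mutate(fraction = ifelse(.data$total > 0,
                                    .data$area / .data$total, NA_real_)) |>
    dplyr::select("protein_accession", "run_id", "fraction")
  undefined <- unique(out$run_id[is.na(out$fraction)])
  if (length(undefined) > 0) {
    warn(paste0("Normalized peak area undefined for all-zero run(s): ",
                paste(undefined, collapse = ", ")))
  }
  attr(out, "undefined_runs") <- undefined
  out
}

#' Score enrichment of each phage protein over the negative control
#'
#' For each protein, the mean normalized peak area over the bait trials is
#' compared with the mean over the control trials (arithmetic means, zeros
#' included). The fold change is their ratio, `Inf` when the protein was
#' never seen in controls but was seen with the bait; proteins never seen
#' with the bait are dropped (they cannot be candidates). `times_detected`
#' counts the bait trials in which the protein had nonzero (biotinylated)
#' signal.
#'
#' @param fractions A tibble with columns `protein_accession`, `run_id`,
#'   `fraction` covering the bait and control runs of `design` (e.g. from
#'   [normalized_peak_area()]).
#' @param design The [experiment_design()].
#' @param bait_label Optional label recorded on the result (e.g. `"ChmA"`).
#' @return An `enrichment_table`: a tibble with columns
#'   `protein_accession`, `times_detected`, `mean_norm_peak_area`,
#'   `mean_norm_peak_area_control`, `fold_change`, `log2_fold_change`,
#'   sorted by the rank key (descending mean normalized peak area), with
#'   attributes `bait_label` and `rank_key`.
#' @export
score_enrichment <- function(fractions, design, bait_label = NULL) {
  assert_design(design)
  fractions <- as_tibble(fractions)
  have <- unique(fractions$run_id)
  missing <- setdiff(design_runs(design), have)
  if (length(missing) > 0) {
    abort(paste0("`fractions` lacks run(s) declared in the design: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(fractions$fraction)) {
    abort("`fractions` contains undefined values (all-zero run?).")
  }
  per_protein <- fractions |>
    dplyr::mutate(arm = dplyr::case_when(
      .data$run_id %in% design$bait_runs ~ "bait",
      .data$run_id %in% design$control_runs ~ "control",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$arm)) |>
    dplyr::group_by(.data$protein_accession) |>
    dplyr::summarise(
      times_detected = sum(.data$arm == "bait" & .data$fraction > 0),
      mean_norm_peak_area =
        sum(.data$fraction[.data$arm == "bait"]) / length(design$bait_runs),
      mean_norm_peak_area_control =
        sum(.data$fraction[.data$arm == "control"]) /
          length(design$control_runs),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$mean_norm_peak_area > 0) |>
    dplyr::mutate(
      times_detected = as.integer(.data$times_detected),
      fold_change = ifelse(
        .data$mean_norm_peak_area_control == 0, Inf,
        .data$mean_norm_peak_area / .data$mean_norm_peak_area_control
      ),
      log2_fold_change = log2(.data$fold_change)
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_norm_peak_area),
                   .data$protein_accession)
  new_enrichment_table(per_protein, bait_label = bait_label,
                       rank_key = "mean_norm_peak_area")
}

new_enrichment_table <- function(x, bait_label = NULL,
                                 rank_key = "mean_norm_peak_area") {
  x <- as_tibble(x)
  attr(x, "bait_label") <- bait_label
  attr(x, "rank_key") <- rank_key
  class(x) <- c("enrichment_table", class(x))
  x
}

#' Filter to enriched proteins and keep the top of the ranking
#'
#' Keeps proteins enriched more than `min_fold` over the control (infinite
#' fold changes always pass), sorts by the rank key and truncates to `top_n`.
#' The default key is the mean normalized peak area, which reproduces the
#' printed ordering of the published candidate tables; ranking by fold
#' change is available instead. Ties are broken by accession so reruns are
#' reproducible.
#'
#' @param results An `enrichment_table`.
#' @param min_fold Minimum fold change, exclusive (default 3: "more than
#'   three-fold").
#' @param top_n Number of rows to keep (default 25).
#' @param rank_key `"mean_norm_peak_area"` (default) or `"fold_change"`.
#' @return An `enrichment_table` with at most `top_n` rows.
#' @export
rank_and_select <- function(results, min_fold = 3, top_n = 25,
                            rank_key = c("mean_norm_peak_area",
                                         "fold_change")) {
  rank_key <- match.arg(rank_key)
  results <- as_tibble(results)
  if (!is.numeric(top_n) || length(top_n) != 1 || top_n < 1) {
    abort("`top_n` must be a single integer >= 1.")
  }
  out <- results |>
    dplyr::filter(.data$fold_change > min_fold) |>
    dplyr::arrange(dplyr::desc(.data[[rank_key]]),
                   .data$protein_accession) |>
    head(n = as.integer(top_n))
  new_enrichment_table(out, bait_label = attr(results, "bait_label"),
                       rank_key = rank_key)
}

#' Run the full enrichment pipeline on one peptide table
#'
#' Convenience wrapper chaining the scoring stages: optional biotinylated
#' peptide filtering, host-peptide normalization, per-protein aggregation,
#' normalized peak area, and enrichment scoring against the control trials.
#'
#' @param table A [peptide_table()] containing both bait and control runs.
#' @param bait_label Optional label recorded on the result.
#' @param filter_biotin Keep only biotinylated peptides first (default
#'   `TRUE`, matching the streptavidin peptide-capture workflow).
#' @param normalization_method Passed to [compute_normalization_factors()].
#' @inheritParams filter_biotinylated
#' @return An `enrichment_table`.
#' @export
run_enrichment <- function(table, bait_label = NULL, filter_biotin = TRUE,
                           normalization_method = "median_of_ratios",
                           delta_mass = 226.08, tolerance = 0.01) {
  assert_peptide_table(table)
  if (filter_biotin) {
    table <- filter_biotinylated(table, delta_mass = delta_mass,
                                 tolerance = tolerance)
  }
  factors <- compute_normalization_factors(table,
                                           method = normalization_method)
  table <- apply_normalization(table, factors)
  areas <- aggregate_protein_areas(table, organism = "phage")
  fractions <- normalized_peak_area(areas)
  score_enrichment(fractions, table$design, bait_label = bait_label)
}
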