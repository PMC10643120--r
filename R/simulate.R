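#' Configure a synthetic proximity-labeling experiment
#'
#' The generator emulates the peptide-level label-free readout of a
#' miniTurboID experiment: a host plus phage proteome digested into tryptic
#' peptides, quantified across bait and control runs, with run-level scale
#' differences, log-normal multiplicative noise, abundance-dependent
#' dropout, lysine biotinylation, and a set of planted bait-specific
#' interactors whose phage proteins are enriched in the bait runs.
#'
#' @param n_host_proteins,n_phage_proteins Proteome sizes (defaults 60 host,
#'   120 phage — a scaled-down proteome that keeps simulations fast).
#' @param peptides_per_protein Integer range (length-2 vector) of peptides
#'   per protein, sampled uniformly (default 2-5).
#' @param n_bait_trials,n_control_trials Run counts (defaults 3 and 3, the
#'   study layout).
#' @param planted_interactors Data frame with columns `index` (phage
#'   protein index) and `fold` (> 1, bait-run enrichment). Default: 20
#'   proteins planted at 16-fold.
#' @param baseline_log10_abundance Length-2 vector `c(mean, sd)` of the
#'   per-peptide log10 baseline peak area (default `c(6, 0.8)`).
#' @param noise_sigma Standard deviation of the log-normal multiplicative
#'   noise on the natural-log scale (default 0.2).
#' @param dropout `NULL` to disable, or a list with `midpoint` (log10 area
#'   at 50% detection) and `slope`; the detection probability is
#'   `plogis(slope * (log10(area) - midpoint))` (default midpoint 4.5,
#'   slope 2).
#' @param run_scale_factors Positive per-run scale factors (bait runs then
#'   control runs), or `NULL` to sample them log-normally (sdlog 0.25) from
#'   the seed.
#' @param biotin_fraction Fraction of peptides carrying the +226.08 Da
#'   biotin adduct on a lysine (default 0.8).
#' @param bait_label Label of the bait fusion (default `"ChmA"`); control
#'   runs are labelled `"GFP-control"`.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_host_proteins = 60L,
                              n_phage_proteins = 120L,
                              peptides_per_protein = c(2L, 5L),
                              n_bait_trials = 3L,
                              n_control_trials = 3L,
                              planted_interactors =
                                data.frame(index = 1:20, fold = 16),
                              baseline_log10_abundance = c(6, 0.8),
                              noise_sigma = 0.2,
                              dropout = list(midpoint = 4.5, slope = 2),
                              run_scale_factors = NULL,
                              biotin_fraction = 0.8,
                              bait_label = "ChmA",
                              seed = 1L) {
  planted_interactors <- as.data.frame(planted_interactors)
  if (nrow(planted_interactors) > 0) {
    if (!all(c("index", "fold") %in% names(planted_interactors))) {
      abort("`planted_interactors` needs columns `index` and `fold`.")
    }
    if (any(planted_interactors$index < 1) ||
        any(planted_interactors$index > n_phage_proteins)) {
      abort("Planted indices must lie in 1..n_phage_proteins.")
    }
    if (any(planted_interactors$fold <= 1)) {
      abort("Planted enrichment folds must be > 1.")
    }
    if (anyDuplicated(planted_interactors$index)) {
      abort("Planted indices must be unique.")
    }
  }
  if (length(peptides_per_protein) != 2 ||
      peptides_per_protein[1] < 1 ||
      peptides_per_protein[2] < peptides_per_protein[1]) {
    abort("`peptides_per_protein` must be an increasing range of >= 1.")
  }
  n_runs <- n_bait_trials + n_control_trials
  if (!is.null(run_scale_factors)) {
    if (length(run_scale_factors) != n_runs ||
        any(run_scale_factors <= 0)) {
      abort(paste0("`run_scale_factors` must be ", n_runs,
                   " positive values."))
    }
  }
  if (biotin_fraction < 0 || biotin_fraction > 1) {
    abort("`biotin_fraction` must lie in [0, 1].")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (!is.null(dropout) &&
      !all(c("midpoint", "slope") %in% names(dropout))) {
    abort("`dropout` must be NULL or list(midpoint=, slope=).")
  }
  structure(
    list(
      n_host_proteins = as.integer(n_host_proteins),
      n_phage_proteins = as.integer(n_phage_proteins),
      peptides_per_protein = as.integer(peptides_per_protein),
      n_bait_trials = as.integer(n_bait_trials),
      n_control_trials = as.integer(n_control_trials),
      planted_interactors = planted_interactors,
      baseline_log10_abundance = as.numeric(baseline_log10_abundance),
      noise_sigma = as.numeric(noise_sigma),
      dropout = dropout,
      run_scale_factors = run_scale_factors,
      biotin_fraction = as.numeric(biotin_fraction),
      bait_label = bait_label,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

random_peptide <- function(min_len = 8L, max_len = 14L) {
  len <- sample(min_len:max_len, 1L)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

#' Simulate one proximity-labeling experiment with known ground truth
#'
#' For every peptide and run, the peak area is the peptide's baseline
#' abundance, multiplied by its protein's planted enrichment fold when the
#' run is a bait run and the protein is a planted (phage) interactor, by the
#' run's scale factor, and by log-normal noise; the observation is then
#' zeroed with the dropout probability implied by its pre-dropout area.
#' Host proteins are never planted, so shared host peptides are valid
#' normalization anchors by construction. The same config and seed always
#' produce the identical table.
#'
#' @param config A [simulation_config()].
#' @return A list with `table` (a [peptide_table()]) and `truth` (a
#'   `ground_truth` list: `planted` with accessions and folds,
#'   `run_scale_factors`, and `protein_abundance`, the per-protein summed
#'   baseline peptide abundance).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from `simulation_config()`.")
  }
  with_preserved_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(config) {
  bait_runs <- sprintf("bait_%d", seq_len(config$n_bait_trials))
  control_runs <- sprintf("ctrl_%d", seq_len(config$n_control_trials))
  runs <- c(bait_runs, control_runs)
  design <- experiment_design(bait_runs, control_runs)

  scale <- config$run_scale_factors
  if (is.null(scale)) {
    scale <- rlnorm(length(runs), meanlog = 0, sdlog = 0.25)
  }
  scale <- setNames(as.numeric(scale), runs)

  host_ids <- sprintf("host_%03d", seq_len(config$n_host_proteins))
  phage_ids <- sprintf("gp%03d", seq_len(config$n_phage_proteins))
  proteins <- tibble(
    protein_accession = c(host_ids, phage_ids),
    organism = rep(c("host", "phage"),
                   c(config$n_host_proteins, config$n_phage_proteins))
  )
  fold <- setNames(rep(1, nrow(proteins)), proteins$protein_accession)
  planted <- config$planted_interactors
  planted_acc <- character(0)
  if (nrow(planted) > 0) {
    planted_acc <- phage_ids[planted$index]
    fold[planted_acc] <- planted$fold
  }

  rng <- config$peptides_per_protein
  n_pep <- sample(rng[1]:rng[2], nrow(proteins), replace = TRUE)
  mu <- config$baseline_log10_abundance[1]
  sd <- config$baseline_log10_abundance[2]

  n_total <- sum(n_pep)
  seqs <- vapply(seq_len(n_total), function(i) random_peptide(),
                 character(1))
  biotin <- runif(n_total) < config$biotin_fraction
  mods <- character(n_total)
  for (i in which(biotin)) {
    pos <- which(strsplit(seqs[i], "")[[1]] == "K")
    if (length(pos) == 0) {
      at <- sample(nchar(seqs[i]), 1L)
      substring(seqs[i], at, at) <- "K"
      pos <- at
    }
    mods[i] <- sprintf("%d:226.08", pos[sample.int(length(pos), 1L)])
  }
  peptides <- tibble(
    protein_accession = rep(proteins$protein_accession, n_pep),
    organism = rep(proteins$organism, n_pep),
    peptide_sequence = seqs,
    modifications = mods,
    baseline = 10^rnorm(n_total, mean = mu, sd = sd)
  )

  obs <- tidyr::expand_grid(
    peptides, run_id = runs
  )
  is_bait_run <- obs$run_id %in% bait_runs
  enr <- ifelse(is_bait_run & obs$organism == "phage",
                unname(fold[obs$protein_accession]), 1)
  noise <- if (config$noise_sigma > 0) {
    rlnorm(nrow(obs), meanlog = 0, sdlog = config$noise_sigma)
  } else {
    rep(1, nrow(obs))
  }
  area <- obs$baseline * enr * unname(scale[obs$run_id]) * noise
  if (!is.null(config$dropout)) {
    p_detect <- plogis(config$dropout$slope *
                         (log10(area) - config$dropout$midpoint))
    area <- ifelse(runif(length(area)) < p_detect, area, 0)
  }

  table <- peptide_table(
    tibble(
      run_id = obs$run_id,
      bait_label = ifelse(is_bait_run, config$bait_label, "GFP-control"),
      replicate_index = as.integer(sub("^.*_", "", obs$run_id)),
      protein_accession = obs$protein_accession,
      organism = obs$organism,
      peptide_sequence = obs$peptide_sequence,
      modifications = obs$modifications,
      peak_area = area
    ),
    design
  )
  truth <- structure(
    list(
      planted = tibble(
        protein_accession = planted_acc,
        fold = if (nrow(planted) > 0) planted$fold else numeric(0)
      ),
      run_scale_factors = scale,
      protein_abundance = peptides |>
        dplyr::group_by(.data$protein_accession, .data$organism) |>
        dplyr::summarise(abundance = sum(.data$baseline),
                         .groups = "drop"),
      config = config
    ),
    class = "ground_truth"
  )
  list(table = table, truth = truth)
}

#' Precision and recall of planted interactors among the top candidates
#'
#' @param results A ranked `enrichment_table` (e.g. from
#'   [run_enrichment()] or [rank_and_select()]).
#' @param truth The `ground_truth` from [simulate_experiment()].
#' @param top_n Size of the candidate window (default 25).
#' @return A list with `precision` (`NA` with a warning when `results` is
#'   empty), `recall` (`NA` with a warning when nothing was planted) and
#'   `n_recovered`.
#' @export
evaluate_recovery <- function(results, truth, top_n = 25) {
  results <- as_tibble(results)
  planted <- truth$planted$protein_accession
  top <- head(results$protein_accession, top_n)
  n_rec <- length(intersect(top, planted))
  precision <- if (nrow(results) == 0) {
    warn("Empty results: precision undefined.")
    NA_real_
  } else {
    n_rec / min(top_n, nrow(results))
  }
  recall <- if (length(planted) == 0) {
    warn("No planted interactors: recall undefined.")
    NA_real_
  } else if (nrow(results) == 0) {
    0
  } else {
    n_rec / length(planted)
  }
  list(precision = precision, recall = recall, n_recovered = n_rec)
}

#' Expected pipeline fold change for each phage protein, analytically
#'
#' Under the generative model without dropout, log-normal noise has the same
#' mean multiplier in every run, and run scaling cancels through the
#' host-peptide normalization, so a protein's expected normalized peak area
#' is its abundance share of the phage total. The expected fold change of
#' protein p is therefore its planted fold deflated by the normalization
#' coupling — the factor by which the planted proteins inflate the phage
#' total in the bait runs:
#' `fold_p * sum_j(A_j) / sum_j(fold_j * A_j)` over phage proteins j. With
#' `truth` supplied the realized baseline abundances `A_j` are used (exact
#' for `noise_sigma = 0`); otherwise all `A_j` are taken as equal, their
#' common expectation.
#'
#' @param config A [simulation_config()] with `dropout = NULL`.
#' @param truth Optional `ground_truth` from a simulation under `config`.
#' @return A named numeric vector: expected fold change per phage protein.
#' @export
closed_form_expectation <- function(config, truth = NULL) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from `simulation_config()`.")
  }
  if (!is.null(config$dropout)) {
    abort("No closed form with dropout enabled; set `dropout = NULL`.")
  }
  phage_ids <- sprintf("gp%03d", seq_len(config$n_phage_proteins))
  fold <- setNames(rep(1, length(phage_ids)), phage_ids)
  if (nrow(config$planted_interactors) > 0) {
    fold[phage_ids[config$planted_interactors$index]] <-
      config$planted_interactors$fold
  }
  abundance <- setNames(rep(1, length(phage_ids)), phage_ids)
  if (!is.null(truth)) {
    ab <- truth$protein_abundance
    ab <- ab[ab$organism == "phage", ]
    abundance[ab$protein_accession] <- ab$abundance
  }
  coupling <- sum(abundance) / sum(fold * abundance)
  fold * coupling
}
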