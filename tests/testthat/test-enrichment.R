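test_that("normalization factors follow the median-of-ratios arithmetic", {
  # identical areas in every run -> all factors 1
  flat <- tiny_experiment(run_scale = c(b1 = 1, b2 = 1, b3 = 1,
                                        c1 = 1, c2 = 1, c3 = 1))
  expect_equal(unname(compute_normalization_factors(flat)),
               rep(1, 6))

  # one run doubled: hand computation on 3 shared peptides over 3 runs.
  # Each peptide's areas are (x, x, 2x): geometric mean x * 2^(1/3), so the
  # doubled run's ratio is 2^(2/3) and the others' 2^(-1/3).
  design <- experiment_design(c("r1", "r2"), "r3")
  rows <- expand.grid(
    run_id = c("r1", "r2", "r3"), pep = c("AKAAAA", "CKCCCC", "DKDDDD"),
    stringsAsFactors = FALSE
  )
  rows$bait_label <- ifelse(rows$run_id == "r3", "GFP-control", "ChmA")
  rows$replicate_index <- 1L
  rows$protein_accession <- "hostA"
  rows$organism <- "host"
  rows$peptide_sequence <- rows$pep
  rows$modifications <- "2:226.08"
  base <- c(AKAAAA = 10, CKCCCC = 30, DKDDDD = 5)
  rows$peak_area <- base[rows$pep] * ifelse(rows$run_id == "r3", 2, 1)
  table <- peptide_table(rows[setdiff(names(rows), "pep")], design)
  factors <- compute_normalization_factors(table)
  expect_equal(unname(factors[c("r1", "r2", "r3")]),
               c(2^(-1 / 3), 2^(-1 / 3), 2^(2 / 3)))
  # factors multiply to 1 (geometric mean 1) for balanced shared peptides
  expect_equal(prod(factors), 1)

  # total-sum variant agrees here (all peptides scale together)
  expect_equal(compute_normalization_factors(table, method = "total_sum"),
               factors)
})

test_that("missing shared host peptides is an error, not a silent factor", {
  design <- experiment_design("r1", "r2")
  rows <- data.frame(
    run_id = c("r1", "r2"), bait_label = c("ChmA", "GFP-control"),
    replicate_index = 1L, protein_accession = "hostA", organism = "host",
    peptide_sequence = c("AKAAAA", "CKCCCC"),  # disjoint between runs
    modifications = "2:226.08", peak_area = 10
  )
  expect_error(
    compute_normalization_factors(peptide_table(rows, design)),
    "shared"
  )
})

test_that("normalization rescales phage rows only and undoes run scaling", {
  table <- tiny_experiment()
  factors <- compute_normalization_factors(table)
  norm <- apply_normalization(table, factors)
  host_rows <- table$peptides$organism == "host"
  expect_equal(norm$peptides$peak_area[host_rows],
               table$peptides$peak_area[host_rows])

  # identity factors leave the table unchanged; explicit division holds
  ident <- setNames(rep(1, 6), names(factors))
  expect_equal(apply_normalization(table, ident)$peptides, table$peptides)
  r <- table$peptides$run_id[!host_rows][1]
  expect_equal(
    norm$peptides$peak_area[!host_rows],
    table$peptides$peak_area[!host_rows] /
      unname(factors[table$peptides$run_id[!host_rows]])
  )
  expect_error(apply_normalization(table, factors[-1]), "factor")

  # scaling one run's raw areas (host and phage together) by c leaves
  # every downstream fold change unchanged: the run's shared host peptides
  # scale with it, so the factor absorbs the whole rescaling
  scaled <- tiny_experiment(run_scale = c(b1 = 1, b2 = 2, b3 = 0.5,
                                          c1 = 7, c2 = 1, c3 = 4))
  res0 <- run_enrichment(table)
  res1 <- run_enrichment(scaled)
  expect_equal(res1$fold_change, res0$fold_change)
  expect_equal(res1$mean_norm_peak_area, res0$mean_norm_peak_area)
})

test_that("protein areas sum peptides per run with zeros for absences", {
  table <- tiny_experiment()
  areas <- aggregate_protein_areas(table)
  # gpB is absent from b2 and all control runs
  gpB <- areas[areas$protein_accession == "gpB", ]
  expect_equal(gpB$area[gpB$run_id == "b2"], 0)
  expect_equal(sum(gpB$area > 0), 2L)

  # brute-force groupby-sum oracle over the phage rows
  pep <- as.data.frame(table$peptides)
  pep <- pep[pep$organism == "phage", ]
  for (i in seq_len(nrow(areas))) {
    expect_equal(
      areas$area[i],
      sum(pep$peak_area[pep$protein_accession ==
                          areas$protein_accession[i] &
                          pep$run_id == areas$run_id[i]])
    )
  }
})

test_that("normalized peak areas are per-run fractions summing to one", {
  table <- tiny_experiment()
  fractions <- normalized_peak_area(aggregate_protein_areas(table))
  sums <- tapply(fractions$fraction, fractions$run_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # two proteins with areas 5 and 15 split 0.25 / 0.75
  toy <- tibble::tibble(
    protein_accession = c("p1", "p2"), run_id = "r",
    area = c(5, 15)
  )
  expect_equal(normalized_peak_area(toy)$fraction, c(0.25, 0.75))

  # an all-zero run is flagged, not silently zeroed
  zero <- tibble::tibble(protein_accession = c("p1", "p2"),
                         run_id = "dead", area = 0)
  expect_warning(out <- normalized_peak_area(zero), "dead")
  expect_true(all(is.na(out$fraction)))
  expect_equal(attr(out, "undefined_runs"), "dead")
})

test_that("fold change is infinite exactly when absent from controls", {
  table <- tiny_experiment()
  res <- run_enrichment(table)
  expect_s3_class(res, "enrichment_table")
  # gpB: bait-only detections -> +Inf; gpD: control-only -> dropped
  expect_true(is.infinite(res$fold_change[res$protein_accession == "gpB"]))
  expect_false("gpD" %in% res$protein_accession)
  expect_equal(
    is.infinite(res$fold_change),
    res$mean_norm_peak_area_control == 0 & res$mean_norm_peak_area > 0
  )
  expect_equal(res$log2_fold_change[is.finite(res$fold_change)],
               log2(res$fold_change[is.finite(res$fold_change)]))
  expect_true(all(res$times_detected >= 1L & res$times_detected <= 3L))

  # 16x enrichment gives log2 fold change 4; equality gives 0
  design <- experiment_design(c("b1", "b2"), c("c1", "c2"))
  frac <- tibble::tibble(
    protein_accession = rep(c("p", "q"), each = 4),
    run_id = rep(c("b1", "b2", "c1", "c2"), 2),
    fraction = c(0.8, 0.8, 0.05, 0.05, 0.2, 0.2, 0.95, 0.95)
  )
  scored <- score_enrichment(frac, design)
  expect_equal(scored$log2_fold_change[scored$protein_accession == "p"], 4)
  same <- tibble::tibble(protein_accession = "p",
                         run_id = c("b1", "b2", "c1", "c2"),
                         fraction = 0.5)
  expect_equal(score_enrichment(same, design)$log2_fold_change, 0)
})

test_that("selection applies the three-fold filter, ranking and ties", {
  res <- tibble::tibble(
    protein_accession = c("a", "b", "c", "d", "e"),
    times_detected = 3L,
    mean_norm_peak_area = c(0.5, 0.3, 0.3, 0.2, 0.1),
    mean_norm_peak_area_control = 0.01,
    fold_change = c(2.9, 50, 10, Inf, 3.0),
    log2_fold_change = log2(c(2.9, 50, 10, Inf, 3.0))
  )
  # strictly more than three-fold: 2.9 and exactly 3.0 are out, Inf is in
  sel <- rank_and_select(res, min_fold = 3, top_n = 25)
  expect_equal(sel$protein_accession, c("b", "c", "d"))
  # tie on the rank key broken by accession, stable across reruns
  expect_equal(rank_and_select(res, min_fold = 0, top_n = 5),
               rank_and_select(res, min_fold = 0, top_n = 5))
  expect_equal(
    rank_and_select(res, min_fold = 0, top_n = 5)$protein_accession[2:3],
    c("b", "c")
  )
  # truncation and the fold-change key
  expect_equal(nrow(rank_and_select(res, min_fold = 0, top_n = 2)), 2L)
  expect_equal(
    rank_and_select(res, min_fold = 0, top_n = 2,
                    rank_key = "fold_change")$protein_accession,
    c("d", "b")
  )
  expect_error(rank_and_select(res, top_n = 0), "top_n")
})

test_that("the whole pipeline matches a hand-coded spreadsheet oracle", {
  table <- tiny_experiment()
  res <- as.data.frame(run_enrichment(table))
  expected <- oracle_enrichment(table)
  expect_equal(res$protein_accession, expected$protein_accession)
  expect_equal(res$times_detected, expected$times_detected)
  expect_equal(res$mean_norm_peak_area, expected$mean_norm_peak_area)
  expect_equal(res$mean_norm_peak_area_control,
               expected$mean_norm_peak_area_control)
  expect_equal(res$fold_change, expected$fold_change)
  expect_equal(res$log2_fold_change, expected$log2_fold_change)
})

test_that("monotonicity: raising a protein's bait signal never demotes it", {
  base <- tiny_experiment()
  res0 <- run_enrichment(base)
  f0 <- res0$fold_change[res0$protein_accession == "gpC"]
  boosted <- base
  idx <- boosted$peptides$protein_accession == "gpC" &
    boosted$peptides$run_id %in% base$design$bait_runs
  boosted$peptides$peak_area[idx] <- boosted$peptides$peak_area[idx] * 5
  res1 <- run_enrichment(boosted)
  f1 <- res1$fold_change[res1$protein_accession == "gpC"]
  expect_gte(f1, f0)
  expect_lte(which(res1$protein_accession == "gpC"),
             which(res0$protein_accession == "gpC"))
})
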