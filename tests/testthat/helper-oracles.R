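# Independent oracles and fixture builders. Everything here is written as
# plain base-R "spreadsheet" computation, deliberately not sharing code with
# the package implementation.

# --- tiny 3+3 peptide fixture ------------------------------------------------

# Deterministic small experiment: 2 shared host peptides and a handful of
# phage proteins, all peptides biotinylated at a lysine, with run-level
# scale differences baked in.
tiny_experiment <- function(run_scale = c(b1 = 1, b2 = 2, b3 = 0.5,
                                          c1 = 1, c2 = 1, c3 = 4)) {
  runs <- names(run_scale)
  host_pep <- data.frame(
    protein_accession = c("hostA", "hostA", "hostB"),
    peptide_sequence = c("AKLMNPK", "GGKDEF", "KVVWYA"),
    modifications = c("2:226.08", "3:226.08", "1:226.08"),
    base = c(100, 40, 250)
  )
  # per-(protein, run) base areas for one peptide each; zero = not observed
  phage_base <- rbind(
    gpA = c(b1 = 80, b2 = 80, b3 = 80, c1 = 5, c2 = 5, c3 = 5),
    gpB = c(b1 = 12, b2 = 0, b3 = 12, c1 = 0, c2 = 0, c3 = 0),
    gpC = c(b1 = 30, b2 = 30, b3 = 30, c1 = 30, c2 = 30, c3 = 30),
    gpD = c(b1 = 0, b2 = 0, b3 = 0, c1 = 9, c2 = 9, c3 = 9)
  )
  phage_seq <- c(gpA = "KAAAAAA", gpB = "KCCCCCC", gpC = "KDDDDDD",
                 gpD = "KEEEEEE")
  rows <- list()
  for (r in runs) {
    for (i in seq_len(nrow(host_pep))) {
      rows[[length(rows) + 1]] <- data.frame(
        run_id = r,
        bait_label = if (startsWith(r, "b")) "ChmA" else "GFP-control",
        replicate_index = as.integer(substring(r, 2)),
        protein_accession = host_pep$protein_accession[i],
        organism = "host",
        peptide_sequence = host_pep$peptide_sequence[i],
        modifications = host_pep$modifications[i],
        peak_area = host_pep$base[i] * run_scale[[r]]
      )
    }
    for (g in rownames(phage_base)) {
      if (phage_base[g, r] > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          run_id = r,
          bait_label = if (startsWith(r, "b")) "ChmA" else "GFP-control",
          replicate_index = as.integer(substring(r, 2)),
          protein_accession = g,
          organism = "phage",
          peptide_sequence = phage_seq[[g]],
          modifications = "1:226.08",
          peak_area = phage_base[g, r] * run_scale[[r]]
        )
      }
    }
  }
  peptide_table(do.call(rbind, rows),
                experiment_design(c("b1", "b2", "b3"),
                                  c("c1", "c2", "c3")))
}

# --- hand-coded enrichment oracle --------------------------------------------

# Full spreadsheet-style recomputation of the enrichment pipeline with base
# loops: median-of-ratios host normalization, per-protein sums, phage-total
# fractions, 3-vs-3 means, fold change, detection counts.
oracle_enrichment <- function(table) {
  pep <- as.data.frame(table$peptides)
  design <- table$design
  runs <- c(design$bait_runs, design$control_runs)

  host <- pep[pep$organism == "host" & pep$peak_area > 0, ]
  host$key <- paste(host$peptide_sequence, host$modifications)
  keys <- unique(host$key)
  shared_ratio <- list()
  for (k in keys) {
    areas <- sapply(runs, function(r) {
      sum(host$peak_area[host$key == k & host$run_id == r])
    })
    if (all(areas > 0)) {
      gm <- exp(mean(log(areas)))
      shared_ratio[[k]] <- areas / gm
    }
  }
  stopifnot(length(shared_ratio) > 0)
  ratio_mat <- do.call(rbind, shared_ratio)
  factors <- apply(ratio_mat, 2, stats::median)

  phage <- pep[pep$organism == "phage", ]
  proteins <- sort(unique(phage$protein_accession))
  area <- matrix(0, length(proteins), length(runs),
                 dimnames = list(proteins, runs))
  for (i in seq_len(nrow(phage))) {
    r <- phage$run_id[i]
    area[phage$protein_accession[i], r] <-
      area[phage$protein_accession[i], r] +
      phage$peak_area[i] / factors[[r]]
  }
  frac <- sweep(area, 2, colSums(area), "/")

  out <- list()
  for (p in proteins) {
    bait <- frac[p, design$bait_runs]
    ctrl <- frac[p, design$control_runs]
    mb <- mean(bait)
    mc <- mean(ctrl)
    if (mb == 0) next
    fc <- if (mc == 0) Inf else mb / mc
    out[[p]] <- data.frame(
      protein_accession = p,
      times_detected = sum(bait > 0),
      mean_norm_peak_area = mb,
      mean_norm_peak_area_control = mc,
      fold_change = fc,
      log2_fold_change = log2(fc)
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$mean_norm_peak_area, res$protein_accession), ]
  rownames(res) <- NULL
  res
}

# --- Gotoh global-alignment oracle -------------------------------------------

# Affine-gap Needleman-Wunsch over an explicit 3-state DP, returning the
# optimal score plus the max and min number of identical aligned columns
# over all co-optimal alignments (every prefix of an optimal path is itself
# optimal, so identity bounds propagate cell by cell).
oracle_global_alignment <- function(a, b, sub, gap_open, gap_extend) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  neg <- -1e9
  gap1 <- gap_open + gap_extend
  # state 1 = match/mismatch, 2 = gap in b (consume a), 3 = gap in a
  S <- array(neg, c(n + 1, m + 1, 3))
  MX <- array(NA_real_, c(n + 1, m + 1, 3))
  MN <- array(NA_real_, c(n + 1, m + 1, 3))
  S[1, 1, 1] <- 0
  MX[1, 1, 1] <- MN[1, 1, 1] <- 0
  for (i in seq_len(n)) {
    S[i + 1, 1, 2] <- -(gap_open + gap_extend * i)
    MX[i + 1, 1, 2] <- MN[i + 1, 1, 2] <- 0
  }
  for (j in seq_len(m)) {
    S[1, j + 1, 3] <- -(gap_open + gap_extend * j)
    MX[1, j + 1, 3] <- MN[1, j + 1, 3] <- 0
  }
  best3 <- function(scores, mx, mn, add_id = 0) {
    s <- max(scores)
    if (s <= neg / 2) return(list(s = neg, mx = NA_real_, mn = NA_real_))
    hit <- which(scores == s)
    list(s = s, mx = max(mx[hit]) + add_id, mn = min(mn[hit]) + add_id)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- sub[a[i], b[j]]
      id <- as.numeric(a[i] == b[j])
      prev <- best3(S[i, j, ], MX[i, j, ], MN[i, j, ], add_id = id)
      S[i + 1, j + 1, 1] <- prev$s + sc
      MX[i + 1, j + 1, 1] <- prev$mx
      MN[i + 1, j + 1, 1] <- prev$mn
      cand <- c(S[i, j + 1, 1] - gap1, S[i, j + 1, 2] - gap_extend,
                S[i, j + 1, 3] - gap1)
      g <- best3(cand, MX[i, j + 1, ], MN[i, j + 1, ])
      S[i + 1, j + 1, 2] <- g$s
      MX[i + 1, j + 1, 2] <- g$mx
      MN[i + 1, j + 1, 2] <- g$mn
      cand <- c(S[i + 1, j, 1] - gap1, S[i + 1, j, 2] - gap1,
                S[i + 1, j, 3] - gap_extend)
      g <- best3(cand, MX[i + 1, j, ], MN[i + 1, j, ])
      S[i + 1, j + 1, 3] <- g$s
      MX[i + 1, j + 1, 3] <- g$mx
      MN[i + 1, j + 1, 3] <- g$mn
    }
  }
  fin <- best3(S[n + 1, m + 1, ], MX[n + 1, m + 1, ], MN[n + 1, m + 1, ])
  list(score = fin$s, max_identical = fin$mx, min_identical = fin$mn)
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# --- independent codon-table oracle ------------------------------------------

oracle_codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(oracle_codon_table[codons], collapse = "")
}

extdata_path <- function(file) {
  system.file("extdata", file, package = "phagemap", mustWork = TRUE)
}
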