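#' Parameters for global pairwise protein alignment
#'
#' Percent identity is computed from a Needleman-Wunsch global (end-to-end)
#' alignment with affine gap penalties: a gap of length L costs
#' `gap_open + L * gap_extend`. The identity denominator is either the full
#' alignment length (gap columns counted, the default) or the length of the
#' shorter sequence.
#'
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative gap penalties (defaults 10 and
#'   0.5).
#' @param identity_denominator `"alignment_length"` or `"shorter_sequence"`.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10,
                             gap_extend = 0.5,
                             identity_denominator = c("alignment_length",
                                                      "shorter_sequence")) {
  if (gap_open < 0 || gap_extend < 0) {
    abort("Gap penalties must be >= 0.")
  }
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         identity_denominator = match.arg(identity_denominator)),
    class = "alignment_params"
  )
}

substitution_matrix <- function(name) {
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env)) {
    abort(paste0("Unknown substitution matrix: ", name))
  }
  get(name, envir = env)
}

#' Percent identity of two proteins under global alignment
#'
#' @param a,b Non-empty protein sequences (character strings).
#' @param params An [alignment_params()].
#' @return Percent identity in \[0, 100\], with the optimal alignment score
#'   attached as attribute `"score"`.
#' @export
pairwise_identity <- function(a, b, params = alignment_params()) {
  a <- sub("\\*$", "", toupper(as.character(a)))
  b <- sub("\\*$", "", toupper(as.character(b)))
  if (nchar(a) == 0 || nchar(b) == 0) {
    abort("Both sequences must be non-empty.")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  identical_cols <- sum(pa == sa & pa != "-")
  denom <- switch(params$identity_denominator,
                  alignment_length = length(pa),
                  shorter_sequence = min(nchar(a), nchar(b)))
  out <- 100 * identical_cols / denom
  attr(out, "score") <- Biostrings::score(aln)
  out
}

#' Mean pairwise percent identity of a homolog family
#'
#' Averages [pairwise_identity()] over all unordered pairs of the input
#' sequences — the statistic used to contrast the conservation of the major
#' nuclear-shell lattice protein family against the much more divergent
#' shell-pore protein family.
#'
#' @param seqs Named character vector or list of at least two protein
#'   sequences.
#' @param params An [alignment_params()].
#' @return A list with `mean_identity` (mean over all C(n,2) pairs) and
#'   `identity_matrix` (symmetric percent-identity matrix, diagonal 100).
#' @export
mean_pairwise_identity <- function(seqs, params = alignment_params()) {
  seqs <- unlist(as.list(seqs))
  n <- length(seqs)
  if (n < 2) abort("Need at least two sequences.")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  mat <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pid <- as.numeric(pairwise_identity(seqs[[i]], seqs[[j]], params))
      mat[i, j] <- mat[j, i] <- pid
      vals <- c(vals, pid)
    }
  }
  list(mean_identity = mean(vals), identity_matrix = mat)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to a protein FASTA file.
#' @return A named character vector (names are the first header words).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

# Average and monoisotopic residue masses (Da) of the 20 standard amino
# acids; a peptide's mass adds one water.
residue_masses <- list(
  average = c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  ),
  monoisotopic = c(
    A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
    C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
    H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
    M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
    T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
  )
)
water_mass <- c(average = 18.0153, monoisotopic = 18.010565)

#' Molecular weight of a protein from its sequence
#'
#' Sums residue masses and adds one water. Average masses are the default,
#' the appropriate scale for comparison with solution measurements such as
#' SEC-MALS; monoisotopic masses are available for MS work. A trailing
#' `"*"` is ignored; any other non-standard residue is an error naming the
#' character.
#'
#' @param protein Protein sequence over the 20 standard residues.
#' @param mass_type `"average"` (default) or `"monoisotopic"`.
#' @return The mass in Da (divide by 1000 for kDa).
#' @export
molecular_weight <- function(protein, mass_type = c("average",
                                                    "monoisotopic")) {
  mass_type <- match.arg(mass_type)
  protein <- sub("\\*$", "", toupper(as.character(protein)))
  if (nchar(protein) == 0) abort("Protein sequence must be non-empty.")
  residues <- strsplit(protein, "")[[1]]
  masses <- residue_masses[[mass_type]]
  unknown <- setdiff(residues, names(masses))
  if (length(unknown) > 0) {
    abort(paste0("Non-standard residue(s): ",
                 paste(unknown, collapse = ", ")))
  }
  unname(sum(masses[residues]) + water_mass[[mass_type]])
}
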