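#' Define an intron-aware gene model
#'
#' Coordinates are 1-based inclusive on the forward genome strand, the NCBI
#' convention. Exons must be ascending and non-overlapping, and the total
#' spliced length must be divisible by 3 so the model translates cleanly.
#'
#' @param gene_id Gene identifier, e.g. `"gp65-66"`.
#' @param exons A two-column matrix or data frame of exon `start`/`end`
#'   coordinates, in transcription order on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param genetic_code NCBI translation table id (default 11, bacterial).
#' @return A `gene_model` object.
#' @examples
#' gene_model("gp65-66", rbind(c(53811, 55004), c(55455, 56447)))
#' @export
gene_model <- function(gene_id, exons, strand = "+", genetic_code = 11L) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2) abort("`exons` must have two columns: start, end.")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "start"] > exons[, "end"])) {
    abort(paste0("Gene model '", gene_id, "': exon start > end."))
  }
  if (nrow(exons) > 1) {
    if (any(diff(exons[, "start"]) <= 0) ||
        any(exons[-1, "start"] <= exons[-nrow(exons), "end"])) {
      abort(paste0("Gene model '", gene_id,
                   "': exons must be ascending and non-overlapping."))
    }
  }
  total <- sum(exons[, "end"] - exons[, "start"] + 1L)
  if (total %% 3L != 0L) {
    abort(paste0("Gene model '", gene_id, "': spliced length ", total,
                 " nt is not divisible by 3."))
  }
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'.")
  structure(
    list(gene_id = gene_id, exons = exons, strand = strand,
         genetic_code = as.integer(genetic_code)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  coords <- paste(x$exons[, "start"], x$exons[, "end"], sep = "-",
                  collapse = ",")
  cat("<gene_model> ", x$gene_id, " (", x$strand, ") ", coords,
      " [code ", x$genetic_code, "]\n", sep = "")
  invisible(x)
}

#' Read a genome sequence from FASTA
#'
#' @param path Path to a single-record nucleotide FASTA.
#' @return A `genome_sequence`: list with `accession` (first word of the
#'   header) and `sequence` (uppercase character string).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1) abort("FASTA contains no sequence.")
  genome_sequence(sub("\\s.*$", "", names(set)[1]),
                  as.character(set[[1]]))
}

#' Construct a genome sequence object
#'
#' @param accession Sequence accession or identifier.
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @return A `genome_sequence`.
#' @export
genome_sequence <- function(accession, sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0) abort("Genome sequence must be non-empty.")
  if (grepl("[^ACGTN]", sequence)) {
    abort("Genome sequence may only contain A, C, G, T, N.")
  }
  structure(list(accession = accession, sequence = sequence),
            class = "genome_sequence")
}

#' Extract the spliced coding sequence of a gene model
#'
#' Concatenates the exon substrings in listed order, dropping any intervening
#' introns, and reverse-complements the result for minus-strand models. The
#' spliced length always equals the sum of the exon lengths.
#'
#' @param genome A `genome_sequence`.
#' @param model A [gene_model()].
#' @return The spliced CDS as an uppercase character string.
#' @export
extract_spliced_cds <- function(genome, model) {
  if (!inherits(genome, "genome_sequence")) {
    abort("`genome` must be a `genome_sequence`.")
  }
  if (!inherits(model, "gene_model")) {
    abort("`model` must be a `gene_model`.")
  }
  glen <- nchar(genome$sequence)
  if (any(model$exons < 1L) || any(model$exons > glen)) {
    abort(paste0("Gene model '", model$gene_id,
                 "': exon coordinates outside genome (1-", glen, ")."))
  }
  pieces <- substring(genome$sequence,
                      model$exons[, "start"], model$exons[, "end"])
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") {
    cds <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds))
    )
  }
  if (nchar(cds) %% 3L != 0L) {
    abort(paste0("Gene model '", model$gene_id,
                 "': spliced CDS length not divisible by 3."))
  }
  cds
}

#' Translate a coding sequence
#'
#' Translates under the given NCBI genetic code. A terminal stop codon is
#' rendered as a trailing `"*"`; an internal stop codon is an error naming
#' its codon position; ambiguous codons (containing N) translate to `"X"`
#' with a warning. A non-ATG initiator gets a warning, not an error, since
#' phages use alternative start codons.
#'
#' @param cds Nucleotide string with length divisible by 3.
#' @param genetic_code NCBI translation table id (default 11).
#' @return The protein as a character string (including any trailing `"*"`).
#' @export
translate_cds <- function(cds, genetic_code = 11L) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n == 0 || n %% 3L != 0L) {
    abort(paste0("CDS length ", n, " nt is not a positive multiple of 3."))
  }
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  if (substring(cds, 1L, 3L) != "ATG") {
    warn(paste0("Non-ATG initiator codon '", substring(cds, 1L, 3L), "'."))
  }
  if (grepl("N", cds, fixed = TRUE)) {
    warn("Ambiguous bases present; affected codons translate to 'X'.")
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), genetic.code = code,
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  internal <- which(strsplit(substr(aa, 1L, nchar(aa) - 1L), "")[[1]] == "*")
  if (length(internal) > 0) {
    abort(paste0("Internal stop codon at codon position ", internal[1],
                 " (nucleotide ", (internal[1] - 1L) * 3L + 1L, ")."))
  }
  aa
}

#' Build a protein FASTA database from gene models
#'
#' Extracts and translates every model and writes one FASTA record per
#' model with header `"<gene_id> <accession>:<coords>"`. Any model that
#' fails extraction or translation aborts with the model named. The output
#' is the search database used for MS protein identification over a
#' re-annotated locus.
#'
#' @param genome A `genome_sequence`.
#' @param models A list of [gene_model()]s.
#' @param path Output FASTA path.
#' @param strip_stop Drop the trailing `"*"` from each record
#'   (default `FALSE`, keeping the full translation).
#' @return Invisibly, a named character vector of the written protein
#'   sequences.
#' @export
build_protein_db <- function(genome, models, path, strip_stop = FALSE) {
  if (inherits(models, "gene_model")) models <- list(models)
  proteins <- vapply(models, function(model) {
    res <- tryCatch(
      translate_cds(extract_spliced_cds(genome, model),
                    genetic_code = model$genetic_code),
      error = function(e) {
        abort(paste0("Model '", model$gene_id, "' failed: ",
                     conditionMessage(e)))
      }
    )
    if (strip_stop) res <- sub("\\*$", "", res)
    res
  }, character(1))
  headers <- vapply(models, function(model) {
    coords <- paste(model$exons[, "start"], model$exons[, "end"],
                    sep = "-", collapse = ",")
    paste0(model$gene_id, " ", genome$accession, ":", coords)
  }, character(1))
  set <- Biostrings::AAStringSet(proteins)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(setNames(proteins,
                     vapply(models, `[[`, character(1), "gene_id")))
}

#' Compare a computed protein against a reference sequence
#'
#' @param protein,reference Protein strings (trailing `"*"` compared as-is).
#' @return A list with `match` (logical) and `first_mismatch` (integer
#'   position of the first differing residue, `NA` when identical; a length
#'   difference with an identical prefix mismatches at the first position
#'   beyond the shorter sequence).
#' @export
verify_against_reference <- function(protein, reference) {
  protein <- as.character(protein)
  reference <- as.character(reference)
  if (identical(protein, reference)) {
    return(list(match = TRUE, first_mismatch = NA_integer_))
  }
  a <- strsplit(protein, "")[[1]]
  b <- strsplit(reference, "")[[1]]
  n <- min(length(a), length(b))
  diff <- which(a[seq_len(n)] != b[seq_len(n)])
  pos <- if (length(diff) > 0) diff[1] else n + 1L
  list(match = FALSE, first_mismatch = as.integer(pos))
}

#' Gene models for the re-annotated region of the phage genome
#'
#' The published re-annotation of the misannotated region between gp64 and
#' gp68: gp65-66, a single protein whose coding sequence is interrupted by
#' an intron spanning nucleotides 55005-55454, and the single-exon gp67.
#'
#' @return A named list of two [gene_model()]s.
#' @export
phipa3_gene_models <- function() {
  list(
    "gp65-66" = gene_model("gp65-66",
                           rbind(c(53811L, 55004L), c(55455L, 56447L))),
    "gp67" = gene_model("gp67", rbind(c(56450L, 58420L)))
  )
}

#' Reference protein sequences for the re-annotated genes
#'
#' The published translations of gp65-66 and gp67, shipped as a FASTA
#' fixture, used as golden references for the spliced extraction and
#' translation machinery.
#'
#' @return A named character vector of protein sequences (with trailing
#'   `"*"`).
#' @export
phipa3_reannotated_proteins <- function() {
  path <- system.file("extdata", "phipa3_reannotated_proteins.fasta",
                      package = "phagemap", mustWork = TRUE)
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

# Fixed codon per residue for deterministic back-translation (code 11).
default_back_codons <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", E = "GAA",
  Q = "CAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT", "*" = "TAA"
)

#' Deterministically back-translate a protein
#'
#' Picks one fixed codon per residue, so `translate_cds(back_translate(p))`
#' returns `p` for any protein starting with M. Used to build synthetic
#' genomic loci around known protein sequences.
#'
#' @param protein Protein string (may include a trailing `"*"`).
#' @return A nucleotide string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein) {
  residues <- strsplit(as.character(protein), "")[[1]]
  unknown <- setdiff(residues, names(default_back_codons))
  if (length(unknown) > 0) {
    abort(paste0("Cannot back-translate residue(s): ",
                 paste(unknown, collapse = ", ")))
  }
  paste(default_back_codons[residues], collapse = "")
}

#' Build a synthetic genome carrying given gene models
#'
#' Constructs a synthetic nucleotide sequence in which each gene model's
#' exons spell out the deterministic back-translation of a supplied protein,
#' while intergenic and intronic positions are seeded random filler. This is
#' a synthetic stand-in for a genome that is not bundled; only the protein
#' sequences and the exon coordinates are real, and any analysis of the
#' filler sequence is meaningless.
#'
#' @param models Named list of plus-strand [gene_model()]s.
#' @param proteins Named character vector of protein sequences, one per
#'   model, each with `3 * nchar(protein)` equal to the model's spliced
#'   length.
#' @param length Genome length (default: 50 nt past the last exon).
#' @param seed Integer seed for the filler sequence.
#' @param accession Identifier recorded on the synthetic genome.
#' @return A `genome_sequence`.
#' @export
synthetic_genome_from_models <- function(models, proteins, length = NULL,
                                         seed = 1L,
                                         accession = "synthetic_locus") {
  if (is.null(length)) {
    length <- max(vapply(models, function(model) max(model$exons),
                         integer(1))) + 50L
  }
  base <- with_preserved_seed(seed, {
    sample(c("A", "C", "G", "T"), length, replace = TRUE)
  })
  for (nm in names(models)) {
    model <- models[[nm]]
    if (model$strand != "+") {
      abort("Synthetic locus construction supports plus-strand models.")
    }
    cds <- back_translate(proteins[[nm]])
    spliced <- sum(model$exons[, "end"] - model$exons[, "start"] + 1L)
    if (nchar(cds) != spliced) {
      abort(paste0("Protein for '", nm, "' does not fit the model: ",
                   nchar(cds), " vs ", spliced, " nt."))
    }
    offset <- 0L
    for (i in seq_len(nrow(model$exons))) {
      s <- model$exons[i, "start"]
      e <- model$exons[i, "end"]
      w <- e - s + 1L
      base[s:e] <- strsplit(substring(cds, offset + 1L, offset + w),
                            "")[[1]]
      offset <- offset + w
    }
  }
  genome_sequence(accession, paste(base, collapse = ""))
}
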