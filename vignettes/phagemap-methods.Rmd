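---
title: "Mapping the jumbo-phage nuclear shell interactome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the jumbo-phage nuclear shell interactome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemap)
```

## The biological problem

Nucleus-forming jumbo phages enclose their replicating genome in a
proteinaceous shell built primarily from one self-assembling lattice
protein, chimallin (ChmA). The pores of that lattice are too narrow for
mRNA or proteins, so the shell must contain additional components that
mediate macromolecular traffic and dock capsids for genome packaging.
`phagemap` implements the computational workflow that identifies such
components from proximity-labeling mass spectrometry: a promiscuous biotin
ligase (miniTurboID) fused to a bait protein (the shell protein ChmA, or
the nucleus-localized RecA) biotinylates its neighbors in infected cells;
biotinylated peptides are captured and quantified label-free; and phage
proteins enriched over a diffuse GFP-miniTurboID control become candidate
interactors, which are then mapped by fluorescence localization and
assembled into an evidence-typed interaction network.

## Enrichment scoring model

The quantitative core works on peptide-level peak areas from three bait
trials and three negative-control trials.

1. **Host-peptide normalization.** Host protein abundance does not depend
   on which bait was labeled, so host peptides observed in *every* run
   anchor the between-run scale. The factor for run $r$ is the median over
   shared host peptides $p$ of $a_{pr} / \tilde a_p$, where
   $\tilde a_p$ is the peptide's geometric mean area across runs
   (median-of-ratios; robust to individual outlier peptides). A
   total-sum-ratio variant is available via
   `compute_normalization_factors(method = "total_sum")`. Phage peptide
   areas are divided by their run's factor; host rows are left untouched.
   The estimator is identified only up to a global constant (factors have
   geometric mean 1 over runs when the shared set is balanced), which
   cancels in everything downstream.

2. **Per-protein aggregation.** A protein's signal in a run is the sum of
   the peak areas of the peptides assigned to it; proteins absent from a
   run get area 0. Shared peptides are counted once per listed accession —
   the input dialect carries one accession per row.

3. **Normalized peak area.** Within each run, a phage protein's normalized
   peak area is its fraction of the total phage-assigned peak area, so the
   fractions in each run sum to 1. A run with zero total is flagged as
   undefined rather than silently zeroed.

4. **Fold change.** Per protein, the arithmetic mean fraction over the
   three bait trials (zeros included) is divided by the mean over the
   three control trials. A protein never seen in controls but seen with
   the bait has fold change $+\infty$ (reported as `inf` in text output);
   a protein never seen with the bait is dropped. `times_detected` counts
   bait trials with nonzero biotinylated signal.

5. **Selection.** Candidates are proteins enriched *more than* three-fold
   (infinite passes), truncated to the top 25. Two orderings exist in
   practice: the published candidate tables are printed in descending
   normalized-peak-area order, while the text describes sorting by fold
   change. The default rank key is `mean_norm_peak_area`, which reproduces
   the printed tables; `rank_key = "fold_change"` selects the enrichment
   ordering, and it is the right key for recovery benchmarks because the
   compositional coupling described below cancels in it. Ties break by
   accession so reruns are reproducible.

### Compositional coupling

Because normalized peak areas are fractions of a per-run total, enriching
some proteins necessarily deflates the fractions of all others. If protein
$j$ has true abundance $A_j$ and bait-run enrichment $f_j$ ($f_j = 1$ for
non-interactors), the expected fold change of protein $p$ is not $f_p$ but

$$ f_p \cdot \frac{\sum_j A_j}{\sum_j f_j A_j}, $$

i.e. every fold change is multiplied by the same coupling factor
$\le 1$. `closed_form_expectation()` computes this exactly, and with all
stochastic terms disabled the pipeline reproduces it to machine precision.
Practical consequences: absolute fold changes understate true enrichment
when interactors carry a large share of the phage signal, but the
*ranking* by fold change is unaffected.

### What is deliberately absent

No p-values or FDR are computed: the workflow is a ranking-and-threshold
procedure on three-versus-three label-free data, and we do not add
significance machinery the scoring scheme does not define. Missing
intensities are not imputed; absence from controls is information (the
infinite fold changes) rather than a gap to fill.

## Biotinylated-peptide filtering

Proximity labeling marks lysines with a +226.08 Da biotin adduct.
`filter_biotinylated()` keeps peptide observations carrying at least one
modification within 0.01 Da of that mass at a lysine residue. The 0.01 Da
tolerance is generous for a value printed to two decimals yet strict
enough to exclude other common modifications (the nearest frequent
adducts are several hundredths of a Dalton away). Because capture happens
at the peptide level in this workflow, the filter is applied by default in
`run_enrichment()` but can be disabled.

## Synthetic experiments and what they do (and do not) show

`simulate_experiment()` generates peptide-level experiments with known
ground truth so the scoring stages are testable without the original raw
deposition. Per peptide and run:

$$ \text{area} = \text{baseline} \times f \times s_r \times
   e^{\sigma Z},\qquad Z \sim \mathcal N(0,1), $$

followed by zeroing with probability
$1 - \mathrm{logit}^{-1}(\beta(\log_{10}\text{area} - m))$. Defaults, chosen
once as realistic label-free conditions and then left alone:

| parameter | default | rationale |
|---|---|---|
| bait / control trials | 3 / 3 | the study layout |
| host / phage proteins | 60 / 120 | the phage encodes 378 proteins; a one-third-scale proteome keeps repeated simulations fast while preserving composition effects |
| peptides per protein | 2–5 | typical detected tryptic peptide counts for small phage proteins |
| baseline $\log_{10}$ area | $\mathcal N(6, 0.8)$ | peak areas spanning ~3 orders of magnitude, centered on ~10^6 |
| noise $\sigma$ | 0.2 | ~20% CV multiplicative error, typical of label-free peak areas |
| dropout | midpoint 4.5, slope 2 | detection falls off below ~3 × 10^4, a soft limit-of-detection |
| run scale factors | log-normal, sdlog 0.25 | ±25% run-to-run loading differences |
| biotin fraction | 0.8 | most, not all, peptides carry the adduct after enrichment |
| planted interactors | 20 at 16-fold | a strong, unambiguous enrichment signal |

Host proteins are never planted, so shared host peptides are valid
normalization anchors by construction. All randomness flows from a single
seed; identical configurations serialize byte-identically.

The generator emulates run scaling, multiplicative noise, and
abundance-dependent missingness. It does **not** emulate peptide
misassignment, shared peptides between host and phage, interference or
co-elution, saturation, or batch structure beyond a scalar per run.
Passing recovery tests therefore demonstrate that the scoring machinery is
correct and well-calibrated under a standard label-free error model — not
that the thresholds are optimal for any particular real instrument run.

Recovery under the defaults: planted 16-fold interactors are recovered in
the top 25 of the fold-change ranking with mean recall ≥ 0.9 over 50
seeds; with no planted interactors the median log2 fold change is within
±0.1 of zero; and estimated normalization factors recover the true run
scales exactly at $\sigma = 0$ and within 10% mean relative error at
$\sigma = 0.2$. These problem sizes (10–50 seeds, one-third-scale
proteome) were chosen so the full test suite runs in well under a minute
of simulation time.

## Candidate pooling, network assembly and localization

`build_candidate_set()` removes the baits from each ranked list (a bait
trivially tops its own list), truncates to the top 25, takes the union,
and flags each candidate with the lists containing it. On the two bundled
published tables this yields 42 candidates, 8 of them found by both baits.

`assemble_network()` merges duplicate bait–prey pairs into single edges
carrying the union of their evidence types (proximity labeling, GFP
pulldown, coexpression pulldown) and attaches localization categories
(nucleus, shell, bouquet, cytoplasm, unassigned) to nodes. Edges are
stored directed bait→prey but exported undirected by default, since
pulldown evidence is symmetric. Proteins that also appear in unrelated
pulldown backgrounds (highly abundant lysate proteins) are a known hazard
of this assay; the package flags rather than removes them, leaving removal
to the analyst. The bundled edge fixture encodes only the interactions
named in the main text of the study; the full pulldown edge list lives in
supplementary material that is not packaged.

## Genome re-annotation

The region between gp64 and gp68 of the phage genome is misannotated in
RefSeq; the corrected models are gp65–66 — one protein whose CDS is
interrupted by a 450-nt intron (nucleotides 55005–55454) — and gp67.
`gene_model()` uses 1-based inclusive forward-strand coordinates (the NCBI
convention); extraction concatenates exon substrings in order and
reverse-complements for minus-strand models; translation uses NCBI genetic
code 11, renders the terminal stop as a trailing `*` (the published
reference sequences include it, and comparisons are performed on the full
string), errors on internal stops with their codon position, translates
ambiguous codons to `X` with a warning, and warns (not errors) on non-ATG
initiators, since phages use alternative starts. Alternative internal
starts (the lattice protein has a known secondary initiator at codon 33)
are out of scope: translation always begins at exon 1, position 1.

The genome itself is not bundled. The published re-annotated protein
sequences are, and `synthetic_genome_from_models()` builds a synthetic
locus that carries their deterministic back-translation at the published
exon coordinates, with seeded random filler elsewhere (including the
intron). Running extraction and translation over that locus and comparing
against the bundled published sequences is a dual-route check —
back-translation on one side, spliced extraction plus translation on the
other — that exercises coordinate arithmetic, intron removal, frame
checks and stop handling end to end. The filler sequence itself is
meaningless and labelled synthetic; given a real genome FASTA,
`read_genome_fasta()` plugs into the same functions unchanged.

## Conservation statistics and molecular weight

No alignment method is stated for the published homolog-conservation
averages (51% mean pairwise identity for the shell lattice protein family
versus 27% for the shell pore protein family across five
*Pseudomonas*-infecting jumbo phages), so the module fixes one and states
it: Needleman–Wunsch global alignment, BLOSUM62, gap open 10 / extend 0.5,
identity denominator = full alignment length (gap columns counted), mean
over all unordered pairs. A `shorter_sequence` denominator is available;
agreement with the published averages should be read as approximate
(method-dependent to a few percentage points). The homolog sequences are
fetched by accession by the user and are not redistributed; the alignment
engine itself is verified against an independently coded affine-gap
dynamic-programming oracle on short sequences, bracketing identity between
the minimum and maximum over co-optimal alignments.

`molecular_weight()` sums average (default) or monoisotopic residue masses
plus one water. Average masses are the appropriate scale for comparison
with solution measurements such as SEC–MALS (the shell pore protein's
measured monomer mass is 22.5 kDa); the function errors on non-standard
residues and ignores a trailing `*`.

## Numerical choices and degenerate inputs

* Fold-change threshold is exclusive (`> 3`), matching "enriched more than
  three-fold"; exactly 3.0 is excluded.
* Ties under any rank key break by accession lexicographic order.
* Normalization requires at least one host peptide (sequence plus
  modification set) with positive area in every run; otherwise the error
  suggests relaxing the peptide filter or adding a spike-in rather than
  guessing.
* Per-run fraction sums are conserved to 1 within 1e-12; the whole
  pipeline is checked field-by-field against a hand-coded spreadsheet
  oracle on a small fixture.
* Peptide tables validate row-by-row (non-negative areas, host/phage
  organism, modification positions within the peptide) and report
  offending row numbers.
* `peak_area` round-trips through the text format at full double
  precision.

## Known limitations

* The original study's printed per-protein values cannot be regenerated
  from first principles without the raw deposition and the original
  peptide-identification software; the bundled tables are treated as
  inputs (for pooling and overlap), not as targets the pipeline re-derives.
* The normalization formula behind the published tables is unstated;
  median-of-ratios is this package's choice, with a total-sum variant for
  sensitivity analysis.
* Enrichment scoring is deterministic ranking, not inference; with other
  data shapes (more replicates, missing-not-at-random structure) a
  model-based tool would be more appropriate.
* The alignment-parameter choice bounds, but does not remove, the
  method-dependence of percent-identity averages.
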