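---
title: "Community translation profiling: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community translation profiling: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaribo)
```

## The problem

Ribosome profiling (Ribo-Seq) sequences the ~30 nt mRNA fragments protected
by translating ribosomes. Applied to a mixed microbial community
(MetaRibo-Seq-style experiments on fecal or other microbiome samples), it
gives a direct readout of protein synthesis for hundreds of organisms at
once — something neither metagenomics (gene presence) nor
metatranscriptomics (RNA abundance) can provide. Two analyses make this
readout valuable:

* **Small-ORF (smORF) discovery.** Genes encoding proteins of ~5–50 amino
  acids are systematically missed by annotation pipelines and by
  proteomics. Footprint coverage over a predicted smORF is direct evidence
  that it is translated.
* **Translational regulation.** Comparing footprint abundance with RNA
  abundance across conditions, through a condition-by-assay interaction
  term, finds genes whose *translation* changes beyond what their
  transcription explains.

`metaribo` implements the full desk-scale workflow — simulation, gene
prediction, mapping, signal diagnostics, quantification, protein-family
analysis, differential testing, and taxonomy propagation — as
data-frame-first R functions, so every stage can be validated against
planted ground truth.

## The synthetic community generator

Real benchmark data for this workflow requires deep sequencing of fecal
samples. The package instead ships a generator whose output has the
statistical structure the downstream analyses assume, with complete ground
truth:

* **Genomes and genes.** `simulate_community()` builds random contigs for
  each taxon and plants non-overlapping genes on random strands: regular
  genes (80–200 aa), smORFs (5–50 aa), untranslated decoy ORFs, and
  optionally protein families. Each planted gene starts with ATG, ends
  with a stop codon, and carries an in-frame stop immediately upstream of
  its start, so a maximal-ORF six-frame scan recovers exactly the planted
  coordinates. A 100 bp gene-free margin at contig ends keeps reads and
  metagene flanks inside the contig.
* **Planted families.** Member 1 is the unmutated ancestor; other members
  substitute residues at a single per-family set of "variable sites"
  (`round(divergence * length)` positions, never the initiator). With
  shared sites, *any* member-to-member identity is approximately
  `1 - divergence`, mirroring a family with hypervariable positions and
  making cluster recovery independent of processing order. At 30%
  divergence members share ~70% identity (above the 50% clustering
  cutoff); at 60% they share ~40% and the family fragments — the behaviour
  expected of rapidly evolving families that escape identity clustering.
* **Abundances.** Transcription levels are lognormal (mu 0, sigma 1 by
  default); translational efficiency (TE, footprint density per
  transcript) is an independent lognormal (sigma 0.75). Decoys have TE
  exactly 0: transcribed, never translated. Regulated genes receive
  planted log2 shifts between two conditions: `transcriptional` genes
  shift RNA and footprints together, `translational` genes shift
  footprints only, `both` shift each independently.
* **Reads.** All reads are exact substrings (or reverse complements) of
  their contig, with fixed length and constant quality — error-free by
  design, because the mapping filter keeps only perfect alignments and
  sequencing errors would only delete reads while breaking exact truth
  accounting. Metagenomic reads are uniform over both strands; RNA 5'
  ends are uniform over gene spans on the coding strand at a rate
  proportional to transcription; footprint 5' ends are drawn per gene at
  a rate proportional to transcription × TE, with within-gene positions
  mixing frame-weighted body density, a start-window peak and a
  stop-window peak.
* **Signal model defaults.** The start-codon peak (×10 over body density,
  12 nt window), stop peak (×5, 12 nt), and frame weights (0.6/0.2/0.2)
  are calibration choices: published figures show pronounced start/stop
  signal and weak codon resolution without quantifying them. Windows are
  whole codons so the peaks do not distort the overall frame mix. The
  off-ORF background rate defaults to 1e-7 per bp per strand (on the
  scale of unit mean gene mass), making background a <0.1% contamination
  fraction — consistent with footprints being ribosome-protected
  fragments rather than random RNA.
* **Replicate counts.** For differential testing,
  `simulate_counts()` draws counts directly: expected counts proportional
  to the per-condition rates scaled to a mean depth per gene, multiplied
  by per-gene lognormal replicate noise (sigma 0.25, i.e. negative
  binomial dispersion ≈ 0.065 — a typical value for good laboratory
  replicates), then Poisson. Dispersion therefore arises across
  replicates, with interpretable planted truth.

What the generator does **not** emulate: sequencing errors and quality
variation, indels, footprint-length heterogeneity, rRNA/tRNA/structured-RNA
contamination, uneven coverage from GC or fragmentation bias, strain-level
variation within a taxon, and partial genes at contig edges. Tests passing
on simulated data therefore validate the *computational* contracts — exact
recovery, calibration, power under the stated model — not robustness to
those artefacts.

## Gene prediction conventions

`find_orfs()` is a transparent six-frame scan replacing a trained gene
caller: for each in-frame stop codon it reports the ORF from the outermost
upstream in-frame start codon (ATG/GTG/TTG) with no intervening stop.
Without a start-scoring model, the maximal-ORF convention is the only
reproducible choice, and the simulator plants unambiguous genes. ORFs
shorter than 15 bp (stop included) are dropped. The protein length counts
the initiator methionine and excludes the stop codon; the 5–50 aa smORF
window applies to that count (a stop codon is not an amino acid). Both
bounds are configurable should a different reading be wanted. Non-ATG
initiators are translated as methionine. Partial ORFs at contig edges are
not reported.

## Mapping and the perfect-unique filter

Because downstream analyses only use perfect, uniquely-placed reads
(avoiding conservation conflicts between related genomes in a community),
exact matching *is* the full mapping semantics. `map_reads()` seeds on the
first k-mer (default k = 21) of the read and of its reverse complement,
verifies the full read against the contig, and reports every 0-mismatch
location; `filter_unique_perfect()` keeps reads with exactly one such
location. Multi-mapping is decided at whole-read granularity: any second
perfect location disqualifies the read. Reads shorter than the seed are
dropped with a message. SAM import requires the `NM` tag and derives hit
multiplicity from equal-best records per read.

## Footprint diagnostics

All positional analyses use the footprint 5' end (leftmost base on `+`,
rightmost on `-`) with no P-site offset: the workflow validates raw
signal, and P-site calibration would introduce a parameter the analysis
does not need. `metagene_profile()` averages per-gene-normalized 5'-end
windows over genes with at least 10 in-ORF reads; normalization makes the
average invariant to any single gene's coverage scale. The flank width
defaults to 50 nt. `frame_periodicity()` classifies in-ORF 5' ends by
offset-from-start modulo 3 and tests uniformity with a Pearson chi-square
(2 df); zero signal returns counts (0,0,0), undefined fractions and p = 1.
`start_enrichment()` is the mean profile over offsets [0, 12) divided by
the mean over the remaining downstream window; a flat profile gives 1 and
a zero body returns `Inf` with a warning.

## Quantification

Counting is by 5'-end containment: a read is assigned to a feature when
its 5' end lies inside the feature span, with the read strand required to
match the feature strand for RNA and footprint assays (metagenomic
counting is unstranded). Containment (rather than any-overlap) is
consistent with the signal-track convention and never double-counts a read
at feature boundaries; a 5' end inside two same-strand overlapping
features counts for both. RPKM uses the retained (unique-perfect)
alignment count of the sample as the library size. The
translation-evidence call is strict: footprint RPKM must exceed 10.
Translational efficiency is footprint RPKM over RNA RPKM from the same
sample — the ratio convention is ours, since no formula is standard — and
is `NA` when the denominator is zero; replicates are pooled before
evidence calls by default. Scatter correlations are computed on
log10(RPKM + pseudocount) with the pseudocount set to half the smallest
positive value, stated here because no convention exists. Zou's 95%
interval for the difference of two overlapping dependent correlations is
implemented from the Fisher-z component intervals and the analytic
correlation between the two estimates.

## Protein families

`pairwise_align()` has two modes sharing BLOSUM62 with gap open 11 /
extend 1. `"local"` (Smith–Waterman) is the homology-search mode; bit
scores and e-values use Karlin–Altschul statistics (lambda 0.267,
K 0.041 — the standard gapped BLOSUM62 values) with search space
`len(query) × len(subject) × n_subjects`. A homolog hit is significant
when e ≤ 0.05 and the alignment length is 90–110% of the query protein
length; "length of the hit" is read as alignment columns (a switch allows
subject length instead). `"global"` (Needleman–Wunsch) is the clustering
mode: greedy clustering requires the alignment to span ≥ 95% of the longer
sequence, and a local alignment of two genuinely full-length homologs at
~30% divergence frequently trims mismatching termini below that bound, so
full-length semantics are the correct reading of CD-Hit-style clustering.
Identity in both modes is identical residues over alignment columns
(internal gaps included, end gaps excluded).

`greedy_cluster()` follows the CD-Hit recipe: length-descending order
(ties by id, making the run deterministic and order-independent), first
sequence founds a cluster, each next sequence joins the best qualifying
representative (highest identity ≥ 0.5, length ratio ≥ 0.95, long-sequence
coverage ≥ 0.95) or founds a new cluster. A family is flagged
`synthesized` when at least one linked smORF is called translated — the
flag is monotone in evidence. Domain enrichment between confidence tiers
is an upper-tail hypergeometric test. Comparative-genomics support and
secreted/transmembrane flags are input tables (external tools compute
them); localization is called at ≥ 80% of members, inclusive.

## Differential testing

Counts are normalized by median-of-ratios size factors (geometric-mean
reference over genes with no zero count, factors rescaled to geometric
mean 1). Each gene is fitted with a negative-binomial GLM (log link,
size-factor offsets) and tested by a likelihood-ratio chi-square:

* `rna` / `ribo` contrasts: `~ samplegroup` vs `~ 1` on that assay's
  columns;
* `interaction`: `~ samplegroup * type` vs `~ samplegroup + type` on all
  columns — the interaction coefficient is the footprint change not
  explained by the RNA change, i.e. translational regulation controlling
  for transcription.

Dispersion is **not** the raw per-gene method-of-moments value: with 2–3
replicates per cell that estimator is so noisy that plugging it into the
likelihood inflates the type-I error to ~10% at nominal 5%. Instead the
per-gene within-cell variances are pooled through a variance–mean trend
`Var = c1·mu + c2·mu²` (c1 ≥ 1, c2 ≥ 0), fitted by weighted least squares
with weights 1/Var² and iterated; the fitted trend value is the plug-in
dispersion. This recovers nominal calibration (measured 4–6.5% across
simulation seeds) and, unlike an unweighted regression of per-gene
dispersion on 1/mu, remains identified when gene means are nearly
constant. The cost is that genuine gene-specific dispersion outliers are
moderated toward the trend — a deliberate trade, documented here, that
diverges from shrinkage-based machinery in established differential
packages. P-values are Benjamini–Hochberg adjusted (the standard choice
where only "FDR" is stated); non-converged genes get `NA` and leave the
adjustment denominator; all-zero genes are removed first. A gene is
called differential only when |log2FC| is strictly above 1 **and** FDR is
strictly below 0.05. With two-replicate designs the test runs but power
is low; simulator defaults use three replicates.

## Taxonomy and genomic context

Reads take the taxon of the gene containing their 5' end (strand rules as
in counting) — classifying reads through gene classifications keeps short
footprint and RNA fragments comparable with long metagenomic reads. Reads
in no gene, or in genes without a taxon label, are unclassified; when a 5'
end falls in two same-strand overlapping genes the gene with the closer
start codon wins and the ambiguity is tallied. Abundances are fractions of
classified reads; taxa strictly below 3% are grouped into "Other".
Neighborhood scans count distance in gene ranks (start-coordinate order,
strand-independent), keep neighbors within 10 ranks, and filter domain
rows at e ≤ 0.05 and PSSM coverage ≥ 80%.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere except BED export
  (0-based half-open); minus-strand ORFs store `start < end`.
* Ambiguous bases are rejected with position information, not skipped:
  the simulator never emits them and perfect-match semantics would be
  undefined.
* Dispersion floor 1e-8; fitted means floored at 1e-10 inside the NB
  log-likelihood; frame fractions are `NA` (not 0/0) at zero signal;
  `translation_efficiency` returns `NA` on zero RNA; `start_enrichment`
  returns `Inf` with a warning on a zero body.
* Clustering ties (equal identity to two representatives) resolve to the
  earlier-founded cluster; representative ties resolve lexicographically.
* All simulation stages accept a seed and restore the caller's RNG state;
  pipeline stage seeds are small fixed offsets from the master seed, so a
  rerun is byte-identical.

## Problem sizes

The bundled experiments are sized for a laptop: demo pipeline with 3 taxa
× 20 kb, ~70 planted genes and 65k reads (~1 minute); signal-shape
validation at 50k footprint reads; translation-evidence validation with
100 smORFs + 100 decoys at 200k reads; clustering recovery with 25
planted family members; differential calibration and power at 2000 genes
× 6–12 columns. These sizes give the checked properties comfortable
statistical margins (e.g. frame-fraction standard error ~0.002 at 50k
reads) while the entire validation suite completes in a few minutes.

## Limitations

Beyond the generator simplifications listed above: the exact-match mapper
is not a general aligner (no mismatches or indels, by design); Prodigal's
start-site scoring and RBS models are not reproduced, so on real contigs
start calls will differ from trained callers; e-values use analytic
Karlin–Altschul statistics rather than empirical BLAST calibration;
greedy clustering is quadratic in the number of query sequences and meant
for hundreds, not hundreds of thousands, of proteins; and the NB test's
trend-moderated dispersion will be conservative for genes with genuinely
outlying dispersion.
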