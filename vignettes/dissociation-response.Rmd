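---
title: "Measuring and removing transcriptional dissociation response with dissoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and removing transcriptional dissociation response with dissoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissoscan)
```

## The problem and the measurement model

Preparing a single-cell suspension stresses cells: dissociation induces a
transcriptional program (immediate-early genes such as *fos*/*jun*, heat
shock factors, and related stress genes) that contaminates both bulk and
single-cell RNA-seq and can masquerade as biology — for example as a
spurious "activated" subpopulation in clustering. Adding 4-thiouridine
(4sU) to the dissociation buffer marks exactly the RNA synthesised during
sample preparation: after iodoacetamide alkylation, incorporated 4sU
reverse-transcribes as cytosine, so nascent molecules carry T-to-C
substitutions relative to the reference. `dissoscan` implements the
computational half of this assay.

The statistical object is simple. For a read base aligned to a
transcript-strand T position (reference `T` on a plus-strand gene,
reference `A` on a minus-strand gene, because the tag libraries are
sense-stranded), let the observed conversion indicator be Bernoulli. In a
sample where a fraction *f* of molecules are nascent and each T of a
nascent molecule converts independently with probability *p*, a T base
call converts with probability

  r = f·p + (1 − f·p)·e/3,

where *e* is the per-base sequencing error rate, spread uniformly over the
three alternative bases. A per-gene *labeling rate* estimates r from the
gene's T positions; genes transcribed during dissociation stand out
because their *f* is high.

## Event calling and filtering

Mismatches are reconstructed per read by walking the CIGAR and MD tag
jointly (insertions/soft-clips advance the read cursor only, deletions and
skips the reference cursor only), without touching the genome FASTA. Three
filters follow:

* **Base quality** — only calls with Phred quality ≥ 20 (99% accuracy)
  count, for conversions and for coverage alike (`min_quality`).
* **SNP blacklist** — positions where *more than* 25% of quality-passing
  calls deviate from the reference are treated as SNPs, and positions with
  coverage *below* 10 as unjudgeable (`max_alt_frac`, `min_coverage`).
  Both rules are deliberately strict inequalities: 3 alternative calls out
  of 12 (exactly 25%) survive, coverage 10 survives. The pileup applies
  the same Q20 filter as conversion calling so the blacklist judges the
  same evidence the rate uses. A `tc_only` switch restricts the fraction
  rule to conversion-like alternatives (C at T positions, G at A
  positions), the strand-naive reading of removing frequent T-to-C sites;
  the default considers all three alternatives, which also catches
  non-conversion SNPs that would distort coverage.
* **Strand** — conversions are resolved to the transcript strand by
  default (genomic A>G on a minus-strand gene is a conversion), with
  `genomic_only = TRUE` reproducing a strand-naive count. Reads aligned
  antisense to their gene are discarded by default; their conversions are
  uninterpretable under sense-stranded chemistry. Which convention the
  original analysis used is not documented; both are provided, and the
  strand-aware default roughly doubles sensitivity on minus-strand genes.

## Per-gene rates and gene selection (bulk)

Two estimators of the labeling rate are exposed:

* `observation` (default): converted T base calls / all T base calls.
  Coverage-weighted, the standard nucleotide-conversion estimator, and the
  one with the clean closed form above.
* `site`: T positions with ≥ 1 conversion / covered T positions. This is
  the literal "fraction of non-blacklisted T positions" reading; it
  saturates with coverage (each extra read can only confirm a site) and is
  kept for fidelity and for the removed-read report.

Genes with zero denominator are reported with a *missing* rate and
excluded from summary statistics — reporting them as 0 would drag the mean
down and misstate absence of evidence. Reads overlapping more than one
gene are excluded from all of them.

Selection uses the mean and standard deviation (n − 1 sample estimator, a
convention fixed once for reproducibility) over all non-missing gene rates
of a sample: genes with rate strictly greater than mean + k·SD are
selected, k = 5 for response-gene calling, k = 1 for the noise filter
applied to the PCA input matrix. Strict ">" is used everywhere a
threshold is compared, resolving the inconsistent "over"/"≥" usage across
descriptions of the method one way, stated here once. With all rates
identical the SD is 0 and nothing exceeds the mean, so the selection is
empty rather than arbitrary. Cross-sample tools classify genes by
membership of two samples' selections (`compare_samples`), intersect
selections across replicates (`consensus_genes`, by default requiring
membership in ≥ 3 samples), and assemble the genes × samples rate matrix
for external PCA (`pca_input_matrix` — the PCA itself is out of scope).

## Single-cell molecule removal

Reads carrying CellRanger-style CB/UB/GX tags are grouped into molecules
(UMIs). A molecule's conversion events are the *union of distinct
converted positions* across its supporting reads: a UMI denotes one
molecule, so conversions are molecular properties; requiring them in a
single read (`mode = "any_read"`, provided since the original code is not
explicit) only discards evidence. A molecule is *labeled* when it carries
≥ 2 distinct conversion events (`sc_min_conversions`) — one event is too
easily an isolated error, two independent quality-passing conversions on
one molecule are strong evidence it was synthesised during labeling.

`regenerate_count_matrix()` counts every molecule into the raw genes ×
cells matrix and omits only labeled molecules from the corrected one; no
gene is ever dropped wholesale, and raw = corrected + removed holds
entry-wise. By default no SNP blacklist is applied in single-cell mode,
matching the described filtering, which names only the quality rule
(`use_blacklist` enables it). Reports follow the published filters: the
per-cell percentage of detected genes with a labeled molecule; the
per-cell-type gene summary requiring ≥ 250 units with ≥ 10% labeled in at
least one cell type (unit = UMI by default; the source material uses
"reads" and "UMIs" interchangeably here, so `unit = "read"` weights each
molecule by its read support); and the removal report listing genes with
≥ 3 removed reads making up ≥ 5% of the gene's reads, with the labeling
rate of the removed reads computed by the site-mode formula restricted to
those reads. `gradual_removal()` removes seeded, nested random subsets of
the labeled molecules (round-half-up of f·n), so partial-correction series
are monotone and reproducible.

## The simulator: what it emulates, and what it does not

`simulate_bulk()` / `simulate_sc()` generate a reference (one random
contig per single-exon gene, uniform base composition, an exact
`strand_mix` split of minus-strand genes), GTF annotation, tagged SAM
alignments and ground-truth tables. The chemistry model: a read (bulk) or
molecule (single-cell) is labeled with probability `labeled_fraction`
(optionally multiplied per gene by `spiked_genes`); each transcript-strand
T of a labeled unit converts independently with `conversion_prob`;
sequencing errors hit each base with `error_rate`, uniformly over the
three alternatives, so every one of the 12 substitution types has
background rate e/3; planted SNPs emit their alternative base with the
configured allele fraction; base qualities are a two-point Q37/Q12 mixture
(10% low by default) so the Q20 filter actually removes something. In
single-cell mode all reads of a UMI share the molecule's start, labeled
flag and planted conversions, while errors and qualities are per-read.

Three numerical choices keep the truth tables exactly reconcilable with
the emitted alignments: errors are overlaid only on bases that still match
the reference (so planted conversions and SNP draws are never silently
reverted and every recorded event is visible as a mismatch); conversions
are only planted at positions whose reference and current base are the
transcript-strand T (so SNP and conversion identities never mix); and MD
tags are computed from the final sequences. Planted conversions carry high
quality by default; `conversion_quality = "mixture"` draws them from the
same quality mixture as every other base. The default is the right model
for detection questions (a conversion is a real molecular feature, and
removal sensitivity should not be an artifact of simulated quality); the
mixture mode is the right model for estimator calibration, because a
quality filter that retains all conversions but drops 10% of other T
observations inflates the observation-mode rate by about one standard
error relative to the closed form above. The calibration checks in this
package therefore use the mixture mode, and the detection checks the
default.

What the simulator does *not* emulate: splicing and multi-exon structure
(one gene per contig, by design — coordinate and strand logic are
exercised without alignment ambiguity), fragment-length and GC biases, PCR
duplication beyond identical-start UMI reads, barcode sequencing errors,
ambient RNA, and cell-type structure beyond the explicit activation
scenario. Passing tests therefore demonstrate correctness of the
*computational* pipeline under the stated chemistry model, not robustness
to every artifact of real libraries.

The activation scenario (`simulate_activation_scenario()`) models the
cluster-artifact phenomenon at desk scale: two populations share an
identical baseline transcriptome; "activated" cells additionally carry
labeled molecules on a stress gene set (3 per gene per cell by default).
Stress molecules are simulated as fully nascent with `conversion_prob`
0.2 per T, so with ~22 Ts per 90 nt read almost all of them carry ≥ 2
conversions and are removable — the scenario asks whether correction
collapses the artifactual difference, which requires the artifact to be
made of detectable molecules. The check compares the between-population
centroid distance on the stress genes before and after correction.

## Problem sizes and tolerances used in the checks

The test suite and `scripts/acceptance.R` size their simulations so every
property is measured with comfortable statistical margin: 500 genes × 200
reads for rate calibration (each gene ~4,000 T observations; ≥ 95% of
genes within 3 binomial SE of the closed form); 50 heterozygous SNPs at
~100× coverage for blacklist recall (at 20× a 50% SNP has a ~2% chance of
a sub-25% draw, which would make "100% blacklisted" a coin flip rather
than a property of the rule); 1,000 genes with 1% spiked for 5-SD
selection and 2,000 genes with 1% spiked for the five-sample consensus —
spike density matters, because spiked genes inflate the mean + 5·SD
threshold themselves; at 10% density the threshold overtakes the spikes
and selection collapses, which is a real property of SD-based selection
worth knowing when interpreting it on small gene universes. Single-cell
checks use 500 cells × 20 UMIs × 2 reads. Removal accuracy is scored
against molecules carrying ≥ 2 *planted* conversions: at `conversion_prob`
0.04 only ~22% of chemically labeled 90 nt molecules ever carry two
convertible positions, so the pipeline is scored on recovering the planted
events — the quantity it can actually observe — with sequencing error and
quality filtering as the confounders.

## Known limitations

* Overlapping mate pairs would be double-counted; the intended inputs are
  single-end tag libraries, and deduplication is a documented pre-step.
* The blacklist cannot distinguish a homozygous SNP from a position that
  is nearly always converted; at realistic conversion rates (≪ 25%) this
  does not occur, but fully labeled spike-in material would be masked.
* MD tags are consumed, not computed; inputs lacking them need a
  `samtools calmd` pre-step (reads without MD are skipped and counted, or
  rejected in strict mode, and a run aborts when more than a configurable
  fraction is missing).
* Gene assignment uses gene extents from the GTF; reads in overlapping
  gene territory are discarded rather than disambiguated.
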