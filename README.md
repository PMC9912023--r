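# dissoscan

Tissue dissociation makes cells transcribe a stress program (*fos*/*jun*,
heat-shock genes, …) while the sample is being prepared, and that program
contaminates bulk and single-cell RNA-seq — sometimes as an entire
spurious "activated" cluster. When 4-thiouridine (4sU) is present in the
dissociation buffer, RNA synthesised during preparation picks up the
label, and after iodoacetamide treatment those molecules show T→C
substitutions against the reference. `dissoscan` is the computational half
of that assay, for anyone running SLAM-seq-style labeling during
dissociation:

* **Conversion calling** — reconstructs mismatches from CIGAR + MD tags,
  keeps calls with base quality ≥ Q20, and resolves T→C to the transcript
  strand (genomic A→G on minus-strand genes).
* **SNP blacklisting** — builds a quality-aware pileup and excludes
  positions with non-reference fraction > 25% or coverage < 10.
* **Bulk response detection** — per-gene labeling rate
  `r = converted T observations / T observations` (or the site-level
  variant), selection of genes with `r > mean + 5·SD`, two-sample
  comparison, cross-replicate consensus (≥ 3 of n samples), and the
  genes × samples rate matrix for external PCA.
* **Single-cell correction** — groups CB/UB/GX-tagged reads into
  molecules, flags UMIs with ≥ 2 distinct conversion events as labeled,
  and regenerates corrected count matrices (10x-style MatrixMarket
  layout) with `raw = corrected + removed` guaranteed entry-wise, plus
  per-cell, per-cell-type and removal reports and a gradual-removal mode.
* **Ground-truth simulator** — emits reference FASTA, GTF, tagged SAM and
  truth tables for every planted conversion, error and SNP, so the whole
  pipeline is testable end to end without external data.

Under the hood the model is binomial: with nascent fraction *f*,
per-T conversion probability *p* and uniform error rate *e*, a T base
call converts with probability `f·p + (1 − f·p)·e/3`; labeled genes stand
out through their high *f*.

## Worked example

Simulate a bulk experiment with 100 genes at a low baseline labeling level
and two genes transcribed heavily during dissociation, then run the
detection chain:

```r
library(dissoscan)

cfg <- sim_config(seed = 42, n_genes = 100, reads_per_gene = 120,
                  labeled_fraction = 0.1, conversion_prob = 0.04,
                  spiked_genes = data.frame(
                    gene_id = c("gene0007", "gene0031"), multiplier = 8))
sim    <- simulate_bulk(cfg)
pileup <- build_pileup(sim$reads, sim$reference, min_quality = 20)
bl     <- build_blacklist(pileup)            # >25% alt or coverage <10
stats  <- gene_labeling_stats(sim$reads, sim$reference, sim$genes,
                              blacklist = bl, sample_id = "demo")
select_labeled_genes(stats, k = 5)
#> <labeled_gene_set> sample=demo  2/100 genes above mean+5*SD (thr 0.02707)

head(stats[order(-rate)], 4)
#>     gene_id t_observations converted_observations t_sites converted_sites read_count        rate
#> 1: gene0007           2765                     97      77              51        120 0.035081374
#> 2: gene0031           2393                     76      69              51        120 0.031759298
#> 3: gene0011           2713                     24      77              24        120 0.008846296
#> 4: gene0086           2070                     17      61              14        120 0.008212560
```

Both planted response genes are recovered: their labeling rates (~3.2–3.5%
of T observations converted) sit far above the background (~0.5–0.9%,
baseline labeling plus sequencing error), and the 5-SD threshold (0.027)
separates them cleanly. The substitution spectrum shows the labeling
channel on both strands, two orders of magnitude above the error floor:

```r
spec <- substitution_spectrum(sim$reads, sim$reference, blacklist = bl,
                              pileup = pileup)
spec[order(-rate)][1:3]
#>    ref alt events observations         rate
#> 1:   A   G    720       243135 0.0029613178
#> 2:   T   C    671       237051 0.0028306145
#> 3:   G   A     92       238856 0.0003851693
```

For single-cell data, `run_sc()` (or `group_umis()` +
`regenerate_count_matrix()`) writes raw and corrected matrix triplets that
drop into Seurat/Scanpy-style workflows; `run_bulk()` is the one-call bulk
equivalent. A thin CLI covering simulation and both pipelines is installed
as `exec/dissoscan` (subcommands `simulate`, `run-bulk`, `run-sc`).

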