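# satquant

Quantification of pericentromeric satellite (HSAT2, HSAT3, alpha
satellite) and retroelement (LINE, SINE, LTR/ERV) transcripts from
stranded, aligned RNA-seq — the computational core of repeat-RNA cargo
analysis in tumours and extracellular vesicles (EVs), where
ETS-fusion-driven cancers transcribe GGAA-rich pericentromeric
heterochromatin and export the resulting pathogen-like RNAs.

It is written for bioinformaticians who have aligned reads (SAM/BAM), a
RepeatMasker-style annotation, and optionally contigs assembled from
unmapped ChIP-seq reads, and who need reproducible repeat-class
composition statistics rather than gene-level expression.

## What it computes

* **HSAT3 locus calling** — simple GAATG/CATTC repeat runs, merged and
  filtered: length > 1 kb, unit purity ≥ 0.8, overlapping a
  pericentromeric window. HSAT2 and other families come from the
  supplied annotation.
* **Hierarchical annotation resolution** — per-base ownership with the
  priority miRNA > piRNA > lncRNA/lincRNA > RepeatMasker repeats, so
  every read is counted once.
* **Read filtering and RPM** — drop rRNA/tRNA-overlapping reads,
  secondary alignments, and MAPQ < 30; assign each fragment by maximal
  overlap; report reads per million filtered mapped reads
  (RPM = 10⁶ · count / total) per category, and the **repeat/mRNA
  ratio** Σ RPM(SINE, LINE, DNA, LTR/ERV, low-complexity, simple,
  satellite) / RPM(protein-coding).
* **Per-locus satellite matrices** (log₁₀ RPM, `NA` = no reads) and
  **sense/antisense strand summaries**.
* **Pathogen-likeness statistics** — AU skew (A−U)/(A+U), GC skew
  (G−C)/(G+C), and CpG/UpA observed/expected usage
  (o/e = [n_XY/(L−1)] / [(n_X/L)(n_Y/L)]).
* **ChIP contig analysis** — 200–700 nt length filter, ungapped
  alignment against 24-mer satellite motifs (identity ≥ 95% = at most
  one mismatch per 24-mer), locus assignment, ChIP-vs-input Wilcoxon
  rank-sum enrichment, recurring k-mer motifs (k = 9), and peak–repeat
  overlap counts (peak score > 5).
* **Exact rank statistics** — enumerated Wilcoxon rank-sum and
  signed-rank tests for small samples, normal approximation with tie
  and continuity corrections otherwise, and Benjamini–Hochberg
  adjustment.
* **Synthetic data** — genomes with planted satellite arrays and gene
  models, stranded aligned reads with configurable category mixtures
  (e.g. EV-like repeat/mRNA ratio 1.7 vs cell-like 0.5), and ChIP
  contigs, all with truth labels.

## Worked example

Simulate an EV-like sample on the example genome and quantify it:

```r
library(satquant)

sim  <- simulate_genome(example_genome_config(seed = 1))
loci <- call_hsat3_loci(sim$genome, sim$pericentromere)
loci
#> GRanges object with 2 ranges and 4 metadata columns:
#>       seqnames      ranges strand |      family       class      tier    purity
#>   [1]     chr1 85001-90000      * |       HSAT3   satellite         3  0.897000
#>   [2]     chr2 65001-66995      * |       HSAT3   satellite         3  0.864662
```

The two called loci are exactly the planted GAATG arrays: 5 kb at 2%
divergence on chr1 and 2 kb at 3% divergence on chr2; `purity` is the
fraction of bases inside exact GAATG/CATTC unit matches.

```r
res   <- resolve_annotations(list(sim$annotation, loci))
cfg   <- read_sim_config(200000, read_mix_target(1.7),
                         rrna_fraction = 0.02, seed = 101)
reads <- simulate_reads(sim, cfg)
kept  <- filter_reads(reads, res)
attr(kept, "filter_report")[c("removed_rrna_trna", "removed_secondary",
                              "removed_low_mapq", "retained")]
#> $removed_rrna_trna  4028
#> $removed_secondary  3978
#> $removed_low_mapq   19148
#> $retained           172846

tab <- abundance_table(assign_reads(kept, res))
tab
#>          category count    rpm
#> 1  protein_coding 57835 334604
#> 2       noncoding  6934  40117
#> 3            SINE 15562  90034
#> 4            LINE 15479  89554
#> 5             DNA  2986  17275
#> 6         LTR/ERV  8811  50976
#> 7  low_complexity 13889  80355
#> 8          simple 19370 112065
#> 9       satellite 21649 125250
#> 10     intergenic 10331  59770

repeat_mrna_ratio(tab)
#> [1] 1.69
```

The RPM column sums to 10⁶, and the repeat/mRNA ratio recovers the
configured EV-like target of 1.7 to within sampling error. Satellite
reads were simulated with a 0.5 sense fraction (double-stranded EV
cargo), which the strand summary recovers per locus:

```r
strand_ratio(kept, res[res$class == "satellite"])
#>   locus sense antisense sense_fraction
#> 1     1  3273      3240      0.5025334
#> 2     2  2309      2420      0.4882639
#> ...
```

## Documentation

The methods vignette
(`vignettes/satellite-repeat-quantification.Rmd`) describes the models,
parameter defaults and their rationale, the synthetic-data generator's
scope, and known limitations.
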