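---
title: "Quantifying satellite and repeat transcripts from stranded RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying satellite and repeat transcripts from stranded RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satquant)
```

## Background

Pericentromeric satellite repeats — HSAT2, built from tandem 23–26 bp
consensus motifs, and HSAT3, built from highly divergent GAATG/CATTC
(equivalently GGAAT/ATTCC) simple repeats — are normally silenced
heterochromatin. In cancers driven by ETS-family transcription factors
(EWS:FLI1 in Ewing sarcoma, ERG in prostate cancer), whose DNA-binding
domains target GGAA-rich sequence, these arrays can be transcribed;
the resulting satellite RNAs, together with LINE, SINE and LTR/ERV
retroelement transcripts, are packaged into extracellular vesicles (EVs)
and display pathogen-like sequence composition. satquant implements the
computational core of this analysis as a reusable, fully testable
pipeline:

1. **Annotation** — de novo HSAT3 locus calling from genome sequence,
   hierarchical resolution of overlapping features, and mapping of
   feature classes to reporting categories.
2. **Quantification** — read filtering, feature assignment, per-category
   RPM, the repeat/mRNA ratio, per-locus satellite expression matrices
   and sense/antisense summaries.
3. **Sequence statistics** — AU/GC skew and CpG/UpA dinucleotide
   observed/expected usage.
4. **ChIP contig motifs** — matching contigs assembled from unmapped
   ChIP-seq reads against a 24-mer satellite motif library, per-locus
   enrichment, and recurring k-mer discovery.
5. **Rank statistics** — exact small-sample Wilcoxon tests and
   Benjamini–Hochberg adjustment.
6. **Synthetic data** — a generator for genomes, stranded aligned read
   sets and ChIP contigs with per-record truth labels, defining the
   study conditions every other module is validated under.

Read alignment, contig assembly, peak calling and differential
expression are deliberately out of scope: the pipeline consumes aligned
reads (SAM), assembled contigs (FASTA) and called peaks (BED).

## The annotation model

### HSAT3 locus calling

HSAT3 has no stable long consensus, so loci are called directly from
sequence: exact matches of the 5-mer unit GAATG and its reverse
complement CATTC are collected on the forward strand, merged when
separated by at most `max_gap` bases, and a merged candidate becomes a
locus when

* it is **longer than `min_length`** (default 1000 bp — satellite arrays
  shorter than 1 kb are indistinguishable from chance microsatellite
  runs),
* its **unit purity** — the fraction of its bases covered by exact unit
  matches — is at least `min_purity` (default 0.80), and
* it **overlaps a pericentromeric window** by at least 1 bp.

`max_gap` (default 25 bp) and `min_purity` are exposed because the
biological literature specifies only the unit, the 1 kb length threshold
and the pericentromeric constraint; the defaults were chosen once so
that arrays diverged by a few percent per base are accepted (purity of a
tandem GAATG array with per-base substitution rate $p$ is approximately
$(1-p)^5$, so 0.80 tolerates up to roughly 4% divergence) while random
sequence is rejected — at 50% GC the chance of any >1 kb window reaching
80% exact 5-mer coverage is negligible, which the test suite verifies
against a brute-force scanner. Pericentromere boundaries are taken from
a user-supplied interval set because they have no universal numeric
definition; "located in" is implemented as ≥1 bp overlap. Loci are
reported unstranded: GAATG arrays on one strand are CATTC arrays on the
other, and calling is invariant under reverse complementation of the
genome (a tested property).

HSAT2 and all other repeat families come from a supplied
RepeatMasker-style annotation, not de novo calling.

### Hierarchical overlap resolution

Genomic feature annotations overlap; to count each read once, every
annotated base must have exactly one owner. Features carry a priority
tier — miRNA (0) > piRNA (1) > lncRNA/lincRNA (2) > RepeatMasker repeat
classes (3), with protein-coding and remaining gene models at 4 — and
contested bases go to the feature with the lowest tier. Within a tier
the rule must still be deterministic; we give the contested piece to the
**widest** competing feature, breaking remaining ties by leftmost start
and then lexicographic family label. (Inside one disjoint atom every
competing feature covers the whole atom, so "longest overlap of the
atom" cannot discriminate; total feature width is the natural
deterministic discriminator.) Adjacent pieces won by the same source
feature are re-merged, so a feature split only by a losing competitor
comes back in one piece. Resolution is idempotent, conserves the
annotated base count, and is verified base-by-base against an
independent per-base arbitration oracle on random feature sets.

### Reporting categories

Resolved features map to the two-group partition used for reporting:
non-repeat transcripts (protein-coding including UTRs and introns;
noncoding: pseudogene, snRNA, miRNA, lncRNA, piRNA) and repeat
transcripts (SINE, LINE, DNA, LTR/ERV, low-complexity, simple,
satellite). rRNA and tRNA map to an excluded category that the read
filter removes; reads outside all features are intergenic.

## Quantification

Reads are filtered by three conjunctive rules — not overlapping an
rRNA/tRNA feature, primary alignment (FLAG bit 0x100 unset), MAPQ ≥ 30
(a read with MAPQ exactly 30 is kept) — and the filter report charges
each removed read to the first rule it fails, in that order. Each
retained fragment is assigned to the resolved feature with the greatest
base overlap of its aligned span (ties: lower tier, then leftmost
feature), or to intergenic. RPM is $10^6 \times
\text{count}/\text{total}$, with the denominator equal to the reads
surviving all filters — the output records this choice because raw-
versus filtered-denominator conventions differ between studies. The
repeat/mRNA ratio is the summed RPM of the seven repeat categories over
the protein-coding RPM (equivalently a count ratio, since the
denominator cancels).

Per-locus satellite matrices report $\log_{10}$ RPM with an explicit
"no reads" marker (`NA`, serialised as the literal `NA` in TSV) instead
of a log of zero; a cumulative mode sums counts across samples before
computing RPM. Strand summaries count a read as sense when its strand
equals the locus reference strand (unstranded loci use `+` as
reference); a flag inverts the convention for dUTP-style protocols
where the sequenced strand is opposite the transcript.

Coordinates are 1-based closed inside the package, following the
GRanges convention of the containers used throughout; BED (0-based
half-open) and SAM (1-based) conversions happen only at the I/O
boundary.

## Sequence statistics

AU skew is $(A-U)/(A+U)$ and GC skew $(G-C)/(G+C)$, computed over
mononucleotide counts with T read as U; both are undefined (`NA`) when
the denominator pair is absent. Published figure legends sometimes pair
the two labels with the formulas in crossed order; this package binds
each name to its formula by content. Dinucleotide usage is the
Karlin-style odds ratio
$$\mathrm{o/e} = \frac{n_{XY}/(L-1)}{(n_X/L)(n_Y/L)}$$
with the numerator counted over the $L-1$ overlapping linear windows
(not circularly). Ambiguity codes are excluded from all counts and a
sequence more than half ambiguous is flagged. Values near 1 indicate
independent base usage; vertebrate mRNAs are CpG/UpA-suppressed while
satellite RNAs are not, which is the pathogen-likeness contrast
`skew_table()` summarises per group (median and IQR).

## ChIP contig motif analysis

Contigs assembled from unmapped ChIP-seq reads are first length-filtered
to the 200–700 nt window (inclusive). Each library motif (typically
24 nt) is then placed ungapped at every offset on both strands of each
contig; identity is matches divided by **motif length**, so the default
0.95 threshold equals "at most one mismatch per 24-mer". Ungapped
placement was chosen over general local alignment because the motifs
are short and tandem-periodic and the reference analysis reports percent
identity against fixed 24-mers; indel handling is deferred. Qualifying
contigs are assigned to the satellite locus containing their best
full-length ungapped match (ties: leftmost locus, recorded), ChIP and
input per-locus counts are compared with the two-sided Wilcoxon
rank-sum test, and recurring motifs are ranked by the number of distinct
contigs containing each k-mer (k = 9 by default, matching the length of
the reported satellite-binding motif), with ties broken by total
occurrences and then lexicographically. Scores are strand-collapsed — a
k-mer and its reverse complement share a score, reported under the
lexicographically smaller with the other orientation alongside — since
assembled contigs have arbitrary orientation; the collapse is
switchable. Peak–repeat overlap counting keeps peaks with score
strictly greater than 5 and counts a peak once per repeat family it
overlaps.

## Rank statistics

`wilcoxon_rank_sum()` enumerates all $\binom{n_x+n_y}{n_x}$ rank
subsets when the combined size is at most 12 and there are no cross-
group ties; `wilcoxon_signed_rank()` enumerates all $2^n$ sign
assignments for at most 12 nonzero differences (zeros dropped and
reported, midranks for tied magnitudes). Larger samples use the normal
approximation with tie correction and a 0.5 continuity correction;
two-sided p-values double the smaller tail, capped at 1, and a
zero-variance null (identical groups) gives p = 1 directly. The
exact/approximate threshold of 12 keeps enumeration below
$\binom{12}{6} = 924$ subsets while the approximation error at that
size is already below 0.02 (a tested property). The suite cross-checks
both tests against `stats::wilcox.test` and against direct enumeration,
and verifies the type-I error rate at 0.05 ± 0.01 under 10,000 null
replicates. `bh_adjust()` validates its input and applies the standard
step-up adjustment.

## The synthetic-data generator

`simulate_genome()` builds random-background chromosomes and plants
tandem arrays and single-copy elements with per-base substitution at a
configured rate; the substitution process (`mutate_sequence()`) is
documented — one uniform draw per base, left to right, then a uniform
choice among the three alternative bases — so tests can replay the draw
sequence and verify mutation counts and positions exactly.
`example_genome_config()` fixes the layout emulated throughout: two
chromosomes (200 kb and 150 kb) with pericentromeric windows hosting
divergent HSAT3 GAATG arrays (5 kb at 2% and 2 kb at 3% per-base
divergence — within the caller's default purity tolerance), synthetic
HSAT2-like 24-mer arrays, an ALR-like monomer array, and arm-located
protein-coding genes, noncoding genes, LINE/SINE/LTR/DNA elements,
simple and low-complexity repeats and rRNA/tRNA genes. The HSAT2 24-mer
and ALR 171-mer consensi are synthetic stand-ins (right length and
GGAAT-richness, arbitrary divergent positions), not published
consensus sequences.

`simulate_reads()` draws each fragment's category from a configurable
mixture (`read_mix_target(r)` builds a mixture whose expected
repeat/mRNA ratio is exactly `r`, with protein-coding and repeat mass
sharing 90% of the reads and a satellite/simple/low-complexity-heavy
repeat profile), places it uniformly within a width-weighted feature of
that category (intergenic reads go uniformly on unannotated bases, so
category RPMs do not trivially sum to one million), assigns strand by
the category's sense fraction — default 1.0 (fully stranded) for all
categories except satellite at 0.5, reflecting the observed
double-stranded sense/antisense symmetry of pericentromeric
transcripts in EVs — and samples MAPQ, secondary flags and rRNA/tRNA
contamination independently. Reads are emitted as already-aligned
records at truth coordinates: isolating the pipeline's own computation
from aligner behaviour is the point, so mapping ambiguity beyond the
MAPQ distribution is not modelled. One record is one fragment
(paired-end geometry is not simulated, matching the
count-each-fragment-once rule). Quality strings, sequencing errors and
indels are out of scope.

`simulate_chip_contigs()` samples contig substrings (lengths uniform on
the configured bounds — no shape beyond that is modelled) from
satellite loci, with a ChIP condition drawn preferentially from bound
loci via a width-times-`bound_weight` sampling law and an input
condition drawn by width alone, random orientation, and per-condition
substitution.

Every simulator draws from its own stream seeded at the config seed
plus a fixed per-operation offset (genome +0, reads +1, contigs +2), so
adding one operation never perturbs another's draws, and identical
configs give byte-identical outputs — the test suite checks md5 sums of
a full two-run pipeline.

What passing tests on these data do **not** show: recovery under real
alignment ambiguity (multi-mapping satellite reads, which the reference
analysis handles by MAPQ filtering at the aligner level), higher-order
repeat structure (HSAT2 subfamily mosaics are unmodelled — arrays are
uniform), GC-biased coverage, or paired-end effects.

## Problem sizes and numerical choices

The shipped tests run at sizes chosen to make sampling error negligible
relative to the tolerances they assert: 100 random feature sets (≤20
features on 10 kb) for the resolution oracle; 200,000 fragments for
repeat/mRNA ratio recovery within ±0.05 (binomial SE ≈ 0.007 there),
with depth series 10⁴/10⁵/10⁶ over fixed seed panels for the
monotone-error check; 10,000 satellite reads for strand symmetry within
±0.015 (3 binomial SDs); 1,000 random sequences for skew antisymmetry;
and 10,000 null replicates for type-I error within ±0.01 (MC SE ≈
0.002). `scripts/acceptance.R` reruns the full pipeline at the same
scales from a single seed.

Degenerate inputs are handled explicitly rather than silently: empty
genomes yield empty locus sets, zero protein-coding RPM makes the
repeat/mRNA ratio an error, all-zero differences make the signed-rank
test an error, zero-count locus entries are `NA` rather than -Inf, and
contigs shorter than a motif simply yield no placement.

## Limitations

* The recurring-motif recurrence score (distinct contigs containing the
  k-mer) is a declared scoring function, not one recovered from any
  reference implementation.
* The ungapped identity model cannot reward gapped homology; heavily
  indel-diverged contigs will be under-assigned.
* RPM is the only normalisation offered; no TPM or size-factor
  normalisation, and no isoform-level quantification.
* The within-tier widest-feature tie-break is one defensible
  deterministic convention among several; results on annotations with
  many same-tier overlaps depend on it.
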