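# Stranded aligned-read simulator. Reads are emitted as already-aligned
# records at their truth coordinates: the aligner is out of scope, so the
# only mapping noise modelled is the configured MAPQ distribution and
# secondary-alignment flags.

#' Configuration for the stranded read simulator
#'
#' @param n_fragments number of fragments to simulate (one record each;
#'   paired-end geometry is not modelled).
#' @param weights named numeric vector of mixture weights over reporting
#'   categories (see [category_levels()]; `"intergenic"` allowed,
#'   `"rRNA_tRNA_excluded"` handled via `rrna_fraction`). Must be
#'   nonnegative and sum to 1 within 1e-9.
#' @param read_length read length in nt (default 100, as for standard
#'   short-read libraries).
#' @param strand_fraction named numeric vector in \[0,1\]: per category,
#'   the fraction of reads sense to the feature. Categories absent from
#'   the vector use `default_strand_fraction`.
#' @param default_strand_fraction fallback sense fraction (default 1:
#'   fully stranded transcription).
#' @param mapq_dist data.frame with columns `mapq` and `prob` (summing to
#'   1): the MAPQ distribution of simulated alignments.
#' @param secondary_prob probability a record carries the
#'   secondary-alignment flag.
#' @param rrna_fraction fraction of fragments drawn from rRNA/tRNA genes
#'   (library contamination surviving depletion).
#' @param seed integer seed.
#' @return a list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_fragments, weights, read_length = 100L,
                            strand_fraction = c(satellite = 0.5),
                            default_strand_fraction = 1,
                            mapq_dist = data.frame(
                              mapq = c(0L, 20L, 30L, 60L),
                              prob = c(0.05, 0.05, 0.10, 0.80)),
                            secondary_prob = 0.02,
                            rrna_fraction = 0, seed = 1L) {
  stopifnot(n_fragments > 0, is.numeric(weights), !is.null(names(weights)))
  if (any(weights < 0)) stop("mixture weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  bad <- setdiff(names(weights), setdiff(category_levels(),
                                         "rRNA_tRNA_excluded"))
  if (length(bad) > 0L) {
    stop("unknown mixture categories: ", paste(bad, collapse = ", "))
  }
  stopifnot(all(strand_fraction >= 0), all(strand_fraction <= 1),
            default_strand_fraction >= 0, default_strand_fraction <= 1,
            abs(sum(mapq_dist$prob) - 1) < 1e-9,
            secondary_prob >= 0, secondary_prob <= 1,
            rrna_fraction >= 0, rrna_fraction < 1)
  structure(
    list(n_fragments = as.integer(n_fragments), weights = weights,
         read_length = as.integer(read_length),
         strand_fraction = strand_fraction,
         default_strand_fraction = default_strand_fraction,
         mapq_dist = mapq_dist, secondary_prob = secondary_prob,
         rrna_fraction = rrna_fraction, seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

#' Mixture weights targeting a repeat/mRNA ratio
#'
#' Builds a category mixture whose expected repeat/mRNA read-count ratio
#' equals `target_ratio`: protein-coding and summed repeat weights share
#' 90% of the mass in ratio `target_ratio`, the remaining 10% is split
#' between noncoding (0.04) and intergenic (0.06). Repeat mass is
#' distributed over the repeat classes in a fixed EV-like profile
#' (satellite-, simple- and low-complexity-heavy).
#'
#' @param target_ratio desired repeat/mRNA ratio (e.g. 1.7 for an EV-like
#'   sample, 0.5 for a cell-like sample).
#' @return named numeric mixture suitable for [read_sim_config()].
#' @export
read_mix_target <- function(target_ratio) {
  stopifnot(target_ratio > 0)
  pc <- 0.9 / (1 + target_ratio)
  rep_total <- 0.9 - pc
  profile <- c(satellite = 0.22, simple = 0.20, low_complexity = 0.14,
               LINE = 0.16, SINE = 0.16, `LTR/ERV` = 0.09, DNA = 0.03)
  c(protein_coding = pc, rep_total * profile,
    noncoding = 0.04, intergenic = 0.06)
}

#' Simulate stranded aligned reads over a synthetic genome
#'
#' Draws each fragment's category from the configured mixture
#' (multinomially), places it uniformly within a feature of that category
#' (features chosen with probability proportional to width; intergenic
#' reads are placed uniformly on unannotated bases), assigns strand by
#' the category's sense fraction relative to the feature strand, and
#' samples MAPQ and the secondary flag independently. Each record keeps
#' its truth category.
#'
#' @param sim a `sim_genome` (from [simulate_genome()]), or any list with
#'   `genome` and `annotation` elements.
#' @param config a [read_sim_config()].
#' @return data.frame of class `aligned_reads`: `read_id`, `chrom`,
#'   `start` (1-based), `width`, `strand`, `mapq`, `secondary` (logical),
#'   `truth` (category). Convert with [reads_to_granges()] or write with
#'   [write_sam()].
#' @export
simulate_reads <- function(sim, config) {
  stopifnot(inherits(config, "read_sim_config"))
  genome <- sim$genome
  annotation <- sim$annotation
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  feat_cat <- classify_category(as.character(
    S4Vectors::mcols(annotation)$class))

  w <- config$weights
  for (cat in names(w)[w > 0]) {
    if (cat != "intergenic" && !any(feat_cat == cat)) {
      stop("mixture gives positive weight to category '", cat,
           "' but the annotation has no such feature")
    }
  }
  if (config$rrna_fraction > 0 && !any(feat_cat == "rRNA_tRNA_excluded")) {
    stop("rrna_fraction > 0 but the annotation has no rRNA/tRNA feature")
  }

  .with_seed(config$seed + 1L, {
    n <- config$n_fragments
    rl <- config$read_length
    is_rrna <- runif(n) < config$rrna_fraction
    truth <- character(n)
    truth[is_rrna] <- "rRNA_tRNA_excluded"
    n_mix <- sum(!is_rrna)
    truth[!is_rrna] <- sample(names(w), n_mix, replace = TRUE, prob = w)

    chrom <- character(n)
    start <- integer(n)
    sense <- logical(n)
    feat_strand <- rep("+", n)

    # intergenic gaps (unannotated bases), weighted by width
    gaps <- GenomicRanges::gaps(GenomicRanges::reduce(
      annotation, ignore.strand = TRUE))
    gaps <- gaps[as.character(GenomicRanges::strand(gaps)) == "*"]

    for (cat in unique(truth)) {
      idx <- which(truth == cat)
      if (cat == "intergenic") {
        pool <- gaps
        pool_strand <- rep("+", length(pool))
      } else {
        sel <- which(feat_cat == cat)
        pool <- annotation[sel]
        pool_strand <- as.character(GenomicRanges::strand(pool))
        pool_strand[pool_strand == "*"] <- "+"
      }
      pw <- GenomicRanges::width(pool)
      j <- sample.int(length(pool), length(idx), replace = TRUE,
                      prob = pw / sum(pw))
      fs <- GenomicRanges::start(pool)[j]
      fe <- GenomicRanges::end(pool)[j]
      hi <- pmax(fs, fe - rl + 1L)
      s <- fs + floor(runif(length(idx)) * (hi - fs + 1L))
      # keep the read on the chromosome when the feature is shorter than
      # the read length
      cln <- chrom_lengths[as.character(GenomeInfoDb::seqnames(pool))[j]]
      s <- pmin(s, pmax(1L, cln - rl + 1L))
      chrom[idx] <- as.character(GenomeInfoDb::seqnames(pool))[j]
      start[idx] <- as.integer(s)
      feat_strand[idx] <- pool_strand[j]
      sf <- config$strand_fraction[cat]
      if (is.na(sf)) sf <- config$default_strand_fraction
      sense[idx] <- runif(length(idx)) < sf
    }

    strand <- ifelse(sense, feat_strand,
                     ifelse(feat_strand == "+", "-", "+"))
    mapq <- config$mapq_dist$mapq[sample.int(nrow(config$mapq_dist), n,
                                             replace = TRUE,
                                             prob = config$mapq_dist$prob)]
    secondary <- runif(n) < config$secondary_prob
    out <- data.frame(
      read_id = sprintf("read%07d", seq_len(n)),
      chrom = chrom, start = start, width = rl, strand = strand,
      mapq = as.integer(mapq), secondary = secondary, truth = truth,
      stringsAsFactors = FALSE
    )
    class(out) <- c("aligned_reads", "data.frame")
    out
  })
}

#' Convert an aligned-read table to GRanges
#'
#' @param reads an `aligned_reads` data.frame (see [simulate_reads()] or
#'   [read_sam()]).
#' @param seqlengths optional named chromosome lengths.
#' @return a [GenomicRanges::GRanges] with `mapq`, `secondary`, `read_id`
#'   (and `truth` if present) metadata columns.
#' @export
reads_to_granges <- function(reads, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    reads$chrom,
    IRanges::IRanges(start = reads$start, width = reads$width),
    strand = reads$strand
  )
  S4Vectors::mcols(gr)$read_id <- reads$read_id
  S4Vectors::mcols(gr)$mapq <- reads$mapq
  S4Vectors::mcols(gr)$secondary <- reads$secondary
  if (!is.null(reads$truth)) S4Vectors::mcols(gr)$truth <- reads$truth
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}
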