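# Brute-force oracles, kept independent of the implementation paths they
# check: per-base arbitration for annotation resolution, per-read rule
# application and maximal-overlap assignment, exhaustive motif placement
# scoring, and exhaustive k-mer tallying.

# per-base ownership over one chromosome: winning feature index per
# annotated base (lowest tier, then widest, then leftmost, then family)
oracle_per_base_ownership <- function(features, chrom_len) {
  own <- rep(NA_integer_, chrom_len)
  st <- GenomicRanges::start(features)
  en <- GenomicRanges::end(features)
  tier <- S4Vectors::mcols(features)$tier
  fam <- as.character(S4Vectors::mcols(features)$family)
  wd <- en - st + 1L
  for (b in seq_len(chrom_len)) {
    cand <- which(st <= b & en >= b)
    if (length(cand) == 0L) next
    o <- order(tier[cand], -wd[cand], st[cand], fam[cand], method = "radix")
    own[b] <- cand[o[1L]]
  }
  own
}

# expand a resolved annotation to per-base source-feature indices
resolved_to_per_base <- function(resolved, chrom_len) {
  own <- rep(NA_integer_, chrom_len)
  for (i in seq_along(resolved)) {
    own[GenomicRanges::start(resolved)[i]:GenomicRanges::end(resolved)[i]] <-
      S4Vectors::mcols(resolved)$source[i]
  }
  own
}

# per-read filtering rules, applied one read at a time
oracle_filter <- function(reads, rrna_ranges, min_mapq = 30L) {
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    overlaps_rrna <- FALSE
    if (!is.null(rrna_ranges) && length(rrna_ranges) > 0L) {
      for (j in seq_along(rrna_ranges)) {
        if (as.character(GenomeInfoDb::seqnames(rrna_ranges))[j] == r$chrom &&
            r$start <= GenomicRanges::end(rrna_ranges)[j] &&
            r$start + r$width - 1L >= GenomicRanges::start(rrna_ranges)[j]) {
          overlaps_rrna <- TRUE
          break
        }
      }
    }
    keep[i] <- !overlaps_rrna && !r$secondary && r$mapq >= min_mapq
  }
  keep
}

# maximal-overlap assignment of one read to resolved pieces
oracle_assign_one <- function(chrom, start, width, resolved) {
  rs <- start
  re <- start + width - 1L
  ov <- pmax(0L, pmin(GenomicRanges::end(resolved), re) -
                 pmax(GenomicRanges::start(resolved), rs) + 1L)
  ov[as.character(GenomeInfoDb::seqnames(resolved)) != chrom] <- 0L
  if (all(ov == 0L)) return(NA_integer_)
  cand <- which(ov > 0L)
  o <- order(-ov[cand], S4Vectors::mcols(resolved)$tier[cand],
             GenomicRanges::start(resolved)[cand], cand, method = "radix")
  cand[o[1L]]
}

# exhaustive ungapped placement of every motif on both strands of every
# contig; returns hits at >= min_identity with the best identity
oracle_motif_hits <- function(contigs, library, min_identity = 0.95) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  mismatches <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  rows <- list()
  for (cn in names(contigs)) {
    cs <- as.character(contigs[[cn]])
    for (mi in seq_len(nrow(library))) {
      pat <- library$sequence[mi]
      np <- nchar(pat)
      best <- Inf
      for (strand_seq in c(cs, revcomp(cs))) {
        ns <- nchar(strand_seq)
        if (ns < np) next
        for (p in seq_len(ns - np + 1L)) {
          mm <- mismatches(substr(strand_seq, p, p + np - 1L), pat)
          if (mm < best) best <- mm
        }
      }
      if (is.finite(best) && (np - best) / np >= min_identity) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = cn, motif_id = library$motif_id[mi],
          identity = (np - best) / np, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig_id = character(0), motif_id = character(0),
                      identity = numeric(0)))
  }
  do.call(rbind, rows)
}

# exhaustive k-mer tally (no strand collapse): score = distinct contigs,
# ties by total occurrences, then lexicographic
oracle_kmer_ranking <- function(contigs, k) {
  per <- lapply(contigs, function(s) {
    s <- as.character(s)
    substring(s, seq_len(nchar(s) - k + 1L),
              seq_len(nchar(s) - k + 1L) + k - 1L)
  })
  occ <- table(unlist(per))
  pres <- table(unlist(lapply(per, unique)))
  motifs <- names(pres)
  score <- as.integer(pres)
  occurrences <- as.integer(occ[motifs])
  o <- order(-score, -occurrences, motifs, method = "radix")
  data.frame(motif = motifs[o], score = score[o],
             occurrences = occurrences[o], stringsAsFactors = FALSE)
}

# random feature set on one chromosome for resolution tests
random_feature_set <- function(n_features, chrom_len,
                               classes = c("miRNA", "piRNA", "lncRNA",
                                           "SINE", "LINE", "satellite",
                                           "simple", "protein_coding")) {
  cls <- sample(classes, n_features, replace = TRUE)
  st <- sample.int(chrom_len - 50L, n_features, replace = TRUE)
  wd <- sample(10:2000, n_features, replace = TRUE)
  en <- pmin(st + wd - 1L, chrom_len)
  feature_set("chr1", st, en,
              strand = sample(c("+", "-"), n_features, replace = TRUE),
              family = paste0("fam", seq_len(n_features)),
              class_label = cls)
}

# small genome: one chromosome, one pure GAATG array inside the
# pericentromere
tiny_hsat3_genome <- function(copies = 240L, array_start = 20001L,
                              chrom_len = 50000L, subst = 0,
                              peri = c(15001L, 35000L), seed = 1L) {
  elements <- data.frame(
    name = "HSAT3_A", class = "satellite", family = "HSAT3",
    unit = "GAATG", copies = copies, chrom = "chr1",
    start = array_start, subst_rate = subst
  )
  cfg <- sim_genome_config(
    c(chr1 = chrom_len),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(peri[1], peri[2])),
    elements, seed = seed
  )
  simulate_genome(cfg)
}
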