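# Analysis of contigs assembled from unmapped ChIP reads: length
# filtering, ungapped alignment against a 24-mer satellite motif
# library, locus assignment, ChIP-vs-input enrichment, recurring k-mer
# motifs, and peak-repeat overlap counting.

.as_dss <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- sprintf("contig%04d", seq_along(x))
  Biostrings::DNAStringSet(x)
}

# minimum Hamming distance of `pattern` over all full-length ungapped
# placements in `subject` (one strand); Inf when subject is shorter
.best_placement <- function(pattern, subject) {
  np <- nchar(pattern)
  ns <- nchar(subject)
  if (ns < np) return(list(mismatches = Inf, at = NA_integer_))
  d <- Biostrings::neditStartingAt(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    starting.at = seq_len(ns - np + 1L), with.indels = FALSE
  )
  i <- which.min(d)
  list(mismatches = d[i], at = i)
}

#' Filter contigs by length
#'
#' Retains contigs with `min_len <= length <= max_len` (inclusive
#' bounds), matching the 200-700 nt window used for satellite contig
#' analysis.
#'
#' @param contigs [Biostrings::DNAStringSet] or character vector.
#' @param min_len,max_len inclusive length bounds (default 200 and 700).
#' @return the retained contigs (same type as input coerced to
#'   `DNAStringSet`).
#' @export
filter_contigs <- function(contigs, min_len = 200L, max_len = 700L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  dss <- .as_dss(contigs)
  dss[Biostrings::width(dss) >= min_len & Biostrings::width(dss) <= max_len]
}

#' Build a 24-mer satellite motif library
#'
#' @param sequences named character vector (or `DNAStringSet`) of motif
#'   sequences.
#' @param family character vector of satellite families (e.g. `"HSAT2"`,
#'   `"HSAT3"`), one per motif.
#' @return data.frame of class `motif_library`: `motif_id`, `family`,
#'   `sequence`.
#' @export
motif_library <- function(sequences, family) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopifnot(length(sequences) >= 1L,
            length(family) == length(sequences))
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("motif%03d", seq_along(sequences))
  }
  if (!all(grepl("^[ACGT]+$", sequences))) {
    stop("motif sequences must be over A/C/G/T")
  }
  structure(
    data.frame(motif_id = names(sequences), family = family,
               sequence = unname(sequences), stringsAsFactors = FALSE),
    class = c("motif_library", "data.frame")
  )
}

#' Built-in synthetic HSAT2,3 24-mer motif library
#'
#' A small stand-in for published satellite subfamily 24-mer references:
#' HSAT3 motifs are phased tilings of the GAATG simple-repeat unit (and
#' one diverged variant); the HSAT2 motif is the synthetic 24-mer
#' consensus planted by [example_genome_config()]. Synthetic — motif
#' sequences are not taken from any published library.
#'
#' @return a [motif_library()].
#' @export
hsat_motif_library_synthetic <- function() {
  hsat3_a <- strrep("GAATG", 5L)
  motif_library(
    c(HSAT3_24A = substr(hsat3_a, 1L, 24L),
      HSAT3_24B = substr(strrep("AATGG", 5L), 1L, 24L),
      HSAT3_24C = sub("GAATGGAATG$", "GAATGGACTG",
                      substr(hsat3_a, 1L, 24L)),
      HSAT2_24A = .HSAT2_UNIT_SYNTH),
    family = c("HSAT3", "HSAT3", "HSAT3", "HSAT2")
  )
}

#' Align contigs against a satellite motif library
#'
#' For each contig and motif, scores every full-length ungapped placement
#' of the motif on both strands; identity = matches / motif length. The
#' best placement per contig-motif pair is kept and reported as a hit
#' when identity >= `min_identity` (with 24-mers the default 0.95 means
#' at most one mismatch). Contigs shorter than a motif yield no placement
#' for it.
#'
#' @param contigs `DNAStringSet` or character vector.
#' @param library a [motif_library()].
#' @param min_identity minimum identity fraction (default 0.95).
#' @return data.frame of class `contig_hits`: `contig_id`, `motif_id`,
#'   `family`, `identity`, `mismatches`, `alignment_length`, `strand`,
#'   `at` (placement start in the contig, forward-strand coordinates of
#'   the strand scanned).
#' @export
align_to_motifs <- function(contigs, library, min_identity = 0.95) {
  stopifnot(inherits(library, "motif_library"), nrow(library) >= 1L)
  dss <- .as_dss(contigs)
  rows <- list()
  for (ci in seq_along(dss)) {
    fwd <- as.character(dss[[ci]])
    rev <- as.character(Biostrings::reverseComplement(dss[[ci]]))
    for (mi in seq_len(nrow(library))) {
      pat <- library$sequence[mi]
      bf <- .best_placement(pat, fwd)
      br <- .best_placement(pat, rev)
      if (is.infinite(bf$mismatches) && is.infinite(br$mismatches)) next
      if (bf$mismatches <= br$mismatches) {
        best <- bf
        strand <- "+"
      } else {
        best <- br
        strand <- "-"
      }
      ident <- (nchar(pat) - best$mismatches) / nchar(pat)
      if (ident >= min_identity) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = names(dss)[ci], motif_id = library$motif_id[mi],
          family = library$family[mi], identity = ident,
          mismatches = best$mismatches, alignment_length = nchar(pat),
          strand = strand, at = best$at, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(contig_id = character(0), motif_id = character(0),
               family = character(0), identity = numeric(0),
               mismatches = numeric(0), alignment_length = integer(0),
               strand = character(0), at = integer(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  class(out) <- c("contig_hits", "data.frame")
  out
}

#' Assign qualifying contigs to satellite loci
#'
#' Each contig with at least one motif hit is placed full-length
#' (ungapped, both orientations) against the sequence of every satellite
#' locus; it is assigned to the locus with the best identity, provided
#' that identity reaches `min_identity`. Ties are broken by the leftmost
#' locus (chromosome order, then start) and recorded.
#'
#' @param hits a `contig_hits` table (see [align_to_motifs()]); only the
#'   contig ids are used.
#' @param contigs the contig sequences (`DNAStringSet` or character).
#' @param loci `GRanges` of satellite loci.
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param min_identity minimum full-contig identity (default 0.95).
#' @return list of class `contig_assignment`: `assignments` (per contig:
#'   locus index, identity, strand, tie flag), `locus_counts` (integer
#'   per locus), `unassigned` (contig ids).
#' @export
assign_contig_loci <- function(hits, contigs, loci, genome,
                               min_identity = 0.95) {
  dss <- .as_dss(contigs)
  qualifying <- intersect(names(dss), unique(hits$contig_id))
  # loci in deterministic genomic order for leftmost tie-breaking
  ord <- order(match(as.character(GenomeInfoDb::seqnames(loci)),
                     names(genome)),
               GenomicRanges::start(loci))
  locus_seqs <- lapply(ord, function(i) {
    as.character(Biostrings::subseq(
      genome[[as.character(GenomeInfoDb::seqnames(loci))[i]]],
      start = GenomicRanges::start(loci)[i],
      width = GenomicRanges::width(loci)[i]))
  })
  res <- lapply(qualifying, function(cid) {
    fwd <- as.character(dss[[cid]])
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    best_mm <- Inf
    best_locus <- NA_integer_
    best_strand <- NA_character_
    tie <- FALSE
    for (k in seq_along(locus_seqs)) {
      for (strand in c("+", "-")) {
        mm <- .best_placement(if (strand == "+") fwd else rev,
                              locus_seqs[[k]])$mismatches
        if (mm < best_mm) {
          best_mm <- mm
          best_locus <- ord[k]
          best_strand <- strand
          tie <- FALSE
        } else if (is.finite(mm) && mm == best_mm && ord[k] != best_locus) {
          tie <- TRUE  # equally good later locus; leftmost kept
        }
      }
    }
    ident <- if (is.finite(best_mm)) {
      (nchar(fwd) - best_mm) / nchar(fwd)
    } else NA_real_
    if (is.na(ident) || ident < min_identity) {
      data.frame(contig_id = cid, locus = NA_integer_,
                 identity = ident, strand = NA_character_, tie = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(contig_id = cid, locus = best_locus, identity = ident,
                 strand = best_strand, tie = tie, stringsAsFactors = FALSE)
    }
  })
  assignments <- if (length(res) == 0L) {
    data.frame(contig_id = character(0), locus = integer(0),
               identity = numeric(0), strand = character(0),
               tie = logical(0), stringsAsFactors = FALSE)
  } else do.call(rbind, res)
  locus_counts <- as.integer(table(factor(assignments$locus,
                                          levels = seq_along(loci))))
  structure(
    list(assignments = assignments, locus_counts = locus_counts,
         unassigned = assignments$contig_id[is.na(assignments$locus)]),
    class = "contig_assignment"
  )
}

#' ChIP vs input per-locus enrichment test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test comparing per-locus
#' contig counts between the ChIP and input conditions (exact for small
#' samples, normal approximation with tie correction otherwise; see
#' [wilcoxon_rank_sum()]).
#'
#' @param chip_counts,input_counts numeric vectors of per-locus counts.
#' @return a `rank_test` result.
#' @export
enrichment_test <- function(chip_counts, input_counts) {
  if (length(chip_counts) == 0L || length(input_counts) == 0L) {
    stop("need at least one locus per condition")
  }
  wilcoxon_rank_sum(chip_counts, input_counts)
}

#' Recurring k-mer motifs across contigs
#'
#' Scores each k-mer by the number of distinct contigs containing it.
#' By default scores are strand-collapsed: a k-mer and its reverse
#' complement share one score, reported under the lexicographically
#' smaller of the two. Ranking is by score, then total occurrence count,
#' then lexicographic order.
#'
#' @param contigs `DNAStringSet` or character vector (nonempty).
#' @param k motif length (default 9; must be at least 4).
#' @param strand_collapse collapse reverse complements (default TRUE).
#' @param top number of motifs to return (default 20; `Inf` for all).
#' @return data.frame of class `motif_ranking`: `motif`, `score`
#'   (distinct contigs), `occurrences` (total occurrences across contigs
#'   and, when collapsed, strands), ordered by rank.
#' @export
recurring_motif <- function(contigs, k = 9L, strand_collapse = TRUE,
                            top = 20L) {
  dss <- .as_dss(contigs)
  if (length(dss) == 0L) stop("contigs must be nonempty")
  if (k < 4L) stop("k must be at least 4")
  if (all(Biostrings::width(dss) < k)) {
    stop("k is larger than every contig")
  }
  # scan the forward strand; strand collapse maps every k-mer to the
  # lexicographically smaller of itself and its reverse complement, so
  # one forward scan covers both strands
  per_contig <- lapply(seq_along(dss), function(ci) {
    s <- as.character(dss[[ci]])
    if (nchar(s) < k) return(NULL)
    kmers <- substring(s, seq_len(nchar(s) - k + 1L),
                       seq_len(nchar(s) - k + 1L) + k - 1L)
    kmers <- kmers[grepl("^[ACGT]+$", kmers)]
    if (length(kmers) > 0L && strand_collapse) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
      kmers <- pmin(kmers, rc)
    }
    kmers
  })
  occ <- table(unlist(per_contig))
  presence <- table(unlist(lapply(per_contig, unique)))
  motifs <- names(presence)
  score <- as.integer(presence)
  occurrences <- as.integer(occ[motifs])
  o <- order(-score, -occurrences, motifs, method = "radix")
  out <- data.frame(motif = motifs[o], score = score[o],
                    occurrences = occurrences[o],
                    stringsAsFactors = FALSE)
  if (strand_collapse) {
    out$motif_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out$motif)))
  }
  if (is.finite(top)) out <- head(out, top)
  class(out) <- c("motif_ranking", "data.frame")
  out
}

#' Count high-score peaks overlapping each repeat family
#'
#' Peaks with score strictly greater than `min_score` are counted once
#' per repeat family they overlap by at least 1 bp (a peak spanning two
#' families contributes to both).
#'
#' @param peaks `GRanges` with a `score` metadata column (e.g. imported
#'   from BED6/narrowPeak).
#' @param repeats `GRanges` with a `family` metadata column.
#' @param min_score score threshold, strict (default 5).
#' @return data.frame: `family`, `peaks` (count), one row per family
#'   present in `repeats`.
#' @export
count_peak_repeat_overlaps <- function(peaks, repeats, min_score = 5) {
  stopifnot(!is.null(S4Vectors::mcols(peaks)$score),
            !is.null(S4Vectors::mcols(repeats)$family))
  keep <- peaks[S4Vectors::mcols(peaks)$score > min_score]
  fam <- as.character(S4Vectors::mcols(repeats)$family)
  families <- unique(fam)
  counts <- vapply(families, function(f) {
    sum(IRanges::overlapsAny(keep, repeats[fam == f],
                             ignore.strand = TRUE))
  }, integer(1))
  data.frame(family = families, peaks = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
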