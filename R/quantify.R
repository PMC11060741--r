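# Read filtering, feature assignment, RPM tables, repeat/mRNA ratio,
# per-locus satellite matrices and strand-symmetry summaries.

# Assign each query range to the target with the greatest base overlap;
# ties go to the lower priority tier (if present), then leftmost target,
# then smallest target index. Returns NA for queries with no overlap.
.max_overlap_assign <- function(query, target) {
  hits <- GenomicRanges::findOverlaps(query, target, ignore.strand = TRUE)
  if (length(hits) == 0L) return(rep(NA_integer_, length(query)))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(query)[q], IRanges::ranges(target)[s]))
  tier <- S4Vectors::mcols(target)$tier
  if (is.null(tier)) tier <- rep(0L, length(target))
  o <- order(q, -ow, tier[s], GenomicRanges::start(target)[s], s,
             method = "radix")
  first <- o[!duplicated(q[o])]
  out <- rep(NA_integer_, length(query))
  out[q[first]] <- s[first]
  out
}

.reads_as_granges <- function(reads) {
  if (methods::is(reads, "GRanges")) reads else reads_to_granges(reads)
}

#' Filter aligned reads for quantification
#'
#' Applies the three retention rules in order: (1) drop reads overlapping
#' (by at least 1 bp) an rRNA or tRNA feature of the resolved annotation,
#' (2) drop secondary alignments, (3) drop reads with MAPQ below
#' `min_mapq`. The rules are conjunctive, so the retained set does not
#' depend on the order; the order only determines which rule a
#' multiply-offending read is charged to in the report.
#'
#' @param reads `aligned_reads` data.frame or equivalent `GRanges`.
#' @param resolved resolved annotation (see [resolve_annotations()]); used
#'   to locate rRNA/tRNA features. May be `NULL` to skip that rule.
#' @param min_mapq minimum mapping quality retained (default 30; reads
#'   with MAPQ exactly `min_mapq` are kept).
#' @return the retained reads, with a `filter_report` attribute: counts
#'   of input reads, removals charged to each rule in application order,
#'   and retained reads.
#' @export
filter_reads <- function(reads, resolved = NULL, min_mapq = 30L) {
  gr <- .reads_as_granges(reads)
  n <- length(gr)
  is_rrna <- rep(FALSE, n)
  if (!is.null(resolved) && length(resolved) > 0L) {
    rr <- resolved[classify_category(as.character(
      S4Vectors::mcols(resolved)$class)) == "rRNA_tRNA_excluded"]
    if (length(rr) > 0L) {
      is_rrna <- IRanges::overlapsAny(gr, rr, ignore.strand = TRUE)
    }
  }
  is_secondary <- S4Vectors::mcols(gr)$secondary
  low_mapq <- S4Vectors::mcols(gr)$mapq < min_mapq
  removed_rrna <- is_rrna
  removed_secondary <- !removed_rrna & is_secondary
  removed_mapq <- !removed_rrna & !is_secondary & low_mapq
  keep <- !(is_rrna | is_secondary | low_mapq)
  report <- list(
    input = n,
    removed_rrna_trna = sum(removed_rrna),
    removed_secondary = sum(removed_secondary),
    removed_low_mapq = sum(removed_mapq),
    retained = sum(keep),
    min_mapq = as.integer(min_mapq)
  )
  out <- if (methods::is(reads, "GRanges")) reads[keep] else {
    r <- reads[keep, , drop = FALSE]
    rownames(r) <- NULL
    r
  }
  attr(out, "filter_report") <- report
  out
}

#' Assign filtered reads to resolved features and categories
#'
#' Each read is assigned to the single resolved feature with the greatest
#' base overlap of its aligned span (ties: lower priority tier, then
#' leftmost feature). Reads overlapping no feature are `"intergenic"`.
#' Each fragment is counted exactly once.
#'
#' @param reads filtered `aligned_reads` (data.frame or `GRanges`).
#' @param resolved resolved annotation `GRanges`.
#' @return a list of class `read_assignment`: `reads` (input table with
#'   `feature` index into `resolved`, `family` and `category` columns),
#'   `category_counts` (named integer vector over [category_levels()]
#'   present), and `feature_counts` (data.frame per resolved piece).
#' @export
assign_reads <- function(reads, resolved) {
  gr <- .reads_as_granges(reads)
  lv <- GenomeInfoDb::seqlevels(resolved)
  if (length(lv) > 0L) {
    unknown <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gr))), lv)
    if (length(unknown) > 0L) {
      stop("read(s) on chromosome(s) unknown to the annotation: ",
           paste(unknown, collapse = ", "))
    }
  }
  idx <- .max_overlap_assign(gr, resolved)
  mc <- S4Vectors::mcols(resolved)
  category <- ifelse(is.na(idx), "intergenic",
                     classify_category(as.character(mc$class))[
                       ifelse(is.na(idx), 1L, idx)])
  family <- ifelse(is.na(idx), NA_character_,
                   as.character(mc$family)[ifelse(is.na(idx), 1L, idx)])
  df <- if (methods::is(reads, "GRanges")) {
    as.data.frame(S4Vectors::mcols(reads))
  } else as.data.frame(reads)
  df$feature <- idx
  df$family <- family
  df$category <- category
  cats_present <- intersect(category_levels(), unique(category))
  category_counts <- vapply(cats_present,
                            function(cc) sum(category == cc), integer(1))
  tab <- table(factor(idx, levels = seq_along(resolved)))
  feature_counts <- data.frame(
    feature = seq_along(resolved),
    family = as.character(mc$family),
    class = as.character(mc$class),
    category = classify_category(as.character(mc$class)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  structure(
    list(reads = df, category_counts = category_counts,
         feature_counts = feature_counts),
    class = "read_assignment"
  )
}

#' Per-category RPM abundance table
#'
#' RPM(category) = 1e6 x count(category) / total filtered mapped reads.
#' When the counts cover every read (including intergenic), the RPMs sum
#' to 1e6.
#'
#' @param counts named numeric vector of per-category read counts, or a
#'   `read_assignment` (its `category_counts` are used).
#' @param total total filtered mapped reads (default `sum(counts)`);
#'   must be positive.
#' @param sample_id optional sample label.
#' @return data.frame of class `class_abundance`: `category`, `count`,
#'   `rpm`; attributes `total` and `sample_id`.
#' @export
abundance_table <- function(counts, total = NULL, sample_id = NA_character_) {
  if (inherits(counts, "read_assignment")) counts <- counts$category_counts
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  if (is.null(total)) total <- sum(counts)
  if (total <= 0) stop("total filtered mapped reads must be positive")
  out <- data.frame(
    category = names(counts),
    count = as.numeric(counts),
    rpm = 1e6 * as.numeric(counts) / total,
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  attr(out, "sample_id") <- sample_id
  class(out) <- c("class_abundance", "data.frame")
  out
}

#' Repeat/mRNA ratio of a sample
#'
#' Summed RPM of the repeat categories (SINE, LINE, DNA, LTR/ERV,
#' low-complexity, simple, satellite) divided by the protein-coding RPM —
#' the sample-level composition statistic distinguishing EV-like
#' (repeat-heavy) from cell-like cargo.
#'
#' @param table a `class_abundance` table (see [abundance_table()]).
#' @return the ratio (dimensionless).
#' @export
repeat_mrna_ratio <- function(table) {
  stopifnot(is.data.frame(table), all(c("category", "rpm") %in% names(table)))
  pc <- sum(table$rpm[table$category == "protein_coding"])
  if (pc == 0) stop("protein-coding RPM is zero; repeat/mRNA ratio undefined")
  rep_total <- sum(table$rpm[table$category %in% repeat_categories()])
  rep_total / pc
}

#' Count reads per satellite locus
#'
#' Assigns reads (maximal overlap) to the given loci; reads overlapping
#' no locus are ignored.
#'
#' @param reads `aligned_reads` or `GRanges`.
#' @param loci `GRanges` of satellite loci.
#' @return integer vector of counts, one per locus.
#' @export
count_by_locus <- function(reads, loci) {
  gr <- .reads_as_granges(reads)
  idx <- .max_overlap_assign(gr, loci)
  as.integer(table(factor(idx, levels = seq_along(loci))))
}

#' Per-locus log10 RPM expression matrix
#'
#' Entries are log10(1e6 x count / total) per locus and sample;
#' zero-count entries are `NA` ("no reads"), never log of zero. With
#' `cumulative = TRUE` counts are summed across samples before RPM, and
#' a single column is returned.
#'
#' @param counts integer matrix, loci x samples (vectors are treated as
#'   one-column matrices).
#' @param totals numeric vector of per-sample totals (filtered mapped
#'   reads), recycled if scalar.
#' @param cumulative sum counts (and totals) across samples first.
#' @return numeric matrix of log10 RPM with `NA` marking "no reads".
#' @export
locus_matrix <- function(counts, totals, cumulative = FALSE) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, ncol = 1L,
                     dimnames = list(names(counts), NULL))
  }
  totals <- rep_len(totals, ncol(counts))
  stopifnot(all(totals > 0))
  if (cumulative) {
    counts <- matrix(rowSums(counts), ncol = 1L,
                     dimnames = list(rownames(counts), "cumulative"))
    totals <- sum(totals)
  }
  rpm <- sweep(counts, 2L, totals, function(x, tot) 1e6 * x / tot)
  out <- suppressWarnings(log10(rpm))
  out[counts == 0L] <- NA_real_
  out
}

#' Sense/antisense strand summary per satellite locus
#'
#' A read is sense when its strand equals the locus reference strand
#' (unstranded loci use `+` as reference). Loci with no assigned reads
#' get an `NA` sense fraction.
#'
#' @param reads assigned satellite reads (`aligned_reads` or `GRanges`).
#' @param loci `GRanges` of satellite loci.
#' @param invert flip the sense convention (for dUTP-style protocols
#'   where the read strand is opposite the transcript strand).
#' @return data.frame: locus index, `sense`, `antisense`,
#'   `sense_fraction` (NA when no reads).
#' @export
strand_ratio <- function(reads, loci, invert = FALSE) {
  gr <- .reads_as_granges(reads)
  idx <- .max_overlap_assign(gr, loci)
  ref <- as.character(GenomicRanges::strand(loci))
  ref[ref == "*"] <- "+"
  read_strand <- as.character(GenomicRanges::strand(gr))
  is_sense <- read_strand == ref[ifelse(is.na(idx), 1L, idx)]
  if (invert) is_sense <- !is_sense
  is_sense[is.na(idx)] <- NA
  sense <- vapply(seq_along(loci), function(i) {
    sum(is_sense[!is.na(idx) & idx == i])
  }, integer(1))
  anti <- vapply(seq_along(loci), function(i) {
    sum(!is_sense[!is.na(idx) & idx == i])
  }, integer(1))
  denom <- sense + anti
  data.frame(
    locus = seq_along(loci),
    sense = sense, antisense = anti,
    sense_fraction = ifelse(denom > 0, sense / denom, NA_real_)
  )
}
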