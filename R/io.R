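# File format boundaries. Internally everything is 1-based closed
# (GRanges convention); BED is converted from/to 0-based half-open and
# SAM positions are 1-based, at these functions only.

#' Write aligned reads as SAM
#'
#' Emits a minimal SAM file: `@HD`/`@SQ` header and one record per read
#' with FLAG bit 0x10 for reverse strand and 0x100 for secondary
#' alignments, CIGAR `<width>M`, and the truth category (when present) in
#' a `XC:Z:` tag. Sequence and quality fields are written as `*`.
#'
#' @param reads an `aligned_reads` data.frame.
#' @param file output path.
#' @param seqlengths named chromosome lengths for the `@SQ` header.
#' @return `file`, invisibly.
#' @export
write_sam <- function(reads, file, seqlengths) {
  stopifnot(is.data.frame(reads), !is.null(names(seqlengths)))
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
            as.integer(seqlengths))
  )
  flag <- ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$secondary, 256L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                 reads$read_id, flag, reads$chrom, reads$start,
                 reads$mapq, reads$width)
  if (!is.null(reads$truth)) rec <- paste0(rec, "\tXC:Z:", reads$truth)
  writeLines(c(header, rec), file)
  invisible(file)
}

# reference-space width of a simple CIGAR (M/D/N/=/X consume reference)
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read aligned reads from SAM or BAM
#'
#' SAM input is converted to BAM via [Rsamtools::asBam()] and parsed with
#' [Rsamtools::scanBam()]. FLAG bits 0x10 (reverse strand) and 0x100
#' (secondary) are decoded; a `XC:Z:` tag, if present, is returned as the
#' `truth` column. Unmapped records are dropped.
#'
#' @param file path to a SAM or BAM file.
#' @return an `aligned_reads` data.frame (see [simulate_reads()]).
#' @export
read_sam <- function(file) {
  is_bam <- grepl("\\.bam$", file, ignore.case = TRUE)
  bam <- if (is_bam) file else {
    Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "XC"
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(res$pos)
  out <- data.frame(
    read_id = res$qname[keep],
    chrom = as.character(res$rname)[keep],
    start = res$pos[keep],
    width = .cigar_ref_width(res$cigar[keep]),
    strand = ifelse(bitwAnd(res$flag[keep], 16L) > 0L, "-", "+"),
    mapq = as.integer(res$mapq[keep]),
    secondary = bitwAnd(res$flag[keep], 256L) > 0L,
    stringsAsFactors = FALSE
  )
  if (!is.null(res$tag$XC)) out$truth <- res$tag$XC[keep]
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Write a feature annotation as BED
#'
#' BED6 with `name = class:family` and `score = tier`; coordinates are
#' converted to 0-based half-open by the exporter.
#'
#' @param features a `GRanges` with `family`, `class`, `tier` metadata.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_features_bed <- function(features, file) {
  gr <- features
  mc <- S4Vectors::mcols(gr)
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out)$name <- paste0(mc$class, ":", mc$family)
  S4Vectors::mcols(out)$score <- as.numeric(mc$tier)
  rtracklayer::export(out, file, format = "BED")
  invisible(file)
}

#' Read a feature annotation from BED
#'
#' Expects the layout written by [write_features_bed()]: `name` holds
#' `class:family`, `score` the priority tier.
#'
#' @param file path to a BED file.
#' @return a `GRanges` with `family`, `class`, `tier` metadata columns.
#' @export
read_features_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  parts <- strsplit(nm, ":", fixed = TRUE)
  cls <- vapply(parts, `[`, character(1), 1L)
  fam <- vapply(parts, function(p) paste(p[-1L], collapse = ":"),
                character(1))
  tier <- S4Vectors::mcols(gr)$score
  if (is.null(tier) || all(is.na(tier))) tier <- default_tier(cls)
  out <- gr
  S4Vectors::mcols(out) <- NULL
  S4Vectors::mcols(out)$family <- fam
  S4Vectors::mcols(out)$class <- cls
  S4Vectors::mcols(out)$tier <- as.integer(tier)
  out
}

#' Read a RepeatMasker-style repeat annotation table
#'
#' Tab-separated columns `chrom`, `begin`, `end`, `strand`,
#' `repeat_name`, `class_family` (e.g. `SINE/Alu`); `begin` is 1-based as
#' in RepeatMasker `.out` exports. The class is the part of
#' `class_family` before the `/`.
#'
#' @param file path to the TSV.
#' @return a `GRanges` with `family`, `class`, `tier` metadata.
#' @export
read_repeatmasker_tsv <- function(file) {
  df <- read.delim(file, header = TRUE, stringsAsFactors = FALSE)
  req <- c("chrom", "begin", "end", "strand", "repeat_name", "class_family")
  if (!all(req %in% names(df))) {
    stop("RepeatMasker TSV needs columns: ", paste(req, collapse = ", "))
  }
  cls <- sub("/.*$", "", df$class_family)
  feature_set(df$chrom, df$begin, df$end,
              strand = ifelse(df$strand %in% c("C", "-"), "-", "+"),
              family = df$repeat_name, class_label = cls)
}

#' Write / read a truth table as TSV
#'
#' Plain tab-separated round trip for the truth tables emitted by the
#' simulators (list columns such as substitution positions are collapsed
#' to comma-separated strings).
#'
#' @param truth a data.frame.
#' @param file path.
#' @return `write_truth_tsv`: `file`, invisibly; `read_truth_tsv`: the
#'   data.frame.
#' @export
write_truth_tsv <- function(truth, file) {
  df <- truth
  for (cn in names(df)) {
    if (is.list(df[[cn]])) {
      df[[cn]] <- vapply(df[[cn]], paste, character(1), collapse = ",")
    }
  }
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(file) {
  read.delim(file, header = TRUE, stringsAsFactors = FALSE)
}
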