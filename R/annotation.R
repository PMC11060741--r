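# Annotation construction: reporting categories, feature tiers, de novo
# HSAT3 locus calling and hierarchical resolution of overlapping features.

# Reporting categories. Repeat classes follow RepeatMasker nomenclature;
# rRNA/tRNA reads are excluded from quantification (see filter_reads).
.CATEGORY_LEVELS <- c(
  "protein_coding", "noncoding", "SINE", "LINE", "DNA", "LTR/ERV",
  "low_complexity", "simple", "satellite", "rRNA_tRNA_excluded", "intergenic"
)

.REPEAT_CATEGORIES <- c(
  "SINE", "LINE", "DNA", "LTR/ERV", "low_complexity", "simple", "satellite"
)

# class label -> reporting category
.CLASS_TO_CATEGORY <- c(
  protein_coding = "protein_coding",
  pseudogene     = "noncoding",
  snRNA          = "noncoding",
  snoRNA         = "noncoding",
  miRNA          = "noncoding",
  piRNA          = "noncoding",
  lncRNA         = "noncoding",
  lincRNA        = "noncoding",
  SINE           = "SINE",
  LINE           = "LINE",
  DNA            = "DNA",
  LTR            = "LTR/ERV",
  ERV            = "LTR/ERV",
  `LTR/ERV`      = "LTR/ERV",
  low_complexity = "low_complexity",
  Low_complexity = "low_complexity",
  simple         = "simple",
  Simple_repeat  = "simple",
  satellite      = "satellite",
  Satellite      = "satellite",
  rRNA           = "rRNA_TRNA_EXCLUDED_",
  tRNA           = "rRNA_TRNA_EXCLUDED_"
)
.CLASS_TO_CATEGORY[.CLASS_TO_CATEGORY == "rRNA_TRNA_EXCLUDED_"] <-
  "rRNA_tRNA_excluded"

# Priority tiers: lower number wins contested bases.
# miRNA (0) > piRNA (1) > lncRNA/lincRNA (2) > RepeatMasker repeats (3);
# gene models (protein-coding and remaining noncoding biotypes) sit at 4.
.CLASS_TO_TIER <- c(
  miRNA = 0L, piRNA = 1L, lncRNA = 2L, lincRNA = 2L,
  SINE = 3L, LINE = 3L, DNA = 3L, LTR = 3L, ERV = 3L, `LTR/ERV` = 3L,
  low_complexity = 3L, Low_complexity = 3L, simple = 3L, Simple_repeat = 3L,
  satellite = 3L, Satellite = 3L, rRNA = 3L, tRNA = 3L,
  protein_coding = 4L, pseudogene = 4L, snRNA = 4L, snoRNA = 4L
)

#' Map a feature class label to its reporting category
#'
#' Reads are reported in two large groups: non-repeat transcripts
#' (protein-coding including UTRs/introns, and noncoding: pseudogenes,
#' snRNA, miRNA, lncRNA, piRNA) and repeat transcripts, subdivided into
#' SINE, LINE, DNA, LTR/ERV, low-complexity, simple (microsatellite) and
#' satellite (pericentromeric and centromeric) classes. rRNA and tRNA map
#' to a category that is removed during read filtering; reads outside any
#' feature are `"intergenic"`.
#'
#' @param class_label character vector of feature class labels
#'   (RepeatMasker-style for repeats, biotype-style for genes).
#' @param family_label optional character vector of family labels (e.g.
#'   `"HSAT2"`, `"AluY"`); accepted for interface symmetry, the category
#'   depends only on the class.
#' @return character vector of reporting categories.
#' @examples
#' classify_category("satellite", "HSAT2")
#' classify_category(c("LTR", "tRNA"))
#' @export
classify_category <- function(class_label, family_label = NULL) {
  stopifnot(is.character(class_label))
  unknown <- setdiff(unique(class_label), names(.CLASS_TO_CATEGORY))
  if (length(unknown) > 0L) {
    stop("unknown feature class label(s): ", paste(unknown, collapse = ", "))
  }
  unname(.CLASS_TO_CATEGORY[class_label])
}

#' Reporting category levels and repeat subset
#'
#' @return `category_levels()` returns all reporting categories in display
#'   order; `repeat_categories()` the subset summed in the numerator of the
#'   repeat/mRNA ratio.
#' @export
category_levels <- function() .CATEGORY_LEVELS

#' @rdname category_levels
#' @export
repeat_categories <- function() .REPEAT_CATEGORIES

#' Default priority tier for a feature class
#'
#' Encodes the annotation hierarchy miRNA (0) > piRNA (1) > lncRNA/lincRNA
#' (2) > RepeatMasker repeat classes (3); gene models occupy tier 4.
#'
#' @param class_label character vector of class labels.
#' @return integer vector of tiers (lower = higher priority).
#' @export
default_tier <- function(class_label) {
  unknown <- setdiff(unique(class_label), names(.CLASS_TO_TIER))
  if (length(unknown) > 0L) {
    stop("no default tier for class label(s): ",
         paste(unknown, collapse = ", "))
  }
  unname(.CLASS_TO_TIER[class_label])
}

#' Construct a feature set as a GRanges with class/family/tier metadata
#'
#' Convenience constructor for the labelled genomic intervals the package
#' works with: 0-based half-open coordinates on input are not assumed —
#' this takes standard 1-based closed GRanges-style arguments.
#'
#' @param seqnames,start,end,strand interval coordinates (1-based, closed,
#'   as usual for [GenomicRanges::GRanges]).
#' @param family,class_label character vectors (recycled) of family and
#'   class labels.
#' @param tier integer tier; defaults to [default_tier()] of the class.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a [GenomicRanges::GRanges] with metadata columns `family`,
#'   `class` and `tier`.
#' @export
feature_set <- function(seqnames, start, end, strand = "*", family,
                        class_label, tier = NULL, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqnames,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  n <- length(gr)
  if (is.null(tier)) tier <- default_tier(rep_len(class_label, n))
  S4Vectors::mcols(gr)$family <- rep_len(family, n)
  S4Vectors::mcols(gr)$class <- rep_len(class_label, n)
  S4Vectors::mcols(gr)$tier <- rep_len(as.integer(tier), n)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Parameters for de novo HSAT3 locus calling
#'
#' HSAT3 arrays are built from highly divergent GAATG/CATTC simple
#' repeats; a locus is called from merged runs of exact 5-mer unit matches
#' on either strand when it is longer than `min_length`, has unit purity
#' of at least `min_purity`, and overlaps a pericentromeric window.
#'
#' @param min_length minimum locus length in bp (a locus must be strictly
#'   longer); default 1000.
#' @param max_gap maximum gap (bp) between unit runs merged into one
#'   locus; default 25.
#' @param min_purity minimum fraction of locus bases inside matched units,
#'   in (0, 1]; default 0.8.
#' @param units repeat units recognised; the reverse complement is always
#'   scanned as well.
#' @return a list of class `hsat3_params`.
#' @export
hsat3_params <- function(min_length = 1000L, max_gap = 25L,
                         min_purity = 0.8, units = "GAATG") {
  stopifnot(min_length > 0, max_gap >= 0,
            min_purity > 0, min_purity <= 1)
  structure(
    list(min_length = as.integer(min_length), max_gap = as.integer(max_gap),
         min_purity = min_purity, units = toupper(units)),
    class = "hsat3_params"
  )
}

#' Call HSAT3 satellite loci from genome sequence
#'
#' Scans each chromosome for exact matches of the GAATG unit and its
#' reverse complement CATTC on the forward sequence, merges matches
#' separated by at most `params$max_gap` bp into candidate loci, and
#' retains candidates that are longer than `params$min_length`, have unit
#' purity (matched bases / locus length) of at least `params$min_purity`,
#' and overlap a pericentromeric window by at least 1 bp. Loci covering
#' units from both strands are reported unstranded.
#'
#' @param genome a [Biostrings::DNAStringSet] of chromosome sequences.
#' @param pericentromere a [GenomicRanges::GRanges] of pericentromeric
#'   windows (may be empty, in which case no locus can be called).
#' @param params an [hsat3_params()] object.
#' @return a [GenomicRanges::GRanges] of called loci with metadata columns
#'   `family = "HSAT3"`, `class = "satellite"`, `tier = 3`, and `purity`.
#' @export
call_hsat3_loci <- function(genome, pericentromere = GenomicRanges::GRanges(),
                            params = hsat3_params()) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome))) stop("genome sequences must be named")
  sl <- setNames(Biostrings::width(genome), names(genome))
  out <- GenomicRanges::GRanges(seqlengths = sl)
  patterns <- unique(c(
    params$units,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(params$units)))
  ))
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    hit_ranges <- IRanges::IRanges()
    for (pat in patterns) {
      m <- Biostrings::matchPattern(pat, subject)
      hit_ranges <- c(hit_ranges, methods::as(m, "IRanges"))
    }
    if (length(hit_ranges) == 0L) next
    hits_union <- IRanges::reduce(hit_ranges)
    loci <- IRanges::reduce(hits_union, min.gapwidth = params$max_gap + 1L)
    # unit purity: fraction of locus bases covered by unit matches
    ov <- IRanges::findOverlaps(hits_union, loci)
    ov_w <- IRanges::width(IRanges::pintersect(
      hits_union[S4Vectors::queryHits(ov)], loci[S4Vectors::subjectHits(ov)]
    ))
    matched <- tapply(ov_w, factor(S4Vectors::subjectHits(ov),
                                   levels = seq_along(loci)), sum)
    matched[is.na(matched)] <- 0
    purity <- as.numeric(matched) / IRanges::width(loci)
    keep <- IRanges::width(loci) > params$min_length &
      purity >= params$min_purity
    loci <- loci[keep]
    purity <- purity[keep]
    if (length(loci) == 0L) next
    gr <- GenomicRanges::GRanges(chrom, loci, strand = "*")
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- sl
    S4Vectors::mcols(gr)$family <- "HSAT3"
    S4Vectors::mcols(gr)$class <- "satellite"
    S4Vectors::mcols(gr)$tier <- 3L
    S4Vectors::mcols(gr)$purity <- purity
    out <- c(out, gr)
  }
  if (length(out) == 0L) return(out)
  # pericentromere constraint: >= 1 bp overlap
  if (length(pericentromere) == 0L) return(out[0])
  keep <- IRanges::overlapsAny(out, pericentromere, ignore.strand = TRUE)
  out[keep]
}

#' Resolve overlapping annotations into disjoint per-base ownership
#'
#' Every base covered by at least one feature is assigned to exactly one
#' source feature: the one with the lowest priority tier; within a tier
#' the widest feature wins, remaining ties go to the leftmost start and
#' then the lexicographically smallest family label. The result is a set
#' of disjoint intervals, each carrying the winning feature's labels and a
#' `source` index back into the input; the union of resolved pieces equals
#' the union of the inputs, so no annotated base is lost.
#'
#' @param features a [GenomicRanges::GRanges] with metadata columns
#'   `family`, `class` and `tier` (see [feature_set()]), or a list of such
#'   objects which are concatenated first.
#' @return a `GRanges` of disjoint pieces, sorted, with metadata columns
#'   `family`, `class`, `tier` and `source` (index of the winning input
#'   feature). Resolution ignores strand: ownership is per genomic base.
#' @export
resolve_annotations <- function(features) {
  if (is.list(features) && !methods::is(features, "GRanges")) {
    features <- do.call(c, lapply(features, function(g) {
      mc <- S4Vectors::mcols(g)
      if (!all(c("family", "class", "tier") %in% colnames(mc))) {
        stop("features need 'family', 'class' and 'tier' metadata columns")
      }
      S4Vectors::mcols(g) <- mc[, c("family", "class", "tier")]
      names(g) <- NULL
      g
    }))
  }
  stopifnot(methods::is(features, "GRanges"))
  mc <- S4Vectors::mcols(features)
  if (!all(c("family", "class", "tier") %in% colnames(mc))) {
    stop("features need 'family', 'class' and 'tier' metadata columns")
  }
  classify_category(as.character(mc$class))  # errors on unknown class
  if (length(features) == 0L) return(features)

  pieces <- GenomicRanges::disjoin(features, with.revmap = TRUE,
                                   ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(pieces)$revmap
  # winner per piece: min tier, then max width, then min start, then family
  tier <- as.integer(mc$tier)
  fwidth <- GenomicRanges::width(features)
  fstart <- GenomicRanges::start(features)
  fam <- as.character(mc$family)
  winner <- vapply(seq_along(pieces), function(i) {
    cand <- revmap[[i]]
    o <- order(tier[cand], -fwidth[cand], fstart[cand], fam[cand],
               method = "radix")
    cand[o[1L]]
  }, integer(1))
  # merge adjacent pieces won by the same source feature, so a feature
  # split only by a losing competitor comes back in one piece
  ord <- order(as.integer(GenomeInfoDb::seqnames(pieces)),
               GenomicRanges::start(pieces))
  pieces <- pieces[ord]
  winner <- winner[ord]
  chr <- as.character(GenomeInfoDb::seqnames(pieces))
  st <- GenomicRanges::start(pieces)
  en <- GenomicRanges::end(pieces)
  n <- length(pieces)
  new_group <- c(TRUE, winner[-1L] != winner[-n] |
                   chr[-1L] != chr[-n] | st[-1L] != en[-n] + 1L)
  grp <- cumsum(new_group)
  g_first <- which(new_group)
  g_start <- st[g_first]
  g_end <- vapply(split(en, grp), max, numeric(1))
  g_winner <- winner[g_first]
  out <- GenomicRanges::GRanges(
    chr[g_first], IRanges::IRanges(g_start, g_end),
    strand = GenomicRanges::strand(features)[g_winner]
  )
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(features)
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(features)
  S4Vectors::mcols(out)$family <- fam[g_winner]
  S4Vectors::mcols(out)$class <- as.character(mc$class)[g_winner]
  S4Vectors::mcols(out)$tier <- tier[g_winner]
  S4Vectors::mcols(out)$source <- g_winner
  GenomicRanges::sort(out, ignore.strand = TRUE)
}
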