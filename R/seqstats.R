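# Pathogen-likeness sequence statistics: AU/GC skew and CpG/UpA
# dinucleotide observed/expected usage. RNA is treated in DNA alphabet
# internally (U read as T); ambiguity codes (N etc.) are excluded from
# all counts.

.base_counts <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single nonempty string")
  }
  s <- chartr("u", "U", toupper(sequence))
  s <- chartr("U", "T", s)
  ct <- Biostrings::letterFrequency(Biostrings::BString(s),
                                    letters = c("A", "C", "G", "T"))
  setNames(as.numeric(ct), c("A", "C", "G", "T"))
}

#' AU skew of a sequence
#'
#' (A - U) / (A + U) over the sequence's A and U (or T) counts; a value
#' in \[-1, 1\] measuring strand compositional asymmetry. `NA` when the
#' sequence contains no A or U.
#'
#' @param sequence a single nucleotide string (DNA or RNA alphabet).
#' @return numeric scalar in \[-1, 1\], or `NA` if A + U = 0.
#' @examples
#' au_skew("GGAAU")  # (2 - 1) / (2 + 1)
#' @export
au_skew <- function(sequence) {
  ct <- .base_counts(sequence)
  denom <- ct[["A"]] + ct[["T"]]
  if (denom == 0) return(NA_real_)
  (ct[["A"]] - ct[["T"]]) / denom
}

#' GC skew of a sequence
#'
#' (G - C) / (G + C); `NA` when the sequence contains no G or C.
#'
#' @inheritParams au_skew
#' @return numeric scalar in \[-1, 1\], or `NA` if G + C = 0.
#' @examples
#' gc_skew("GGAAU")  # (2 - 0) / (2 + 0)
#' @export
gc_skew <- function(sequence) {
  ct <- .base_counts(sequence)
  denom <- ct[["G"]] + ct[["C"]]
  if (denom == 0) return(NA_real_)
  (ct[["G"]] - ct[["C"]]) / denom
}

#' Dinucleotide observed/expected usage (Karlin-style odds ratio)
#'
#' o/e = \[count(XpY) / (L - 1)\] / \[(count(X)/L) x (count(Y)/L)\],
#' counting XpY over the L - 1 overlapping linear windows. Values below 1
#' indicate depletion (e.g. CpG suppression in vertebrate mRNA); HSAT
#' RNAs show pathogen-like CpG/UpA usage. Ambiguous bases are excluded
#' from the counts (L is the number of unambiguous bases; windows
#' containing an ambiguous base are not counted).
#'
#' @inheritParams au_skew
#' @param dinucleotide two-letter string such as `"CG"` (CpG) or `"TA"`
#'   (UpA; `U` accepted).
#' @return the o/e ratio (>= 0), or `NA` when either mononucleotide is
#'   absent.
#' @examples
#' dinucleotide_oe("CGCGCG", "CG")  # (3/5) / (0.5 * 0.5) = 2.4
#' @export
dinucleotide_oe <- function(sequence, dinucleotide = "CG") {
  din <- chartr("Uu", "TT", toupper(dinucleotide))
  if (nchar(din) != 2L || !all(strsplit(din, "")[[1]] %in%
                               c("A", "C", "G", "T"))) {
    stop("dinucleotide must be two bases over A/C/G/T (U read as T)")
  }
  ct <- .base_counts(sequence)
  len <- sum(ct)
  if (len < 2L) stop("sequence must contain at least 2 unambiguous bases")
  s <- chartr("Uu", "TT", toupper(sequence))
  obs <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(
    gsub("[^ACGT]", "N", s)))[[din]]
  x <- substr(din, 1L, 1L)
  y <- substr(din, 2L, 2L)
  if (ct[[x]] == 0 || ct[[y]] == 0) return(NA_real_)
  (obs / (len - 1)) / ((ct[[x]] / len) * (ct[[y]] / len))
}

#' Per-sequence skew profiles with per-group summaries
#'
#' Computes AU skew, GC skew and the requested dinucleotide o/e ratios
#' for each sequence, flags sequences that are more than half ambiguous
#' bases, and summarises each group by median and IQR of every statistic
#' — the comparison used to contrast satellite RNAs with the coding
#' transcriptome.
#'
#' @param sequences named character vector or
#'   [Biostrings::DNAStringSet]/`RNAStringSet`.
#' @param groups character vector of group labels, one per sequence
#'   (default: one group `"all"`).
#' @param dinucleotides dinucleotides to profile (default CpG and UpA).
#' @return list of class `skew_table`: `profiles` (one row per sequence:
#'   id, group, length, skews, o/e ratios, `flag_ambiguous`) and
#'   `summary` (per group and statistic: n, median, IQR).
#' @export
skew_table <- function(sequences, groups = NULL,
                       dinucleotides = c("CG", "TA")) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%04d", seq_along(sequences))
  }
  if (is.null(groups)) groups <- rep("all", length(sequences))
  stopifnot(length(groups) == length(sequences))
  n_unamb <- vapply(sequences, function(s) sum(.base_counts(s)), numeric(1))
  profiles <- data.frame(
    id = names(sequences), group = groups,
    length = nchar(sequences),
    au_skew = vapply(sequences, au_skew, numeric(1)),
    gc_skew = vapply(sequences, gc_skew, numeric(1)),
    flag_ambiguous = n_unamb < 0.5 * nchar(sequences),
    row.names = NULL, stringsAsFactors = FALSE
  )
  for (din in dinucleotides) {
    cn <- paste0("oe_", chartr("T", "U", din))
    profiles[[cn]] <- vapply(sequences, dinucleotide_oe, numeric(1),
                             dinucleotide = din)
  }
  stat_cols <- setdiff(names(profiles),
                       c("id", "group", "length", "flag_ambiguous"))
  summ <- do.call(rbind, lapply(split(profiles, profiles$group),
                                function(gdf) {
    do.call(rbind, lapply(stat_cols, function(cc) {
      v <- gdf[[cc]]
      data.frame(group = gdf$group[1L], statistic = cc,
                 n = sum(!is.na(v)),
                 median = median(v, na.rm = TRUE),
                 iqr = unname(diff(quantile(v, c(0.25, 0.75),
                                            na.rm = TRUE))),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(profiles = profiles, summary = summ),
            class = "skew_table")
}
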