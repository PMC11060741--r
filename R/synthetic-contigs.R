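# Simulated ChIP contigs: substrings of satellite arrays with point
# mutations, in a ChIP-like condition drawn preferentially from bound
# loci and an input-like condition drawn uniformly.

#' Configuration for the ChIP contig simulator
#'
#' @param source_loci [GenomicRanges::GRanges] of satellite array loci
#'   contigs are sampled from (must be nonempty).
#' @param bound_loci indices into `source_loci` of the loci the factor is
#'   bound to; ChIP-like contigs are drawn from these preferentially.
#' @param bound_weight sampling-weight multiplier applied to bound loci
#'   in the ChIP condition (input is uniform by width).
#' @param n_chip,n_input contigs per condition.
#' @param min_length,max_length contig length bounds (nt); lengths are
#'   uniform on the interval (and capped at the source locus width).
#' @param subst_chip,subst_input per-condition substitution rates.
#' @param seed integer seed.
#' @return a list of class `contig_sim_config`.
#' @export
contig_sim_config <- function(source_loci, bound_loci = seq_along(source_loci),
                              bound_weight = 5, n_chip = 30L, n_input = 30L,
                              min_length = 200L, max_length = 700L,
                              subst_chip = 0.01, subst_input = 0.01,
                              seed = 1L) {
  if (length(source_loci) == 0L) stop("source_loci must be nonempty")
  if (min_length <= 0 || max_length <= 0 || min_length > max_length) {
    stop("contig length bounds must be positive with min <= max")
  }
  stopifnot(all(bound_loci %in% seq_along(source_loci)),
            subst_chip >= 0, subst_chip <= 0.5,
            subst_input >= 0, subst_input <= 0.5)
  structure(
    list(source_loci = source_loci, bound_loci = as.integer(bound_loci),
         bound_weight = bound_weight, n_chip = as.integer(n_chip),
         n_input = as.integer(n_input), min_length = as.integer(min_length),
         max_length = as.integer(max_length), subst_chip = subst_chip,
         subst_input = subst_input, seed = as.integer(seed)),
    class = "contig_sim_config"
  )
}

#' Simulate ChIP-like and input-like contig sets from satellite loci
#'
#' Each contig is a substring of a source locus (length uniform on the
#' configured bounds, orientation random) diverged at the condition's
#' substitution rate. ChIP-like contigs sample loci with probability
#' proportional to width times `bound_weight` at bound loci; input-like
#' contigs sample proportionally to width alone.
#'
#' @param sim a `sim_genome` (or a list with a `genome` DNAStringSet).
#' @param config a [contig_sim_config()].
#' @return list of class `sim_contigs`: `chip` and `input`
#'   ([Biostrings::DNAStringSet]) and `truth` (data.frame: contig id,
#'   condition, source locus index and coordinates, strand, substitution
#'   count).
#' @export
simulate_chip_contigs <- function(sim, config) {
  stopifnot(inherits(config, "contig_sim_config"))
  genome <- sim$genome
  loci <- config$source_loci
  if (any(GenomicRanges::width(loci) < config$min_length)) {
    stop("every source locus must be at least min_length wide")
  }
  .with_seed(config$seed + 2L, {
    draw_condition <- function(n, weights, rate, prefix) {
      if (n == 0L) {
        return(list(
          seqs = setNames(character(0), character(0)),
          truth = data.frame(contig_id = character(0),
                             condition = character(0), locus = integer(0),
                             chrom = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             n_substitutions = integer(0),
                             stringsAsFactors = FALSE)))
      }
      j <- sample.int(length(loci), n, replace = TRUE,
                      prob = weights / sum(weights))
      len <- config$min_length +
        floor(runif(n) * (config$max_length - config$min_length + 1L))
      len <- pmin(len, GenomicRanges::width(loci)[j])
      s <- GenomicRanges::start(loci)[j] +
        floor(runif(n) * (GenomicRanges::width(loci)[j] - len + 1L))
      chrom <- as.character(GenomeInfoDb::seqnames(loci))[j]
      revc <- runif(n) < 0.5
      seqs <- character(n)
      nsub <- integer(n)
      for (i in seq_len(n)) {
        sq <- as.character(Biostrings::subseq(genome[[chrom[i]]],
                                              start = s[i],
                                              width = len[i]))
        sq <- mutate_sequence(sq, rate)
        nsub[i] <- length(attr(sq, "positions"))
        sq <- as.character(sq)
        if (revc[i]) {
          sq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(sq)))
        }
        seqs[i] <- sq
      }
      list(
        seqs = setNames(seqs, sprintf("%s_%04d", prefix, seq_len(n))),
        truth = data.frame(
          contig_id = sprintf("%s_%04d", prefix, seq_len(n)),
          condition = prefix, locus = j, chrom = chrom,
          start = as.integer(s), end = as.integer(s + len - 1L),
          strand = ifelse(revc, "-", "+"), n_substitutions = nsub,
          stringsAsFactors = FALSE
        )
      )
    }
    w_chip <- GenomicRanges::width(loci) *
      ifelse(seq_along(loci) %in% config$bound_loci, config$bound_weight, 1)
    w_input <- GenomicRanges::width(loci)
    chip <- draw_condition(config$n_chip, w_chip, config$subst_chip, "chip")
    input <- draw_condition(config$n_input, w_input, config$subst_input,
                            "input")
    structure(
      list(chip = Biostrings::DNAStringSet(chip$seqs),
           input = Biostrings::DNAStringSet(input$seqs),
           truth = rbind(chip$truth, input$truth)),
      class = "sim_contigs"
    )
  })
}
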