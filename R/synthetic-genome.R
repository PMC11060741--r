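# Synthetic genome generator: toy chromosomes with planted satellite
# arrays (HSAT2 24-mer consensus, HSAT3 GAATG/CATTC simple repeats, ALR
# monomers), retroelements and gene models, with per-element divergence
# and a truth table of exact planted coordinates.

# Run expr with a private, seeded RNG stream; the caller's stream is
# untouched. Every simulate_* operation uses seed + a fixed offset so
# adding one operation never perturbs another's draws.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Apply random base substitutions to a sequence
#'
#' The documented substitution process used by all simulators: one
#' `runif()` draw per base decides whether it is substituted (probability
#' `rate`), then each substituted base receives one of the three other
#' bases, chosen uniformly. Draw order is strictly left to right, so the
#' process can be replayed to verify mutation counts and positions.
#'
#' @param sequence a single character string over A/C/G/T.
#' @param rate per-base substitution probability in \[0, 0.5\].
#' @return the mutated string with attribute `positions`: the 1-based
#'   positions that were substituted.
#' @export
mutate_sequence <- function(sequence, rate) {
  stopifnot(length(sequence) == 1L, rate >= 0, rate <= 0.5)
  if (rate == 0) return(structure(sequence, positions = integer(0)))
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(bases)) < rate
  pos <- which(hit)
  for (i in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), bases[i])
    bases[i] <- alt[sample.int(3L, 1L)]
  }
  structure(paste(bases, collapse = ""), positions = pos)
}

#' Configuration for the synthetic genome
#'
#' Describes a toy genome: chromosome lengths, pericentromeric windows
#' and a table of planted elements. Each element is a tandem array (or
#' single copy) of a consensus unit, optionally diverged by per-base
#' substitution, placed either at an explicit start or randomly
#' inside/outside the pericentromere.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param pericentromere [GenomicRanges::GRanges] of pericentromeric
#'   windows (possibly empty).
#' @param elements data.frame with columns `name`, `class`, `family`,
#'   `unit` (consensus sequence), `copies` (tandem copy number), and
#'   optionally `chrom`, `start` (1-based; `NA` for random placement),
#'   `strand` (default `"+"`), `location` (`"inside"`/`"outside"` the
#'   pericentromere, used when `start` is `NA`; default `"outside"`),
#'   `subst_rate` (default 0).
#' @param seed integer random seed; identical config + seed gives
#'   byte-identical outputs.
#' @return a list of class `sim_genome_config`.
#' @export
sim_genome_config <- function(chrom_lengths, pericentromere, elements, seed) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0), is.data.frame(elements))
  req <- c("name", "class", "family", "unit", "copies")
  missing_cols <- setdiff(req, names(elements))
  if (length(missing_cols) > 0L) {
    stop("elements is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  el <- elements
  n <- nrow(el)
  if (is.null(el$chrom)) el$chrom <- NA_character_
  if (is.null(el$start)) el$start <- NA_integer_
  if (is.null(el$strand)) el$strand <- "+"
  if (is.null(el$location)) el$location <- "outside"
  if (is.null(el$subst_rate)) el$subst_rate <- 0
  if (any(el$subst_rate < 0 | el$subst_rate > 0.5)) {
    stop("substitution rates must lie in [0, 0.5]")
  }
  el$length <- nchar(el$unit) * as.integer(el$copies)
  placed <- !is.na(el$start)
  if (any(placed)) {
    bad <- placed & (el$start < 1 |
      el$start + el$length - 1 > chrom_lengths[el$chrom])
    if (any(bad)) {
      stop("planted element(s) exceed chromosome bounds: ",
           paste(el$name[bad], collapse = ", "))
    }
  }
  structure(
    list(chrom_lengths = setNames(as.integer(chrom_lengths),
                                  names(chrom_lengths)),
         pericentromere = pericentromere,
         elements = el, seed = as.integer(seed)),
    class = "sim_genome_config"
  )
}

# Sample a start position for an element of given length, inside or
# outside the pericentromeric windows of a chromosome, avoiding occupied
# ranges. Returns NA after max_tries failures.
.place_element <- function(len, chrom_len, peri, occupied, location,
                           max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    if (location == "inside" && length(peri) > 0L) {
      w <- peri[sample.int(length(peri), 1L)]
      lo <- IRanges::start(w)
      hi <- IRanges::end(w) - len + 1L
      if (hi < lo) next
      s <- lo + floor(runif(1) * (hi - lo + 1L))
    } else {
      s <- 1L + floor(runif(1) * (chrom_len - len + 1L))
    }
    cand <- IRanges::IRanges(s, width = len)
    if (location == "outside" && length(peri) > 0L &&
        any(IRanges::overlapsAny(cand, peri))) next
    if (location == "inside" && length(peri) > 0L &&
        !any(IRanges::overlapsAny(cand, peri))) next
    if (length(occupied) > 0L && any(IRanges::overlapsAny(cand, occupied))) next
    return(as.integer(s))
  }
  NA_integer_
}

#' Simulate a genome with planted repeat and gene features
#'
#' Builds random-background chromosomes, plants each configured element
#' (tandem unit array, diverged at its substitution rate), and returns
#' the sequences together with a feature annotation and a truth table of
#' exact planted coordinates. Placement, background and divergence all
#' draw from one RNG stream seeded at `config$seed`, so identical configs
#' give byte-identical output.
#'
#' @param config a [sim_genome_config()].
#' @return a list of class `sim_genome` with elements `genome`
#'   ([Biostrings::DNAStringSet]), `annotation` (a [feature_set()]-style
#'   `GRanges` with `family`/`class`/`tier`), `truth` (data.frame with
#'   one row per planted element: coordinates, labels, copy number, unit,
#'   substitution count and positions), and `pericentromere`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_genome_config"))
  .with_seed(config$seed + 0L, {
    cl <- config$chrom_lengths
    seqs <- lapply(cl, .random_dna)
    el <- config$elements
    peri <- config$pericentromere
    occupied <- GenomicRanges::GRanges(seqlengths = cl)

    # explicit placements first, then random ones
    ord <- order(is.na(el$start))
    el <- el[ord, , drop = FALSE]
    starts <- el$start
    chroms <- el$chrom
    nsub <- integer(nrow(el))
    subpos <- vector("list", nrow(el))
    for (i in seq_len(nrow(el))) {
      len <- el$length[i]
      if (is.na(chroms[i])) {
        # choose among chromosomes that can host the element
        cand <- names(cl)[cl >= len]
        if (el$location[i] == "inside") {
          cand <- intersect(cand, unique(as.character(
            GenomeInfoDb::seqnames(peri))))
        }
        if (length(cand) == 0L) {
          stop("no chromosome can host element '", el$name[i], "'")
        }
        chroms[i] <- cand[sample.int(length(cand), 1L)]
      }
      if (is.na(starts[i])) {
        peri_i <- peri[as.character(GenomeInfoDb::seqnames(peri)) == chroms[i]]
        occ_i <- IRanges::ranges(occupied[
          as.character(GenomeInfoDb::seqnames(occupied)) == chroms[i]])
        starts[i] <- .place_element(len, cl[[chroms[i]]],
                                    IRanges::ranges(peri_i), occ_i,
                                    el$location[i])
        if (is.na(starts[i])) {
          stop("could not place element '", el$name[i],
               "' without overlap; reduce element sizes or lengthen ",
               "the chromosome")
        }
      }
      occupied <- c(occupied, GenomicRanges::GRanges(
        chroms[i], IRanges::IRanges(starts[i], width = len),
        strand = el$strand[i]))
      # build, diverge, and write the array into the chromosome
      arr <- strrep(el$unit[i], el$copies[i])
      arr <- mutate_sequence(arr, el$subst_rate[i])
      nsub[i] <- length(attr(arr, "positions"))
      subpos[[i]] <- attr(arr, "positions")
      if (el$strand[i] == "-") {
        arr <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(as.character(arr))))
      }
      s <- seqs[[chroms[i]]]
      substr(s, starts[i], starts[i] + len - 1L) <- as.character(arr)
      seqs[[chroms[i]]] <- s
    }

    # collision check on explicit placements: same strand, same tier
    tier <- default_tier(el$class)
    hits <- GenomicRanges::findOverlaps(occupied, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) > 0L) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      same <- tier[q] == tier[s] &
        as.character(GenomicRanges::strand(occupied))[q] ==
          as.character(GenomicRanges::strand(occupied))[s]
      if (any(same)) {
        i <- which(same)[1L]
        stop("planted elements overlap on the same strand and tier: '",
             el$name[q[i]], "' and '", el$name[s[i]], "'")
      }
    }

    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(cl)
    annotation <- feature_set(
      seqnames = chroms, start = starts, end = starts + el$length - 1L,
      strand = el$strand, family = el$family, class_label = el$class,
      tier = tier, seqlengths = cl
    )
    names(annotation) <- el$name
    truth <- data.frame(
      name = el$name, chrom = chroms, start = starts,
      end = starts + el$length - 1L, strand = el$strand,
      class = el$class, family = el$family, copies = el$copies,
      unit = el$unit, subst_rate = el$subst_rate, n_substitutions = nsub,
      stringsAsFactors = FALSE
    )
    truth$subst_positions <- subpos
    structure(
      list(genome = genome, annotation = annotation, truth = truth,
           pericentromere = config$pericentromere),
      class = "sim_genome"
    )
  })
}

# Synthetic consensus units for the example genome. The HSAT3 unit is the
# genuine GAATG simple-repeat unit; the HSAT2 24-mer and the ALR-like
# 171-mer are synthetic stand-ins with the right length and GGAAT-richness
# (HSAT2) but arbitrary divergent positions.
.HSAT3_UNIT <- "GAATG"
.HSAT2_UNIT_SYNTH <- "GGAATGGAATCGAGTACGTCGGAA"

#' Example synthetic genome configuration
#'
#' A ready-made two-chromosome toy genome emulating the genomic structure
#' the pipeline targets: pericentromeric windows hosting HSAT3 GAATG
#' simple-repeat arrays (divergent), HSAT2-like 24-mer consensus arrays
#' and ALR-like monomer arrays, with protein-coding genes, noncoding
#' genes (lncRNA, miRNA, piRNA, pseudogene, snRNA), LINE/SINE/LTR/DNA
#' retroelements, simple and low-complexity repeats, and rRNA/tRNA genes
#' on the chromosome arms. All placements are explicit so the layout is
#' identical across seeds; the seed controls background sequence and
#' element divergence only.
#'
#' @param seed integer seed passed through to [sim_genome_config()].
#' @return a `sim_genome_config`.
#' @export
example_genome_config <- function(seed = 1L) {
  cl <- c(chr1 = 200000L, chr2 = 150000L)
  peri <- GenomicRanges::GRanges(
    c("chr1", "chr2"),
    IRanges::IRanges(start = c(80001L, 60001L), end = c(130000L, 100000L))
  )
  # units for the non-satellite element families: fixed synthetic
  # consensi drawn once from a dedicated stream so they do not depend on
  # the genome seed
  units <- .with_seed(990001L, list(
    line = .random_dna(1200L), sine = .random_dna(300L),
    ltr = .random_dna(500L), dna = .random_dna(300L),
    alr = .random_dna(171L),
    gene1 = .random_dna(3000L), gene2 = .random_dna(3000L),
    gene3 = .random_dna(3000L), lnc = .random_dna(2000L),
    mir = .random_dna(22L), pir = .random_dna(30L),
    pseudo = .random_dna(1000L), snrna = .random_dna(150L),
    rrna = .random_dna(500L), trna = .random_dna(80L)
  ))
  elements <- rbind(
    data.frame(name = "HSAT3_chr1", class = "satellite", family = "HSAT3",
               unit = .HSAT3_UNIT, copies = 1000L, chrom = "chr1",
               start = 85001L, subst_rate = 0.02),
    data.frame(name = "HSAT2_chr1", class = "satellite", family = "HSAT2",
               unit = .HSAT2_UNIT_SYNTH, copies = 150L, chrom = "chr1",
               start = 95001L, subst_rate = 0.03),
    data.frame(name = "ALR_chr1", class = "satellite", family = "ALR",
               unit = units$alr, copies = 20L, chrom = "chr1",
               start = 100001L, subst_rate = 0.05),
    data.frame(name = "HSAT3_chr2", class = "satellite", family = "HSAT3",
               unit = .HSAT3_UNIT, copies = 400L, chrom = "chr2",
               start = 65001L, subst_rate = 0.03),
    data.frame(name = "HSAT2_chr2", class = "satellite", family = "HSAT2",
               unit = .HSAT2_UNIT_SYNTH, copies = 100L, chrom = "chr2",
               start = 70001L, subst_rate = 0.05),
    data.frame(name = "GENE1", class = "protein_coding", family = "GENE1",
               unit = units$gene1, copies = 1L, chrom = "chr1",
               start = 5001L, subst_rate = 0),
    data.frame(name = "GENE2", class = "protein_coding", family = "GENE2",
               unit = units$gene2, copies = 1L, chrom = "chr1",
               start = 20001L, subst_rate = 0),
    data.frame(name = "GENE3", class = "protein_coding", family = "GENE3",
               unit = units$gene3, copies = 1L, chrom = "chr2",
               start = 10001L, subst_rate = 0),
    data.frame(name = "LNC1", class = "lncRNA", family = "LNC1",
               unit = units$lnc, copies = 1L, chrom = "chr1",
               start = 30001L, subst_rate = 0),
    data.frame(name = "MIR1", class = "miRNA", family = "MIR1",
               unit = units$mir, copies = 1L, chrom = "chr1",
               start = 35001L, subst_rate = 0),
    data.frame(name = "PIR1", class = "piRNA", family = "PIR1",
               unit = units$pir, copies = 1L, chrom = "chr1",
               start = 37001L, subst_rate = 0),
    data.frame(name = "PSEUDO1", class = "pseudogene", family = "PSEUDO1",
               unit = units$pseudo, copies = 1L, chrom = "chr1",
               start = 74001L, subst_rate = 0),
    data.frame(name = "SNRNA1", class = "snRNA", family = "SNRNA1",
               unit = units$snrna, copies = 1L, chrom = "chr1",
               start = 76001L, subst_rate = 0),
    data.frame(name = "L1_chr1", class = "LINE", family = "L1",
               unit = units$line, copies = 1L, chrom = "chr1",
               start = 45001L, subst_rate = 0.05),
    data.frame(name = "L1_chr2", class = "LINE", family = "L1",
               unit = units$line, copies = 1L, chrom = "chr2",
               start = 20001L, subst_rate = 0.08),
    data.frame(name = "Alu_chr1", class = "SINE", family = "AluY",
               unit = units$sine, copies = 1L, chrom = "chr1",
               start = 40001L, subst_rate = 0.05),
    data.frame(name = "Alu_chr2", class = "SINE", family = "AluY",
               unit = units$sine, copies = 1L, chrom = "chr2",
               start = 25001L, subst_rate = 0.08),
    data.frame(name = "HERVK_chr1", class = "LTR", family = "HERVK",
               unit = units$ltr, copies = 1L, chrom = "chr1",
               start = 50001L, subst_rate = 0.05),
    data.frame(name = "DNA_chr1", class = "DNA", family = "Tigger1",
               unit = units$dna, copies = 1L, chrom = "chr1",
               start = 55001L, subst_rate = 0.05),
    data.frame(name = "CA_rep", class = "simple", family = "(CA)n",
               unit = "CA", copies = 250L, chrom = "chr1",
               start = 60001L, subst_rate = 0.02),
    data.frame(name = "Arich", class = "low_complexity", family = "A-rich",
               unit = "AAAAAAAAAT", copies = 40L, chrom = "chr1",
               start = 62001L, subst_rate = 0.02),
    data.frame(name = "RRNA1", class = "rRNA", family = "RRNA1",
               unit = units$rrna, copies = 1L, chrom = "chr1",
               start = 70001L, subst_rate = 0),
    data.frame(name = "TRNA1", class = "tRNA", family = "TRNA1",
               unit = units$trna, copies = 1L, chrom = "chr1",
               start = 72001L, subst_rate = 0)
  )
  sim_genome_config(cl, peri, elements, seed = seed)
}
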