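# Contig length filtering, motif alignment against the exhaustive
# placement oracle, locus assignment, enrichment, recurring k-mers and
# peak-repeat overlap counting.

test_that("contig length filter keeps the inclusive 200-700 window", {
  lens <- c(150L, 199L, 200L, 450L, 700L, 701L)
  contigs <- Biostrings::DNAStringSet(setNames(
    vapply(lens, function(n) strrep("A", n), character(1)),
    paste0("c", lens)))
  kept <- filter_contigs(contigs)
  expect_equal(names(kept), c("c200", "c450", "c700"))
  # idempotent
  expect_identical(as.character(filter_contigs(kept)), as.character(kept))
  expect_error(filter_contigs(contigs, min_len = 500L, max_len = 200L),
               "min_len")
})

test_that("motif identity threshold admits at most one mismatch per
           24-mer", {
  motif <- substr(strrep("GAATG", 5L), 1L, 24L)
  lib <- motif_library(c(M1 = motif), family = "HSAT3")
  exact <- Biostrings::DNAStringSet(c(e1 = paste0("CCCC", motif, "TTTT")))
  h <- align_to_motifs(exact, lib)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  one_mm <- motif
  substr(one_mm, 10L, 10L) <- "C"
  h1 <- align_to_motifs(Biostrings::DNAStringSet(c(m1 = one_mm)), lib)
  expect_equal(h1$identity, 23 / 24)
  expect_equal(nrow(h1), 1L)
  two_mm <- one_mm
  substr(two_mm, 20L, 20L) <- "C"
  h2 <- align_to_motifs(Biostrings::DNAStringSet(c(m2 = two_mm)), lib)
  expect_equal(nrow(h2), 0L)
  # contig shorter than the motif yields no placement, not an error
  short <- Biostrings::DNAStringSet(c(s1 = "GAATGGAATG"))
  expect_equal(nrow(align_to_motifs(short, lib)), 0L)
})

test_that("hit sets match the exhaustive placement oracle on random
           contigs", {
  set.seed(61)
  motifs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE), collapse = "")
  }, character(1))
  lib <- motif_library(setNames(motifs, paste0("m", 1:5)),
                       family = rep("HSAT3", 5L))
  contigs <- Biostrings::DNAStringSet(setNames(vapply(1:20, function(i) {
    base <- paste(sample(c("A", "C", "G", "T"), 60L, replace = TRUE),
                  collapse = "")
    # plant a copy of a random motif (sometimes mutated) in some contigs
    if (i %% 2L == 0L) {
      m <- motifs[sample.int(5L, 1L)]
      if (i %% 4L == 0L) substr(m, 3L, 3L) <- "A"
      substr(base, 20L, 19L + nchar(m)) <- m
    }
    base
  }, character(1)), paste0("c", 1:20)))
  hits <- align_to_motifs(contigs, lib, min_identity = 0.9)
  oracle <- oracle_motif_hits(contigs, lib, min_identity = 0.9)
  key <- function(df) {
    df <- df[order(df$contig_id, df$motif_id), ]
    paste(df$contig_id, df$motif_id, round(df$identity, 10))
  }
  expect_equal(key(hits), key(oracle))
})

test_that("motif alignment is strand-symmetric", {
  set.seed(71)
  lib <- hsat_motif_library_synthetic()
  sim <- tiny_hsat3_genome(copies = 400L)
  locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001L, 22000L))
  ct <- simulate_chip_contigs(sim, contig_sim_config(
    locus, n_chip = 10L, n_input = 0L, min_length = 200L,
    max_length = 300L, subst_chip = 0.01, seed = 3L))
  hits_fwd <- align_to_motifs(ct$chip, lib)
  rc <- Biostrings::reverseComplement(ct$chip)
  names(rc) <- names(ct$chip)
  hits_rc <- align_to_motifs(rc, lib)
  key <- function(df) {
    df <- df[order(df$contig_id, df$motif_id), ]
    paste(df$contig_id, df$motif_id, round(df$identity, 10))
  }
  expect_equal(key(hits_fwd), key(hits_rc))
  # strands flip
  m <- merge(hits_fwd, hits_rc, by = c("contig_id", "motif_id"))
  expect_true(all(m$strand.x != m$strand.y))
})

test_that("contigs are assigned to their source locus; ambiguous matches
           break ties leftmost", {
  sim <- tiny_hsat3_genome(copies = 400L, subst = 0.02, seed = 13L)
  loci <- call_hsat3_loci(sim$genome, sim$pericentromere)
  lib <- hsat_motif_library_synthetic()
  ct <- simulate_chip_contigs(sim, contig_sim_config(
    loci, n_chip = 12L, n_input = 0L, subst_chip = 0.01, seed = 19L))
  hits <- align_to_motifs(ct$chip, lib)
  asgn <- assign_contig_loci(hits, ct$chip, loci, sim$genome)
  tr <- ct$truth$locus[match(asgn$assignments$contig_id,
                             ct$truth$contig_id)]
  ok <- !is.na(asgn$assignments$locus)
  expect_true(all(asgn$assignments$locus[ok] == tr[ok]))

  # two identical planted arrays: a verbatim contig matches both; the
  # leftmost locus wins and the tie is recorded
  el <- rbind(
    data.frame(name = "arrA", class = "satellite", family = "HSAT3",
               unit = "GAATG", copies = 300L, chrom = "chr1",
               start = 5001L, subst_rate = 0),
    data.frame(name = "arrB", class = "satellite", family = "HSAT3",
               unit = "GAATG", copies = 300L, chrom = "chr1",
               start = 20001L, subst_rate = 0)
  )
  cfg <- sim_genome_config(
    c(chr1 = 40000L),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 40000L)),
    el, seed = 5L)
  sim2 <- simulate_genome(cfg)
  loci2 <- call_hsat3_loci(sim2$genome, sim2$pericentromere)
  expect_equal(length(loci2), 2L)
  contig <- Biostrings::DNAStringSet(c(amb = strrep("GAATG", 50L)))
  hits2 <- align_to_motifs(contig, lib)
  asgn2 <- assign_contig_loci(hits2, contig, loci2, sim2$genome)
  expect_equal(asgn2$assignments$locus, 1L)
  expect_true(asgn2$assignments$tie)

  # a contig matching nowhere near threshold stays unassigned
  junk <- Biostrings::DNAStringSet(c(j = paste0(
    strrep("GAATG", 5L),
    paste(rep(c("C", "T", "A", "G"), 60L), collapse = ""))))
  hits3 <- align_to_motifs(junk, lib)
  expect_gt(nrow(hits3), 0L)  # carries a motif copy
  asgn3 <- assign_contig_loci(hits3, junk, loci2, sim2$genome)
  expect_equal(asgn3$unassigned, "j")
})

test_that("enrichment test reduces to the exact rank-sum", {
  expect_equal(enrichment_test(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(enrichment_test(rep(4, 3), rep(4, 3))$p_value, 1)
  expect_error(enrichment_test(numeric(0), 1), "locus")
})

test_that("a 5-fold ChIP enrichment at 20 loci is detected in at least
           95% of seeded replicates", {
  set.seed(91)
  rejected <- vapply(seq_len(1000L), function(i) {
    input <- rpois(20L, 3)
    chip <- rpois(20L, 15)   # counts x5 at the bound loci
    enrichment_test(chip, input)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("recurring motif scoring counts distinct contigs with declared
           tie-breaking", {
  # contigs from a pure GAATG array: the reported 9-mer is in the top tie
  contigs <- Biostrings::DNAStringSet(c(
    a = strrep("GAATG", 60L), b = strrep("GAATG", 50L),
    c = strrep("GAATG", 40L)))
  rm_ <- recurring_motif(contigs, k = 9L)
  top <- rm_[rm_$score == rm_$score[1L], ]
  expect_true("GAATGGAAT" %in% c(top$motif, top$motif_rc))
  expect_equal(rm_$score[1L], 3L)

  # single homopolymer contig
  mono <- recurring_motif(Biostrings::DNAStringSet(c(x = strrep("A", 100L))),
                          k = 9L)
  expect_equal(mono$motif[1L], strrep("A", 9L))
  expect_equal(mono$score[1L], 1L)

  # ranking equals the exhaustive tally oracle (no strand collapse)
  set.seed(81)
  rnd <- Biostrings::DNAStringSet(setNames(vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 40L, replace = TRUE), collapse = "")
  }, character(1)), paste0("r", 1:20)))
  mine <- recurring_motif(rnd, k = 6L, strand_collapse = FALSE, top = Inf)
  oracle <- oracle_kmer_ranking(as.character(rnd), k = 6L)
  expect_equal(mine$motif, oracle$motif)
  expect_equal(mine$score, oracle$score)
  expect_equal(mine$occurrences, oracle$occurrences)
  # score never exceeds the number of contigs
  expect_true(all(mine$score <= 20L))
  expect_error(recurring_motif(rnd, k = 3L), "at least 4")
  expect_error(recurring_motif(
    Biostrings::DNAStringSet(c(s = "ACGT")), k = 9L), "larger")
})

test_that("peak-repeat overlap counting is strict on score and counts a
           peak once per family", {
  repeats <- feature_set("chr1", c(100L, 300L, 1000L),
                         c(400L, 600L, 1200L),
                         family = c("HSAT2", "HSAT3", "ALR"),
                         class_label = "satellite")
  peaks <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(150L, 350L, 1100L, 1150L, 50L, 500L),
                     width = 60L))
  peaks$score <- c(10, 8, 6, 5, 9, 7)
  counts <- count_peak_repeat_overlaps(peaks, repeats, min_score = 5)
  got <- setNames(counts$peaks, counts$family)
  # peak1 [150,209] hits HSAT2 only; peak2 [350,409] spans HSAT2+HSAT3;
  # peak3 hits ALR; peak4 has score 5 (excluded, strict >); peak5 [50,109]
  # clips HSAT2; peak6 [500,559] hits HSAT3
  expect_equal(got[["HSAT2"]], 3L)
  expect_equal(got[["HSAT3"]], 2L)
  expect_equal(got[["ALR"]], 1L)
})
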