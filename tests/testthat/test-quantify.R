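# Read filtering, assignment against the maximal-overlap oracle, RPM
# tables, repeat/mRNA ratio, locus matrices and strand summaries.

make_reads <- function(chrom, start, width = 100L, strand = "+",
                       mapq = 60L, secondary = FALSE, truth = NA) {
  n <- length(start)
  out <- data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    chrom = rep_len(chrom, n), start = start,
    width = rep_len(width, n), strand = rep_len(strand, n),
    mapq = rep_len(mapq, n), secondary = rep_len(secondary, n),
    truth = rep_len(truth, n), stringsAsFactors = FALSE
  )
  class(out) <- c("aligned_reads", "data.frame")
  out
}

simple_resolved <- function() {
  resolve_annotations(feature_set(
    "chr1", c(1000L, 5000L, 9000L), c(1999L, 5999L, 9999L),
    family = c("HSAT2", "RRNA1", "GENE1"),
    class_label = c("satellite", "rRNA", "protein_coding"),
    seqlengths = c(chr1 = 20000L)
  ))
}

test_that("MAPQ filtering removes scores below 30 and keeps 30 exactly", {
  res <- simple_resolved()
  reads <- make_reads("chr1", c(1100L, 1200L), mapq = c(29L, 30L))
  kept <- filter_reads(reads, res)
  expect_equal(kept$read_id, "r002")
  rep <- attr(kept, "filter_report")
  expect_equal(rep$removed_low_mapq, 1L)
  expect_equal(rep$retained, 1L)
})

test_that("constructed 10-read set filters exactly as per-read rule
           application, with matching report", {
  res <- simple_resolved()
  rrna <- res[res$class == "rRNA"]
  # 2 secondary, 3 MAPQ<30 (one of them also secondary), 1 rRNA overlap
  reads <- make_reads(
    "chr1",
    start = c(1100L, 1200L, 1300L, 1400L, 1500L, 1600L, 1700L, 1800L,
              5200L, 9100L),
    mapq = c(60L, 60L, 25L, 10L, 60L, 60L, 60L, 29L, 60L, 60L),
    secondary = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                  FALSE, FALSE)
  )
  kept <- filter_reads(reads, res)
  oracle_keep <- oracle_filter(reads, rrna)
  expect_equal(kept$read_id, reads$read_id[oracle_keep])
  expect_equal(sum(oracle_keep), 5L)
  rep <- attr(kept, "filter_report")
  expect_equal(rep$input, 10L)
  expect_equal(rep$removed_rrna_trna, 1L)
  expect_equal(rep$removed_secondary, 2L)   # charged before the MAPQ rule
  expect_equal(rep$removed_low_mapq, 2L)
  expect_equal(rep$retained, 5L)
  expect_equal(rep$removed_rrna_trna + rep$removed_secondary +
                 rep$removed_low_mapq + rep$retained, rep$input)
})

test_that("the retained set is independent of rule order (conjunctive
           rules)", {
  res <- simple_resolved()
  set.seed(5)
  reads <- make_reads(
    "chr1", start = sample.int(15000L, 200L),
    mapq = sample(c(0L, 20L, 29L, 30L, 60L), 200L, replace = TRUE),
    secondary = sample(c(TRUE, FALSE), 200L, replace = TRUE, prob = c(.2, .8))
  )
  kept <- filter_reads(reads, res)
  rrna <- res[res$class == "rRNA"]
  # alternative order: MAPQ first, then secondary, then rRNA
  alt <- reads[reads$mapq >= 30L, ]
  alt <- alt[!alt$secondary, ]
  alt <- alt[!IRanges::overlapsAny(reads_to_granges(alt), rrna,
                                   ignore.strand = TRUE), ]
  expect_equal(sort(kept$read_id), sort(alt$read_id))
})

test_that("reads are assigned by maximal overlap with tier tie-breaking", {
  # resolved pieces: miRNA [100,199], SINE [200,299] (after resolution of
  # miRNA [100,199] with SINE [170,299])
  feats <- feature_set("chr1", c(100L, 170L), c(199L, 299L),
                       family = c("MIR1", "AluY"),
                       class_label = c("miRNA", "SINE"),
                       seqlengths = c(chr1 = 1000L))
  res <- resolve_annotations(feats)
  # read [170,219]: 30 bp on the miRNA piece, 20 bp on the SINE piece
  reads <- make_reads("chr1", 170L, width = 50L)
  asg <- assign_reads(reads, res)
  expect_equal(asg$reads$category, "noncoding")
  expect_equal(asg$reads$family, "MIR1")
  # read wholly inside a satellite feature
  sat <- resolve_annotations(feature_set("chr1", 500L, 900L,
                                         family = "HSAT2",
                                         class_label = "satellite",
                                         seqlengths = c(chr1 = 1000L)))
  asg2 <- assign_reads(make_reads("chr1", 600L), sat)
  expect_equal(asg2$reads$category, "satellite")
  # read overlapping nothing is intergenic
  asg3 <- assign_reads(make_reads("chr1", 950L, width = 40L), sat)
  expect_equal(asg3$reads$category, "intergenic")
  expect_true(is.na(asg3$reads$feature))
})

test_that("assignment errors on chromosomes unknown to the annotation", {
  res <- simple_resolved()
  expect_error(assign_reads(make_reads("chrUn", 100L), res), "chrUn")
})

test_that("assignment matches the brute-force per-read oracle on random
           sets", {
  set.seed(202)
  for (rep in 1:25) {
    feats <- random_feature_set(sample(2:12, 1L), 10000L)
    res <- resolve_annotations(feats)
    reads <- make_reads("chr1", sample.int(9900L, 50L),
                        width = sample(c(50L, 100L), 50L, replace = TRUE))
    asg <- assign_reads(reads, res)
    oracle <- vapply(seq_len(nrow(reads)), function(i) {
      oracle_assign_one(reads$chrom[i], reads$start[i], reads$width[i], res)
    }, integer(1))
    expect_identical(asg$reads$feature, oracle)
  }
})

test_that("simulated reads with unambiguous placement recover truth
           categories exactly and counts are conserved", {
  sim <- simulate_genome(example_genome_config(seed = 4))
  res <- resolve_annotations(sim$annotation)
  cfg <- read_sim_config(
    20000L, read_mix_target(1.7),
    mapq_dist = data.frame(mapq = 60L, prob = 1),
    secondary_prob = 0, seed = 8L
  )
  reads <- simulate_reads(sim, cfg)
  kept <- filter_reads(reads, res)
  asg <- assign_reads(kept, res)
  nonintergenic <- asg$reads$truth != "intergenic"
  expect_equal(asg$reads$category[nonintergenic],
               asg$reads$truth[nonintergenic])
  # conservation: every filtered read lands in exactly one category
  expect_equal(sum(asg$category_counts), nrow(kept))
})

test_that("abundance table computes RPM by definition", {
  tab <- abundance_table(c(LINE = 250000, protein_coding = 750000))
  expect_equal(tab$rpm[tab$category == "LINE"], 250000)
  one <- abundance_table(c(satellite = 1e6))
  expect_equal(one$rpm, 1e6)
  set.seed(3)
  counts <- setNames(rpois(5, 1000), c("SINE", "LINE", "satellite",
                                       "protein_coding", "intergenic"))
  tab2 <- abundance_table(counts)
  expect_equal(tab2$rpm, 1e6 * as.numeric(counts) / sum(counts))
  expect_equal(sum(tab2$rpm), 1e6)
  expect_error(abundance_table(c(LINE = 0), total = 0), "positive")
})

test_that("repeat/mRNA ratio sums repeat classes over protein-coding RPM", {
  tab <- abundance_table(c(
    satellite = 200000, simple = 80000, low_complexity = 60000,
    protein_coding = 200000, noncoding = 100000, intergenic = 360000))
  expect_equal(repeat_mrna_ratio(tab), 1.7)
  even <- abundance_table(c(LINE = 500, protein_coding = 500))
  expect_equal(repeat_mrna_ratio(even), 1.0)
  nopc <- abundance_table(c(LINE = 500, noncoding = 500))
  expect_error(repeat_mrna_ratio(nopc), "protein-coding")
})

test_that("locus matrix is log10 RPM with an explicit no-reads marker", {
  m <- locus_matrix(c(loc1 = 1000L, loc2 = 0L), totals = 1e6)
  expect_equal(unname(m["loc1", 1]), 3.0)
  expect_true(is.na(m["loc2", 1]))
  # cumulative mode on a 2-sample toy: counts summed before RPM
  counts <- matrix(c(10L, 0L, 30L, 0L), nrow = 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  cum <- locus_matrix(counts, totals = c(1e5, 3e5), cumulative = TRUE)
  expect_equal(unname(cum["a", 1]), log10(1e6 * 40 / 4e5))
  expect_true(is.na(cum["b", 1]))
})

test_that("strand summary counts sense relative to the locus reference
           strand", {
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000L, 3000L),
                                 strand = "*")
  reads <- make_reads("chr1", rep(1500L, 100L),
                      strand = rep(c("+", "-"), each = 50L))
  ss <- strand_ratio(reads, loci)
  expect_equal(ss$sense, 50L)
  expect_equal(ss$antisense, 50L)
  expect_equal(ss$sense_fraction, 0.5)
  all_sense <- strand_ratio(make_reads("chr1", rep(1500L, 20L)), loci)
  expect_equal(all_sense$sense_fraction, 1.0)
  # inverted protocol flips the convention
  inv <- strand_ratio(make_reads("chr1", rep(1500L, 20L)), loci,
                      invert = TRUE)
  expect_equal(inv$sense_fraction, 0)
  # locus with no reads has an undefined fraction
  empty <- strand_ratio(make_reads("chr1", 10L, width = 5L), loci)
  expect_true(is.na(empty$sense_fraction))
})

test_that("SAM round trip preserves coordinates, flags, MAPQ and truth", {
  sim <- tiny_hsat3_genome()
  cfg <- read_sim_config(300L, c(satellite = 1), seed = 2L,
                         rrna_fraction = 0)
  reads <- simulate_reads(sim, cfg)
  f <- tempfile(fileext = ".sam")
  write_sam(reads, f, setNames(Biostrings::width(sim$genome),
                               names(sim$genome)))
  back <- read_sam(f)
  back <- back[order(back$read_id), ]
  rownames(back) <- NULL
  expect_equal(back$start, reads$start)
  expect_equal(back$strand, reads$strand)
  expect_equal(back$mapq, reads$mapq)
  expect_equal(back$secondary, reads$secondary)
  expect_equal(back$truth, reads$truth)
  expect_equal(back$width, reads$width)
})
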