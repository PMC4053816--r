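test_that("undercovered intervals are maximal runs below threshold", {
  rel <- make_rel(c(1, 0.05, 0.05, 1))
  iv <- undercovered_intervals(rel)
  expect_equal(iv[, c("start", "end")], data.frame(start = 1L, end = 3L))

  expect_equal(nrow(undercovered_intervals(make_rel(rep(1, 10)))), 0L)

  # a masked base splits a low run
  rel <- make_rel(c(1, 0.05, 0.05, 0.05, 1), seq = "AANAA")
  iv <- undercovered_intervals(rel)
  expect_equal(iv$start, c(1L, 3L))
  expect_equal(iv$end, c(2L, 4L))
})

test_that("contig splitting produces near-equal pieces within bounds", {
  x <- c(a = random_seq(100000))
  expect_equal(split_contigs(x), x)

  y <- c(b = random_seq(120000))
  p <- split_contigs(y)
  expect_equal(nchar(p), c(b.1 = 60000L, b.2 = 60000L))
  expect_equal(paste0(p[[1]], p[[2]]), y[[1]])

  z <- c(c = paste(rep("ACGTA", 50001), collapse = ""))  # 250,005 bases
  pz <- split_contigs(z)
  expect_equal(sum(nchar(pz)), 250005L)
  expect_true(all(nchar(pz) >= 50000L & nchar(pz) <= 100000L))
  expect_equal(length(pz), 3L)
  expect_equal(paste(pz, collapse = ""), z[[1]])
  # near-equal split of 250,001 bases: {83334, 83334, 83333}
  w <- split_contigs(c(d = random_seq(250001)))
  expect_equal(unname(nchar(w)), c(83334L, 83334L, 83333L))
})

test_that("assembly-variation mask excludes gaps and high-error windows", {
  ref <- make_ref(c(chr = random_seq(1500)))
  seqpart <- function(a, b) substring(ref$seqs[["chr"]], a, b)

  # 500M200D500M: the 200 skipped reference bases are excluded as gaps
  sam <- write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "500M200D500M",
    seq = paste0(seqpart(1, 500), seqpart(701, 1200))))
  m <- assembly_variation_mask(sam, ref)
  expect_equal(which(m$chr == 1L), 501:700)
  # the deleted bases also push flanking 100-base windows over the error
  # budget, so high_error_window provenance extends around the gap
  flank <- which(m$chr == 2L)
  expect_true(all(flank >= 407L & flank <= 794L))
  expect_equal(sum(m$chr != 0L), 200L + length(flank))

  # exactly 5 errors in a window: kept; 6 errors: excluded
  mutate_at <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    ch[at] <- chartr("ACGT", "CATG", ch[at])
    paste(ch, collapse = "")
  }
  full <- ref$seqs[["chr"]]
  five <- mutate_at(full, seq(600, 680, by = 20))   # 5 mismatches in 100 bases
  six <- mutate_at(full, seq(600, 650, by = 10))    # 6 mismatches in 51 bases
  m5 <- assembly_variation_mask(write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "1500M", seq = five)), ref)
  m6 <- assembly_variation_mask(write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "1500M", seq = six)), ref)
  expect_equal(sum(m5$chr != 0L), 0L)
  expect_gt(sum(m6$chr == 2L), 0L)
  # every window holding all six mismatches is excluded
  expect_true(all(m6$chr[620:680] == 2L))

  # a perfect contig alignment excludes nothing
  mp <- assembly_variation_mask(write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "1500M", seq = full)), ref)
  expect_equal(sum(mp$chr != 0L), 0L)
})

test_that("diverse-consistency filter applies the well-covered/undercovered rule", {
  div <- list(make_rel(c(0.6, 0.6, 0.3, 0.6)))
  s1 <- make_rel(c(0.05, 0.05, 0.00, 0.05))
  s2 <- make_rel(c(0.08, 0.20, 0.00, 0.09))
  s3 <- make_rel(c(0.02, 0.02, 0.00, 0.11))
  m <- diverse_consistency_filter(div, list(s1, s2, s3))
  # base 1: diverse 0.6, all samples < 0.1 -> excluded
  # base 2: one sample at 0.2 -> kept
  # base 3: diverse only 0.3 -> kept
  # base 4: one sample at 0.11 -> kept
  expect_equal(m$chr, c(3L, 0L, 0L, 0L))

  # multiple diverse tracks: "either" means the max decides
  div2 <- list(make_rel(c(0.2, 0.2, 0.2, 0.2)),
               make_rel(c(0.55, 0.2, 0.2, 0.2)))
  m2 <- diverse_consistency_filter(div2, list(s1))
  expect_equal(m2$chr, c(3L, 0L, 0L, 0L))
})

test_that("the discovery cascade filters, merges and annotates correctly", {
  # undercovered set fully inside a generalized motif: empty report
  rel <- make_rel(c(1, 1, 0.05, 0.05, 1, 1))
  ref <- make_ref(c(chr = "ACGTAC"))
  rep0 <- discover_uncategorized(
    rel, ref, generalized_motifs = data.frame(contig = "chr", start = 1L,
                                              end = 5L))
  expect_equal(nrow(rep0$intervals), 0L)
  expect_equal(rep0$total_bases, 0L)
  expect_equal(unname(rep0$excluded_by[["generalized_motif"]]), 2)

  # with empty filters the cascade reduces to undercovered_intervals
  set.seed(8)
  vals <- runif(2000, 0, 2)
  vals[sample(2000, 100)] <- 0.01
  seqs <- random_seq(2000)
  rel <- make_rel(vals, seq = seqs)
  ref <- make_ref(c(chr = seqs))
  plain <- undercovered_intervals(rel)
  full <- discover_uncategorized(rel, ref)
  expect_equal(full$intervals[, c("contig", "start", "end")],
               plain[, c("contig", "start", "end")])
  expect_equal(full$total_bases, sum(plain$end - plain$start))

  # filters only remove; provenance counts add up
  amask <- structure(list(chr = integer(2000)), class = "ExclusionMask")
  amask$chr[101:300] <- 1L
  filt <- discover_uncategorized(rel, ref, assembly_mask = amask)
  expect_lte(filt$total_bases, full$total_bases)
  expect_equal(full$total_bases - filt$total_bases,
               unname(sum(filt$excluded_by)))

  # per-interval annotation: GC fraction and homopolymer N50
  gseq <- paste0("AA", strrep("G", 6), "TT")
  rel2 <- make_rel(c(1, 1, rep(0.02, 6), 1, 1), seq = gseq)
  ref2 <- make_ref(c(chr = gseq))
  rep2 <- discover_uncategorized(rel2, ref2)
  expect_equal(rep2$intervals$length, 6L)
  expect_equal(rep2$intervals$gc_fraction, 1)
  expect_equal(rep2$intervals$homopolymer_n50, 6L)
  expect_equal(rep2$interval_n50, 6L)
})

test_that("interval N50 matches a brute-force oracle", {
  set.seed(77)
  for (k in 1:20) {
    lens <- sample(1:500, sample(1:40, 1), replace = TRUE)
    expect_equal(biasassay:::length_n50(lens), brute_n50(lens))
  }
  expect_true(is.na(biasassay:::length_n50(integer(0))))
})

test_that("planted neutral bias loci survive the cascade, motif-like ones do not", {
  # genome: 50%-GC background with four 85%-GC tracts; ten depressed loci,
  # five inside the GC tracts and five in neutral background
  tracts <- data.frame(
    length = c(40000, 3000, 40000, 3000, 40000, 3000, 40000, 3000, 40000,
               3000, 45000),
    gc = c(50, 85, 50, 85, 50, 85, 50, 85, 50, 85, 50))
  gc_mid <- cumsum(tracts$length) - tracts$length / 2
  gc_loci <- as.integer(gc_mid[tracts$gc == 85])       # centers of GC tracts
  neutral_loci <- as.integer(c(20000, 60000, 100000, 140000, 180000) + 500)
  loci <- sort(c(gc_loci, neutral_loci))
  cfg <- sim_config(
    genome_length = sum(tracts$length), gc_tracts = tracts,
    target_depth = 50,
    error_rates = c(mismatch = 0, deletion = 0, insertion = 0),
    planted_weights = data.frame(start = loci - 150L, end = loci + 150L,
                                 weight = 0.01),
    seed = 4)
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(ref, cfg)
  rel <- relative_coverage(compute_coverage(sim$sam, ref))
  gen <- do.call(rbind, lapply(standard_motif_set(generalized = TRUE),
                               function(sp) scan_motif(ref, sp)))
  report <- discover_uncategorized(rel, ref, generalized_motifs = gen)
  hit <- function(p) any(report$intervals$start < p & report$intervals$end > p)
  expect_equal(vapply(neutral_loci, hit, logical(1)), rep(TRUE, 5))
  expect_equal(vapply(gc_loci, hit, logical(1)), rep(FALSE, 5))
})
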