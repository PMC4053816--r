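test_that("error attribution follows the CIGAR conventions", {
  ref <- make_ref(c(chr = paste0("AGGT", strrep("A", 16))))
  # mismatch: read ACGT vs ref AGGT under 4M
  et <- count_errors(write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "4M", seq = "ACGT")), ref)
  expect_equal(which(et$mismatch$chr == 1L), 2L)
  expect_equal(sum(et$mismatch$chr), 1L)
  expect_equal(sum(et$deletion$chr) + sum(et$insertion$chr), 0L)

  # insertion: 2M3I2M charges 3 insertions to the ref base after the insert
  et <- count_errors(write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "2M3I2M", seq = "AGCCCGT")), ref)
  expect_equal(et$insertion$chr[3], 3L)
  expect_equal(sum(et$insertion$chr), 3L)
  expect_equal(sum(et$mismatch$chr), 0L)

  # deletion: 2M1D2M counts one deletion at the skipped base, coverage 0 there
  et <- count_errors(write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "2M1D2M", seq = "AGTA")), ref)
  expect_equal(et$deletion$chr[3], 1L)
  expect_equal(et$coverage$counts$chr[3], 0L)
  expect_equal(et$coverage$counts$chr[1:5], c(1L, 1L, 0L, 1L, 1L))
})

test_that("edge insertions are charged to the nearest aligned base", {
  ref <- make_ref(c(chr = strrep("A", 20)))
  # trailing insertion -> last preceding aligned base (0-based offset 2)
  et <- count_errors(write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "3M2I", seq = "AAACC")), ref)
  expect_equal(et$insertion$chr[3], 2L)
  # leading insertion -> first aligned base
  et <- count_errors(write_test_sam(ref, data.frame(
    rname = "chr", pos = 5L, cigar = "2I3M", seq = "CCAAA")), ref)
  expect_equal(et$insertion$chr[5], 2L)
  # counts are conserved either way
  expect_equal(sum(et$insertion$chr), 2L)
})

test_that("N read bases over unambiguous reference count as mismatches", {
  ref <- make_ref(c(chr = strrep("A", 10)))
  et <- count_errors(write_test_sam(ref, data.frame(
    rname = "chr", pos = 1L, cigar = "4M", seq = "ANAA")), ref)
  expect_equal(sum(et$mismatch$chr), 1L)
  expect_equal(which(et$mismatch$chr == 1L), 2L)
})

test_that("records without sequence are skipped with a logged count", {
  ref <- make_ref(c(chr = strrep("A", 10)))
  sam <- write_test_sam(ref, data.frame(
    rname = "chr", pos = c(1L, 1L), cigar = c("4M", "4M"),
    seq = c("AAAA", "*"), qname = c("a", "b")))
  expect_message(et <- count_errors(sam, ref), "without read sequence")
  expect_equal(sum(et$coverage$counts$chr), 4)
})

test_that("error rates are error counts over mapped bases", {
  ref <- make_ref(c(chr = random_seq(10)))
  perfect <- substring(ref$seqs[["chr"]], 1, 10)
  flawed <- paste0(substring(perfect, 1, 4),
                   chartr("ACGT", "CATG", substring(perfect, 5, 5)),
                   substring(perfect, 6, 10))
  recs <- data.frame(rname = "chr", pos = 1L, cigar = "10M",
                     seq = c(rep(perfect, 99), flawed),
                     qname = sprintf("q%03d", 1:100))
  et <- count_errors(write_test_sam(ref, recs), ref)
  r <- error_rates(et)
  expect_equal(r$mapped_bases, 1000)
  expect_equal(r$mismatch_rate, 0.001)
  expect_equal(r$total_rate, 0.001)
  expect_equal(r$deletion_rate, 0)

  # restricted to a region not containing the mismatch
  r2 <- error_rates(et, data.frame(contig = "chr", start = 6L, end = 10L))
  expect_equal(r2$mismatch_rate, 0)
  expect_equal(r2$mapped_bases, 400)

  # region with no mapped bases -> undefined marker
  empty <- count_errors(write_test_sam(ref, recs[0, ]), ref)
  expect_true(is.na(error_rates(empty)$mismatch_rate))
})

test_that("simulated error counts are conserved exactly and bin totals add up", {
  cfg <- sim_config(genome_length = 60000, target_depth = 15,
                    error_rates = c(mismatch = 0.004, deletion = 0.001,
                                    insertion = 0.001),
                    seed = 77)
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(ref, cfg)
  et <- count_errors(sim$sam, ref)

  # exact conservation per type against the ground-truth event log
  expect_equal(sum(et$mismatch$sim), sim$event_counts[["mismatch"]])
  expect_equal(sum(et$deletion$sim), sim$event_counts[["deletion"]])
  expect_equal(sum(et$insertion$sim), sim$event_counts[["insertion"]])

  # exact conservation per position
  for (type in c("mismatch", "deletion", "insertion")) {
    ev <- sim$events[sim$events$type == type, ]
    want <- integer(ref$lengths[["sim"]])
    if (nrow(ev) > 0) {
      agg <- tapply(ev$length, ev$pos, sum)
      want[as.integer(names(agg)) + 1L] <- as.integer(agg)
    }
    field <- c(mismatch = "mismatch", deletion = "deletion",
               insertion = "insertion")[[type]]
    expect_equal(et[[field]]$sim, want)
  }

  # GC profile: binned + unbinned numerators sum to genome-wide numerators
  prof <- error_profile(et, "gc_percent", ref, min_windows = 1L)
  gcw <- gc_percent_windows(ref)
  bins <- biasassay:::per_base_gc_bin(gcw, "sim", ref$lengths)
  unbinned <- is.na(bins$sim)
  expect_equal(sum(prof$mismatch_rate * prof$mapped_bases, na.rm = TRUE) +
                 sum(et$mismatch$sim[unbinned]),
               sum(et$mismatch$sim))
  # rates are bounded
  expect_true(all(prof$mismatch_rate[!is.na(prof$mismatch_rate)] <= 1))
})

test_that("GC error bins honor the minimum-window reportability rule", {
  cfg <- sim_config(genome_length = 20000, target_depth = 5, seed = 5)
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(ref, cfg)
  et <- count_errors(sim$sam, ref)
  prof <- error_profile(et, "gc_percent", ref, min_windows = 1000L)
  gcw <- gc_percent_windows(ref)
  counts <- tabulate(gcw$gc$sim[!is.na(gcw$gc$sim)] + 1L, nbins = 101L)
  expect_equal(prof$reportable, counts >= 1000L)
  expect_true(any(prof$reportable))
  expect_true(any(!prof$reportable))
})

test_that("homopolymer profile recovers a planted deletion-rate multiplier", {
  planted <- data.frame(type = "homopolymer",
                        start = seq(1000, 195000, by = 1000),
                        length = 10, base = "G")
  cfg <- sim_config(
    genome_length = 200000, target_depth = 25,
    error_rates = c(mismatch = 0.002, deletion = 0.002, insertion = 0.0005),
    homopolymer_multipliers = list(
      deletion = function(len) ifelse(len >= 8, 10, 1)),
    planted_sequences = planted, seed = 31
  )
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(ref, cfg)
  et <- count_errors(sim$sam, ref)
  prof <- error_profile(et, "homopolymer_length", ref)
  long <- prof$bin >= 8
  short <- prof$bin <= 4
  rate_long <- sum(prof$deletion_rate[long] * prof$mapped_bases[long],
                   na.rm = TRUE) / sum(prof$mapped_bases[long])
  rate_short <- sum(prof$deletion_rate[short] * prof$mapped_bases[short],
                    na.rm = TRUE) / sum(prof$mapped_bases[short])
  ratio <- rate_long / rate_short
  n_long <- rate_long * sum(prof$mapped_bases[long])
  n_short <- rate_short * sum(prof$mapped_bases[short])
  se_rel <- sqrt(1 / n_long + 1 / n_short)
  expect_gt(ratio, 10 * (1 - 3 * se_rel) - 0.5)
  expect_lt(ratio, 10 * (1 + 3 * se_rel) + 0.5)
})
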