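sim_small <- function(seed, depth = 20, L = 50000, paired = FALSE) {
  cfg <- sim_config(genome_length = L, target_depth = depth, paired = paired,
                    error_rates = c(mismatch = 0, deletion = 0, insertion = 0),
                    seed = seed)
  ref <- simulate_reference(cfg)
  list(ref = ref, sim = simulate_alignments(ref, cfg), cfg = cfg)
}

test_that("downsampling is deterministic, pair-safe and hits the target depth", {
  s <- sim_small(seed = 2)
  out1 <- tempfile(fileext = ".sam")
  out2 <- tempfile(fileext = ".sam")

  # probability 1 keeps every record
  downsample_alignments(s$sim$sam, out1, current_mean = 20, target_mean = 20,
                        seed = 4)
  expect_identical(readLines(out1), readLines(s$sim$sam))

  # same seed twice: byte-identical output
  downsample_alignments(s$sim$sam, out1, 20, 5, seed = 4)
  downsample_alignments(s$sim$sam, out2, 20, 5, seed = 4)
  expect_identical(readLines(out1), readLines(out2))

  # target above current is a hard error
  expect_error(downsample_alignments(s$sim$sam, out1, 20, 25, seed = 1),
               "exceeds")

  # realized mean within 4 binomial SEs of target
  cov_full <- compute_coverage(s$sim$sam, s$ref)
  downsample_alignments(s$sim$sam, out1, cov_full$mu, cov_full$mu / 2,
                        seed = 9)
  cov_half <- compute_coverage(out1, s$ref)
  n_reads <- s$sim$n_reads
  se <- cov_full$mu * sqrt(0.5 * 0.5 / n_reads)
  expect_lt(abs(cov_half$mu - cov_full$mu / 2), 4 * se)

  # paired data: mates are never split
  sp <- sim_small(seed = 3, depth = 10, paired = TRUE)
  out3 <- tempfile(fileext = ".sam")
  downsample_alignments(sp$sim$sam, out3, 10, 4, seed = 6)
  body <- readLines(out3)
  body <- body[!startsWith(body, "@")]
  qn <- sub("\t.*", "", body)
  expect_true(all(table(qn) == 2L))
})

test_that("combining tracks adds counts and means", {
  ref <- make_ref(c(chr = random_seq(300)))
  a <- coverage_track(list(chr = rep(5L, 300)), ref)
  b <- coverage_track(list(chr = rep(5L, 300)), ref)
  ab <- combine_tracks(a, b)
  expect_equal(ab$counts$chr, rep(10L, 300))
  expect_equal(ab$mu, 10)

  # complementarity mechanics: a zero region filled by the partner
  ca <- c(rep(0L, 100), rep(6L, 200))
  cb <- c(rep(6L, 100), rep(0L, 200))
  m <- combine_tracks(coverage_track(list(chr = ca), ref),
                      coverage_track(list(chr = cb), ref))
  expect_true(all(m$counts$chr > 0))

  # commutative and associative
  x <- coverage_track(list(chr = rpois(300, 3)), ref)
  expect_equal(combine_tracks(a, x)$counts, combine_tracks(x, a)$counts)
  expect_equal(combine_tracks(combine_tracks(a, b), x)$counts,
               combine_tracks(a, combine_tracks(b, x))$counts)

  # mask mismatch is a hard error
  ref2 <- make_ref(c(chr = paste0("N", random_seq(299))))
  c2 <- coverage_track(list(chr = rep(5L, 300)), ref2)
  expect_error(combine_tracks(a, c2), "different references")
})

test_that("a 50/50 mixture of biased and unbiased data is intermediate", {
  L <- 200000
  gc_tracts <- data.frame(length = rep(10000, 20), gc = rep(c(35, 75), 10))
  mk <- function(bias, seed) {
    cfg <- sim_config(genome_length = L, gc_tracts = gc_tracts,
                      target_depth = 40, coverage_bias = bias,
                      error_rates = c(mismatch = 0, deletion = 0,
                                      insertion = 0),
                      seed = seed)
    ref <- simulate_reference(cfg)
    list(ref = ref, sam = simulate_alignments(ref, cfg)$sam)
  }
  flat <- mk(NULL, seed = 101)
  # heavy depletion of high-GC windows
  dep <- function(gc) ifelse(gc >= 60, 0.05, 1)
  cfg2 <- sim_config(genome_length = L, gc_tracts = gc_tracts,
                     target_depth = 40, coverage_bias = dep,
                     error_rates = c(mismatch = 0, deletion = 0,
                                     insertion = 0),
                     seed = 101)
  biased_sam <- simulate_alignments(flat$ref, cfg2)$sam

  res <- mix_experiment(flat$sam, biased_sam, flat$ref,
                        per_component_mean = 15,
                        thresholds = c(0, 0.1, 0.25, 0.5), seed = 7)
  f_mix <- res$mixture$fraction[3]
  f_flat <- res$component_a$fraction[3]
  f_bias <- res$component_b$fraction[3]
  expect_gte(f_mix, f_flat)
  expect_lte(f_mix, f_bias)
  expect_gt(f_bias, 0.1)  # the biased component really is badly undercovered
})

test_that("motif statistics are stable under shallow subsampling", {
  cfg <- sim_config(genome_length = 100000, target_depth = 25,
                    error_rates = c(mismatch = 0, deletion = 0,
                                    insertion = 0),
                    seed = 13)
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(ref, cfg)
  motifs <- list(
    left_half = data.frame(contig = "sim", start = 0L, end = 50000L),
    scattered = data.frame(contig = "sim",
                           start = seq(0L, 90000L, by = 10000L),
                           end = seq(2000L, 92000L, by = 10000L))
  )
  st <- subsample_stability(sim$sam, ref, motifs, target_mean = 2,
                            reps = 5L, seed = 3)
  expect_equal(st$motif, c("left_half", "scattered"))
  expect_true(all(abs(st$mean - st$full_value) < 0.05))
  expect_true(all(st$sd >= 0))
  expect_true(all(abs(st$full_value - 1) < 0.2))
})
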