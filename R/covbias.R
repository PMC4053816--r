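#' Per-base coverage from an alignment file
#'
#' Counts, at every reference base, the number of read bases aligned to it
#' under the CIGAR M, `=` or X operators — only those read bases contribute
#' to coverage. Deleted (D), skipped (N), inserted (I), soft-clipped (S),
#' hard-clipped (H) and padded (P) bases contribute nothing. Unmapped,
#' secondary, supplementary and duplicate-flagged records are excluded;
#' MAPQ-0 records are kept so that randomly placed multi-mappers count.
#'
#' The mean coverage `mu` is total aligned bases on included positions
#' divided by the number of included positions; masked bases are excluded
#' from the denominator and from every downstream statistic.
#'
#' @param alignments Path to a SAM or BAM file, or a record list from
#'   [read_alignments()].
#' @param ref A `ReferenceModel`.
#' @return A `CoverageTrack`: list with per-contig integer `counts`, the
#'   reference mask, `mu` and `included_base_count`.
#' @export
compute_coverage <- function(alignments, ref) {
  stopifnot(inherits(ref, "ReferenceModel"))
  rec <- if (is.character(alignments)) read_alignments(alignments, ref) else
    alignments
  acc <- accumulate_records(rec, ref, count_errors = FALSE)
  coverage_track(acc$cov, ref)
}

#' Construct a CoverageTrack from per-contig counts
#'
#' @param counts Named list of per-contig non-negative integer vectors, one
#'   value per reference base (values at masked bases are carried but never
#'   enter any statistic).
#' @param ref The `ReferenceModel` the counts were computed on.
#' @return A `CoverageTrack`.
#' @export
coverage_track <- function(counts, ref) {
  stopifnot(inherits(ref, "ReferenceModel"),
            identical(sort(names(counts)), sort(ref$names)))
  counts <- counts[ref$names]
  for (ctg in ref$names) {
    stopifnot(length(counts[[ctg]]) == ref$lengths[[ctg]])
  }
  total <- sum(vapply(ref$names, function(ctg)
    sum(as.numeric(counts[[ctg]][ref$included[[ctg]]])), numeric(1L)))
  structure(list(
    counts = counts,
    included = ref$included,
    contigs = ref$names,
    lengths = ref$lengths,
    included_base_count = ref$included_base_count,
    mu = total / ref$included_base_count
  ), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack: %d contig(s), mean coverage %.3f over %s included bases\n",
              length(x$contigs), x$mu,
              format(x$included_base_count, big.mark = ",")))
  invisible(x)
}

#' Relative coverage
#'
#' The fundamental coverage-bias statistic: each base's aligned-base count
#' divided by the genome-wide mean coverage. A value of 1 means the base is
#' covered at the expected average rate; values below 1 mean undercoverage.
#' By construction the mean of relative coverage over included bases is
#' exactly 1.
#'
#' @param track A `CoverageTrack` with `mu > 0`.
#' @return A `RelativeCoverageTrack`: list with per-contig numeric `values`,
#'   the mask, and the `mu` it was normalized by.
#' @export
relative_coverage <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (track$mu <= 0) stop("no aligned bases: mean coverage is zero")
  values <- lapply(track$counts, function(v) v / track$mu)
  structure(list(
    values = values,
    included = track$included,
    contigs = track$contigs,
    lengths = track$lengths,
    included_base_count = track$included_base_count,
    mu = track$mu
  ), class = "RelativeCoverageTrack")
}

#' @export
print.RelativeCoverageTrack <- function(x, ...) {
  cat(sprintf("RelativeCoverageTrack: %d contig(s), normalized by mu = %.3f\n",
              length(x$contigs), x$mu))
  invisible(x)
}

rel_values_included <- function(rel) {
  unlist(lapply(rel$contigs, function(ctg)
    rel$values[[ctg]][rel$included[[ctg]]]), use.names = FALSE)
}

#' Undercoverage fractions at relative-coverage thresholds
#'
#' Fraction of included bases with relative coverage exactly 0 (for the
#' threshold 0) or at most t (for t > 0). Comparisons across data sets
#' should be made at a common depth (see [downsample_alignments()]) because
#' tail fractions depend on depth.
#'
#' @param rel A `RelativeCoverageTrack`.
#' @param thresholds Ascending thresholds; default `c(0, 0.1, 0.25, 0.5)`.
#' @return Data.frame with `threshold`, `fraction` and `percent` (the
#'   fraction as a 2-significant-figure percentage, matching report style).
#' @export
undercoverage_fractions <- function(rel, thresholds = c(0, 0.1, 0.25, 0.5)) {
  stopifnot(inherits(rel, "RelativeCoverageTrack"),
            !is.unsorted(thresholds))
  v <- rel_values_included(rel)
  frac <- vapply(thresholds, function(t) {
    if (t == 0) mean(v == 0) else mean(v <= t)
  }, numeric(1L))
  data.frame(threshold = thresholds, fraction = frac,
             percent = signif(100 * frac, 2L))
}

#' Mean relative coverage of a motif
#'
#' The arithmetic mean of per-base relative coverage over the union of
#' included bases in the given intervals, each base counted once. Because a
#' motif aggregates many loci, this statistic is measurable at far lower
#' depth than per-base statistics.
#'
#' @param rel A `RelativeCoverageTrack`.
#' @param intervals Interval data.frame (e.g. a motif scan or a bad-promoter
#'   list).
#' @return The mean relative coverage, or `NA` when the intervals contain no
#'   included bases.
#' @export
motif_relative_coverage <- function(rel, intervals) {
  stopifnot(inherits(rel, "RelativeCoverageTrack"))
  if (nrow(intervals) == 0L) return(NA_real_)
  merged <- merge_intervals(intervals)
  total <- 0
  nbase <- 0
  for (ctg in unique(merged$contig)) {
    if (!ctg %in% rel$contigs) {
      stop("interval contig not in track: ", ctg)
    }
    d <- merged[merged$contig == ctg, , drop = FALSE]
    idx <- unlist(mapply(function(s, e) (s + 1L):e, d$start, d$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    keep <- rel$included[[ctg]][idx]
    total <- total + sum(rel$values[[ctg]][idx][keep])
    nbase <- nbase + sum(keep)
  }
  if (nbase == 0L) return(NA_real_)
  total / nbase
}

#' GC-bias curve
#'
#' Groups all 100-base sliding windows of the genome by integer GC
#' percentage and reports the mean relative coverage per percentage. A
#' window's relative coverage is the mean of its per-base values, so the
#' curve composes exactly with the per-base statistic. Bins are flagged
#' reportable only when the genome holds at least `min_windows` windows of
#' that GC content; unbiased sequencing gives a flat curve at 1.
#'
#' @param rel A `RelativeCoverageTrack`.
#' @param gc_windows Output of [gc_percent_windows()] on the same reference
#'   and mask.
#' @param min_windows Minimum windows per reportable bin (default 1000).
#' @return A `GCBiasCurve` data.frame: `gc`, `n_windows`,
#'   `mean_relative_coverage` (`NA` for empty bins), `reportable`.
#' @export
gc_bias_curve <- function(rel, gc_windows, min_windows = 1000L) {
  stopifnot(inherits(rel, "RelativeCoverageTrack"),
            inherits(gc_windows, "gc_windows"))
  w <- gc_windows$window
  sums <- numeric(101L)
  ns <- numeric(101L)
  for (ctg in rel$contigs) {
    gcv <- gc_windows$gc[[ctg]]
    if (length(gcv) == 0L) next
    ok <- which(!is.na(gcv))
    if (length(ok) == 0L) next
    cs <- c(0, cumsum(rel$values[[ctg]]))
    winmean <- (cs[ok + w] - cs[ok]) / w
    bin <- gcv[ok] + 1L
    sums <- sums + as.numeric(tapply(winmean, factor(bin, levels = 1:101),
                                     sum, default = 0))
    ns <- ns + as.numeric(tabulate(bin, nbins = 101L))
  }
  mean_rel <- ifelse(ns > 0, sums / ns, NA_real_)
  structure(data.frame(
    gc = 0:100,
    n_windows = as.integer(ns),
    mean_relative_coverage = mean_rel,
    reportable = ns >= min_windows
  ), class = c("GCBiasCurve", "data.frame"))
}

#' Poisson significance of an undercoverage threshold
#'
#' Number of Poisson standard deviations separating a relative-coverage
#' threshold from the mean: `(mu - t * mu) / sqrt(mu)`. Under unbiased
#' sequencing at mean depth mu, observing a base at or below relative
#' coverage t is a `poisson_sigma(mu, t)`-sigma event, e.g. about 2.2 sigma
#' for halved coverage at 20x but more than 12 sigma for ten-fold
#' undercoverage at 198x — which is why deep data make low relative coverage
#' a reliable bias signal.
#'
#' @param mean_coverage Mean coverage mu (> 0).
#' @param relative_threshold Relative-coverage threshold t in [0, 1).
#' @return The z-score in Poisson standard deviations.
#' @export
poisson_sigma <- function(mean_coverage, relative_threshold) {
  stopifnot(mean_coverage > 0,
            relative_threshold >= 0, relative_threshold < 1)
  (mean_coverage - relative_threshold * mean_coverage) / sqrt(mean_coverage)
}
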