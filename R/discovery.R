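#' Deeply undercovered intervals
#'
#' Maximal runs of included bases whose relative coverage is at or below the
#' threshold. At deep coverage such runs are many standard deviations below
#' the mean under a Poisson model (see [poisson_sigma()]), so in the absence
#' of bias they should be essentially empty. Masked bases break runs.
#'
#' @param rel A `RelativeCoverageTrack`.
#' @param threshold Relative-coverage cutoff in (0, 1); default 0.1
#'   (ten-fold undercovered).
#' @return Interval data.frame.
#' @export
undercovered_intervals <- function(rel, threshold = 0.1) {
  stopifnot(inherits(rel, "RelativeCoverageTrack"),
            threshold > 0, threshold < 1)
  low <- lapply(rel$contigs, function(ctg)
    rel$included[[ctg]] & rel$values[[ctg]] <= threshold)
  names(low) <- rel$contigs
  mask_to_intervals(low, label = "undercovered")
}

#' Split long contigs into near-equal pieces
#'
#' Contigs at most `max_len` pass through unchanged; a longer contig of
#' length L is split into `ceiling(L / max_len)` near-equal pieces, which
#' guarantees every piece lies in `[min_len, max_len]` whenever
#' `min_len <= max_len / 2` (used to keep assembly contigs within an
#' aligner's maximum read length while avoiding short fragments).
#'
#' @param contigs Named character vector of sequences, or a
#'   `ReferenceModel`.
#' @param max_len Maximum piece length (default 100,000).
#' @param min_len Minimum piece length the scheme must respect (default
#'   50,000).
#' @return Named character vector of piece sequences; split pieces are named
#'   `<contig>.1`, `<contig>.2`, ...
#' @export
split_contigs <- function(contigs, max_len = 100000L, min_len = 50000L) {
  stopifnot(min_len <= max_len)
  if (inherits(contigs, "ReferenceModel")) contigs <- contigs$seqs
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  out <- character(0L)
  for (nm in names(contigs)) {
    s <- contigs[[nm]]
    L <- nchar(s)
    if (L <= max_len) {
      out[nm] <- s
      next
    }
    k <- ceiling(L / max_len)
    base <- L %/% k
    rem <- L %% k
    sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
    if (any(sizes < min_len)) {
      stop("cannot split contig ", nm, " (length ", L,
           ") into pieces of at least ", min_len, " bases")
    }
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    pieces <- substring(s, starts, ends)
    names(pieces) <- paste0(nm, ".", seq_len(k))
    out <- c(out, pieces)
  }
  out
}

empty_provenance <- function(ref) {
  m <- lapply(ref$lengths, function(L) integer(L))
  names(m) <- ref$names
  m
}

PROVENANCE_LEVELS <- c("assembly_gap", "high_error_window",
                       "diverse_consistent", "generalized_motif")

#' Exclusion mask from assembly-vs-reference contig alignments
#'
#' Marks reference bases whose low coverage is plausibly a sample/reference
#' difference rather than sequencing bias, using an assembly of the sample
#' aligned back to the reference: (1) reference bases skipped by D operators
#' in contig alignments are gaps in the sample (provenance `assembly_gap`);
#' (2) reference bases inside any sliding `window`-base window of the
#' aligned span containing strictly more than `max_errors` alignment errors
#' (mismatches + deleted bases + inserted bases, attributed as in
#' [count_errors()]) may carry high local polymorphism that defeats read
#' alignment (provenance `high_error_window`). Windows slide on reference
#' coordinates and are evaluated only where fully inside contig-covered
#' sequence.
#'
#' @param contig_alignments Path to SAM/BAM of assembly contigs aligned to
#'   the reference, or a record list.
#' @param ref A `ReferenceModel`.
#' @param window Sliding window size (default 100).
#' @param max_errors Error tolerance per window; windows with more errors
#'   are excluded (default 5).
#' @return An `ExclusionMask`: per-contig integer vectors coding provenance
#'   (0 = not excluded).
#' @export
assembly_variation_mask <- function(contig_alignments, ref, window = 100L,
                                    max_errors = 5L) {
  stopifnot(inherits(ref, "ReferenceModel"))
  rec <- if (is.character(contig_alignments))
    read_alignments(contig_alignments, ref) else contig_alignments
  acc <- accumulate_records(rec, ref, count_errors = TRUE)
  prov <- empty_provenance(ref)
  for (ctg in ref$names) {
    gap <- acc$del[[ctg]] > 0L
    err <- acc$mm[[ctg]] + acc$del[[ctg]] + acc$ins[[ctg]]
    covered <- acc$span[[ctg]] > 0L
    L <- ref$lengths[[ctg]]
    high <- logical(L)
    if (L >= window) {
      esum <- sliding_sum(err, window)
      csum <- sliding_sum(as.integer(covered), window)
      bad_start <- which(csum == window & esum > max_errors)
      for (s in bad_start) high[s:(s + window - 1L)] <- TRUE
    }
    p <- integer(L)
    p[high] <- 2L
    p[gap] <- 1L  # assembly gaps take precedence in provenance
    prov[[ctg]] <- p
  }
  structure(prov, class = "ExclusionMask")
}

#' Exclusion mask from diverse-population consistency
#'
#' Excludes bases whose poor coverage in the focal sample is consistent
#' across that sample's data sets yet absent from diverse multi-individual
#' data — the signature of sequence present in the population but missing
#' from the sample. A base is excluded iff its relative coverage is at least
#' `well_cov` in at least one diverse track (well covered somewhere) AND
#' below `under` in every sample track (undercovered in all).
#'
#' @param diverse_tracks List of one or more `RelativeCoverageTrack`s from
#'   diverse-population data.
#' @param sample_tracks List of one or more `RelativeCoverageTrack`s from
#'   the focal sample.
#' @param well_cov Well-covered threshold (default 0.5).
#' @param under Undercovered threshold (default 0.1, exclusive).
#' @return An `ExclusionMask` with provenance `diverse_consistent`.
#' @export
diverse_consistency_filter <- function(diverse_tracks, sample_tracks,
                                       well_cov = 0.5, under = 0.1) {
  stopifnot(length(diverse_tracks) >= 1L, length(sample_tracks) >= 1L)
  tr0 <- diverse_tracks[[1L]]
  prov <- lapply(tr0$lengths, function(L) integer(L))
  names(prov) <- tr0$contigs
  for (ctg in tr0$contigs) {
    well <- Reduce(pmax, lapply(diverse_tracks, function(t) t$values[[ctg]]))
    worst <- Reduce(pmax, lapply(sample_tracks, function(t) t$values[[ctg]]))
    excl <- tr0$included[[ctg]] & well >= well_cov & worst < under
    p <- integer(tr0$lengths[[ctg]])
    p[excl] <- 3L
    prov[[ctg]] <- p
  }
  structure(prov, class = "ExclusionMask")
}

#' Discover uncategorized coverage bias
#'
#' The filter cascade: start from ten-fold-undercovered intervals, remove
#' bases explained as probable sample/reference biological differences
#' (assembly-gap and high-error-window mask, diverse-consistency mask), then
#' remove bases similar to known bias motifs (the union of the generalized
#' motif scans and the bad-promoter list), and re-merge what remains into
#' maximal intervals. Each surviving interval is annotated with its length,
#' GC fraction and homopolymer N50; the report carries the total base count,
#' its fraction of the included genome, and the interval N50. Filters are
#' set subtractions, so the final interval set does not depend on their
#' order; provenance labels follow the order assembly, diverse, motif.
#'
#' @param rel A `RelativeCoverageTrack` of the focal data set.
#' @param ref The `ReferenceModel`.
#' @param assembly_mask Optional `ExclusionMask` from
#'   [assembly_variation_mask()].
#' @param diverse_mask Optional `ExclusionMask` from
#'   [diverse_consistency_filter()].
#' @param generalized_motifs Optional interval data.frame (union of
#'   generalized motif scans).
#' @param bad_promoters Optional interval data.frame.
#' @param threshold Undercoverage threshold (default 0.1).
#' @return A `DiscoveryReport`: list with `intervals` (annotated
#'   data.frame), `total_bases`, `genome_fraction`, `interval_n50`, and
#'   `excluded_by` (base counts per provenance category).
#' @export
discover_uncategorized <- function(rel, ref, assembly_mask = NULL,
                                   diverse_mask = NULL,
                                   generalized_motifs = NULL,
                                   bad_promoters = NULL, threshold = 0.1) {
  stopifnot(inherits(rel, "RelativeCoverageTrack"),
            inherits(ref, "ReferenceModel"))
  low <- lapply(ref$names, function(ctg)
    rel$included[[ctg]] & rel$values[[ctg]] <= threshold)
  names(low) <- ref$names
  excluded_by <- stats::setNames(numeric(length(PROVENANCE_LEVELS)),
                                 PROVENANCE_LEVELS)
  apply_mask <- function(low, prov_mask) {
    for (ctg in ref$names) {
      p <- prov_mask[[ctg]]
      hit <- low[[ctg]] & p > 0L
      if (any(hit)) {
        tb <- tabulate(p[hit], nbins = 4L)
        excluded_by <<- excluded_by + tb
        low[[ctg]][hit] <- FALSE
      }
    }
    low
  }
  if (!is.null(assembly_mask)) low <- apply_mask(low, assembly_mask)
  if (!is.null(diverse_mask)) low <- apply_mask(low, diverse_mask)
  motif_iv <- NULL
  if (!is.null(generalized_motifs) && nrow(generalized_motifs) > 0L) {
    motif_iv <- generalized_motifs[, c("contig", "start", "end")]
  }
  if (!is.null(bad_promoters) && nrow(bad_promoters) > 0L) {
    motif_iv <- rbind(motif_iv, bad_promoters[, c("contig", "start", "end")])
  }
  if (!is.null(motif_iv)) {
    mm <- intervals_to_mask(motif_iv, ref)
    prov <- lapply(mm, function(v) 4L * as.integer(v))
    low <- apply_mask(low, prov)
  }
  intervals <- mask_to_intervals(low, label = "uncategorized")
  runs <- homopolymer_runs(ref)
  gc_frac <- numeric(nrow(intervals))
  hp_n50 <- integer(nrow(intervals))
  if (nrow(intervals) > 0L) {
    for (k in seq_len(nrow(intervals))) {
      ctg <- intervals$contig[k]
      idx <- (intervals$start[k] + 1L):intervals$end[k]
      ch <- ref$chars[[ctg]][idx]
      gc_frac[k] <- mean(ch == "G" | ch == "C")
      hp_n50[k] <- homopolymer_n50(intervals[k, ], ref, runs = runs)
    }
  }
  intervals$length <- intervals$end - intervals$start
  intervals$gc_fraction <- gc_frac
  intervals$homopolymer_n50 <- hp_n50
  total <- sum(intervals$length)
  structure(list(
    intervals = intervals,
    total_bases = total,
    genome_fraction = total / ref$included_base_count,
    interval_n50 = length_n50(intervals$length),
    excluded_by = excluded_by
  ), class = "DiscoveryReport")
}

#' @export
print.DiscoveryReport <- function(x, ...) {
  cat(sprintf(paste0("DiscoveryReport: %d interval(s), %s bases (%.3g%% of ",
                     "included genome), interval N50 = %s\n"),
              nrow(x$intervals), format(x$total_bases, big.mark = ","),
              100 * x$genome_fraction,
              ifelse(is.na(x$interval_n50), "NA", x$interval_n50)))
  eb <- x$excluded_by[x$excluded_by > 0]
  if (length(eb) > 0L) {
    cat("Undercovered bases excluded by filters:\n")
    for (nm in names(eb)) cat(sprintf("  %-20s %s\n", nm,
                                      format(eb[[nm]], big.mark = ",")))
  }
  invisible(x)
}

#' Write a discovery report as TSV
#'
#' One row per surviving interval with its coordinates, length, GC fraction
#' and homopolymer N50.
#'
#' @param report A `DiscoveryReport`.
#' @param path Output path.
#' @export
write_discovery_report <- function(report, path) {
  stopifnot(inherits(report, "DiscoveryReport"))
  df <- report$intervals[, c("contig", "start", "end", "length",
                             "gc_fraction", "homopolymer_n50")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
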