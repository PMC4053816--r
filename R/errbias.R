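#' Per-base error counts from an alignment file
#'
#' Attributes every alignment error to a reference base. A mismatch is an
#' M/=/X-aligned read base differing from the reference base (an N in the
#' read over an unambiguous reference base counts as a mismatch). A deletion
#' increments the counter of each reference base skipped by a D operator. An
#' insertion of length L charges L to the reference base immediately after
#' the inserted sequence; at record edges, a trailing insertion is charged
#' to the last preceding aligned base and a leading one to the first aligned
#' base, so counts are conserved. Records without a read sequence (SEQ "*")
#' are skipped with a logged count. The coverage computed from the same
#' records is carried along as the rate denominator.
#'
#' @param alignments Path to a SAM or BAM file, or a record list from
#'   [read_alignments()].
#' @param ref A `ReferenceModel`.
#' @return An `ErrorTrack`: per-contig integer vectors `mismatch`,
#'   `deletion`, `insertion`, plus the `CoverageTrack` denominator.
#' @export
count_errors <- function(alignments, ref) {
  stopifnot(inherits(ref, "ReferenceModel"))
  rec <- if (is.character(alignments)) read_alignments(alignments, ref) else
    alignments
  acc <- accumulate_records(rec, ref, count_errors = TRUE)
  structure(list(
    mismatch = acc$mm,
    deletion = acc$del,
    insertion = acc$ins,
    coverage = coverage_track(acc$cov, ref),
    contigs = ref$names,
    included = ref$included
  ), class = "ErrorTrack")
}

#' @export
print.ErrorTrack <- function(x, ...) {
  r <- error_rates(x)
  cat(sprintf(paste0("ErrorTrack: mismatch %.2g, deletion %.2g, insertion ",
                     "%.2g (total %.2g) over %s mapped bases\n"),
              r$mismatch_rate, r$deletion_rate, r$insertion_rate,
              r$total_rate, format(r$mapped_bases, big.mark = ",")))
  invisible(x)
}

sum_over_region <- function(vecs, included, contigs, region_mask = NULL) {
  total <- 0
  for (ctg in contigs) {
    keep <- included[[ctg]]
    if (!is.null(region_mask)) keep <- keep & region_mask[[ctg]]
    total <- total + sum(as.numeric(vecs[[ctg]][keep]))
  }
  total
}

#' Genome-wide or regional error rates
#'
#' Error rates are fractions: the error count in the region divided by the
#' number of mapped bases (coverage) in the region, summed over included
#' bases only.
#'
#' @param track An `ErrorTrack`.
#' @param region Optional interval data.frame restricting the computation;
#'   `NULL` means the whole (included) genome.
#' @return List with `mismatch_rate`, `deletion_rate`, `insertion_rate`,
#'   `total_rate` and `mapped_bases`; rates are `NA` when the region has no
#'   mapped bases.
#' @export
error_rates <- function(track, region = NULL) {
  stopifnot(inherits(track, "ErrorTrack"))
  region_mask <- NULL
  if (!is.null(region)) {
    ref_like <- list(lengths = track$coverage$lengths,
                     names = track$contigs)
    validate_intervals(region)
    region_mask <- lapply(track$coverage$lengths, function(L) logical(L))
    for (k in seq_len(nrow(region))) {
      ctg <- region$contig[k]
      region_mask[[ctg]][(region$start[k] + 1L):region$end[k]] <- TRUE
    }
  }
  denom <- sum_over_region(track$coverage$counts, track$included,
                           track$contigs, region_mask)
  num <- vapply(c("mismatch", "deletion", "insertion"), function(f)
    sum_over_region(track[[f]], track$included, track$contigs, region_mask),
    numeric(1L))
  if (denom == 0) {
    return(list(mismatch_rate = NA_real_, deletion_rate = NA_real_,
                insertion_rate = NA_real_, total_rate = NA_real_,
                mapped_bases = 0))
  }
  rates <- num / denom
  list(mismatch_rate = rates[[1L]], deletion_rate = rates[[2L]],
       insertion_rate = rates[[3L]], total_rate = sum(rates),
       mapped_bases = denom)
}

# Per-base GC bin: GC% of the 100-base window centered on the base, NA when
# the centered window is not fully inside an included region.
per_base_gc_bin <- function(gc_windows, contigs, lengths) {
  w <- gc_windows$window
  half <- w %/% 2L
  out <- vector("list", length(contigs))
  names(out) <- contigs
  for (ctg in contigs) {
    L <- lengths[[ctg]]
    gcv <- gc_windows$gc[[ctg]]
    bin <- rep(NA_integer_, L)
    if (length(gcv) > 0L) {
      # base i (1-based) gets the window starting at i - half (1-based),
      # i.e. covering [i - half, i + half) in 0-based coordinates
      i <- seq_len(L)
      ws <- i - half
      ok <- ws >= 1L & ws <= length(gcv)
      bin[ok] <- gcv[ws[ok]]
    }
    out[[ctg]] <- bin
  }
  out
}

# Per-base homopolymer-run length, capped at max_len; NA at masked bases.
per_base_run_length <- function(runs, contigs, lengths, max_len = 15L) {
  out <- vector("list", length(contigs))
  names(out) <- contigs
  for (ctg in contigs) {
    v <- rep(NA_integer_, lengths[[ctg]])
    r <- runs[runs$contig == ctg, , drop = FALSE]
    if (nrow(r) > 0L) {
      lens <- pmin(r$length, max_len)
      v[unlist(mapply(function(s, e) (s + 1L):e, r$start, r$end,
                      SIMPLIFY = FALSE), use.names = FALSE)] <-
        rep(lens, r$length)
    }
    out[[ctg]] <- v
  }
  out
}

#' Error-rate profile by GC content or homopolymer length
#'
#' Bins every included base either by the GC percentage of the 100-base
#' window centered on it (bases without a fully included centered window are
#' unbinned) or by the length of its containing homopolymer run (capped at
#' `max_hp`, so the top bin aggregates all longer runs), then computes
#' mismatch, deletion and insertion rates per bin as error counts over
#' mapped bases. GC bins are flagged reportable only where the genome holds
#' at least `min_windows` windows of that GC content, mirroring the
#' GC-bias-curve rule so panels are comparable.
#'
#' @param track An `ErrorTrack`.
#' @param by `"gc_percent"` or `"homopolymer_length"`.
#' @param ref The `ReferenceModel` the track was computed on.
#' @param gc_windows Optional precomputed [gc_percent_windows()] output.
#' @param runs Optional precomputed [homopolymer_runs()] output.
#' @param max_hp Homopolymer cap (default 15; the top bin is "max_hp or
#'   longer").
#' @param min_windows Reportability threshold for GC bins (default 1000).
#' @return An `ErrorRateProfile` data.frame: `bin`, `mapped_bases`,
#'   `mismatch_rate`, `deletion_rate`, `insertion_rate`, `reportable`.
#' @export
error_profile <- function(track, by = c("gc_percent", "homopolymer_length"),
                          ref, gc_windows = NULL, runs = NULL,
                          max_hp = 15L, min_windows = 1000L) {
  by <- match.arg(by)
  stopifnot(inherits(track, "ErrorTrack"), inherits(ref, "ReferenceModel"))
  if (by == "gc_percent") {
    if (is.null(gc_windows)) gc_windows <- gc_percent_windows(ref)
    bins <- per_base_gc_bin(gc_windows, track$contigs, ref$lengths)
    levels <- 0:100
    win_counts <- tabulate(unlist(lapply(gc_windows$gc, function(v)
      v[!is.na(v)]), use.names = FALSE) + 1L, nbins = 101L)
    reportable <- win_counts >= min_windows
  } else {
    if (is.null(runs)) runs <- homopolymer_runs(ref)
    bins <- per_base_run_length(runs, track$contigs, ref$lengths, max_hp)
    levels <- seq_len(max_hp)
    reportable <- rep(TRUE, length(levels))
  }
  agg <- function(vecs) {
    total <- numeric(length(levels))
    for (ctg in track$contigs) {
      b <- bins[[ctg]]
      keep <- track$included[[ctg]] & !is.na(b)
      if (!any(keep)) next
      idx <- match(b[keep], levels)
      total <- total + as.numeric(tapply(as.numeric(vecs[[ctg]][keep]),
                                         factor(idx, levels = seq_along(levels)),
                                         sum, default = 0))
    }
    total
  }
  denom <- agg(track$coverage$counts)
  mm <- agg(track$mismatch)
  del <- agg(track$deletion)
  ins <- agg(track$insertion)
  rate <- function(x) ifelse(denom > 0, x / denom, NA_real_)
  structure(data.frame(
    bin = levels,
    mapped_bases = denom,
    mismatch_rate = rate(mm),
    deletion_rate = rate(del),
    insertion_rate = rate(ins),
    reportable = reportable
  ), class = c("ErrorRateProfile", "data.frame"),
  by = by, max_hp = if (by == "homopolymer_length") max_hp else NA_integer_)
}
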