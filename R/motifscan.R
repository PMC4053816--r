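#' Bias motif specifications
#'
#' A bias motif is a window of `window` bases whose centered core of `core`
#' bases satisfies a base-composition predicate. Predicates:
#' \describe{
#'   \item{gc_max}{core GC content at most `threshold` percent}
#'   \item{gc_min}{core GC content at least `threshold` percent}
#'   \item{at_repeat}{core is a perfect alternating A/T dinucleotide repeat
#'     (either phase)}
#'   \item{gc_or_c_homopolymer_frac}{core is at least `threshold` percent G,
#'     or at least `threshold` percent C (matches long G or C homopolymers)}
#' }
#' GC thresholds compare integer base counts: a core of length C passes
#' `gc_min t` iff `#G + #C >= ceiling(t * C / 100)` and `gc_max t` iff
#' `#G + #C <= floor(t * C / 100)`, avoiding float comparisons at exact
#' thresholds.
#'
#' @param name Motif name (used as BED label).
#' @param window Full window length W.
#' @param core Centered core length C; `W - C` must be even.
#' @param predicate One of the predicates above.
#' @param threshold Percent threshold (ignored by `at_repeat`).
#' @return A `MotifSpec` object.
#' @export
motif_spec <- function(name, window, core, predicate, threshold = NA_real_) {
  predicate <- match.arg(predicate, c("gc_max", "gc_min", "at_repeat",
                                      "gc_or_c_homopolymer_frac"))
  window <- as.integer(window)
  core <- as.integer(core)
  stopifnot(core >= 1L, core <= window, (window - core) %% 2L == 0L)
  structure(list(name = name, window = window, core = core,
                 predicate = predicate, threshold = threshold),
            class = "MotifSpec")
}

#' @export
print.MotifSpec <- function(x, ...) {
  cat(sprintf("MotifSpec %s: %d-base window, %d-base core, %s%s\n",
              x$name, x$window, x$core, x$predicate,
              if (is.na(x$threshold)) "" else paste0(" @ ", x$threshold, "%")))
  invisible(x)
}

#' The standard (or generalized) bias motif set
#'
#' The standard set holds five motifs associated with coverage loss:
#' GC <= 10%, GC >= 75% and GC >= 85% (200-base windows, middle 100 bases),
#' (AT)^15 (130-base windows whose middle 30 bases are a perfect AT
#' dinucleotide repeat) and G|C >= 80% (130-base windows whose middle 30
#' bases are at least 80% G or 80% C). The generalized set relaxes each to
#' cover roughly twice as many bases — GC <= 13%, GC >= 70%, (AT)^10
#' (middle 20 bases) and G|C >= 75% — and is used to exclude
#' "similar to known motifs" regions in the discovery pipeline. Bad
#' promoters are an empirically derived interval list, not a scanned motif,
#' so they do not appear here.
#'
#' @param generalized If `TRUE` return the four generalized motifs, else the
#'   five standard ones.
#' @return A list of `MotifSpec` objects, named by motif.
#' @export
standard_motif_set <- function(generalized = FALSE) {
  specs <- if (!generalized) {
    list(
      motif_spec("gc_le10", 200L, 100L, "gc_max", 10),
      motif_spec("gc_ge75", 200L, 100L, "gc_min", 75),
      motif_spec("gc_ge85", 200L, 100L, "gc_min", 85),
      motif_spec("at15", 130L, 30L, "at_repeat"),
      motif_spec("gchomo80", 130L, 30L, "gc_or_c_homopolymer_frac", 80)
    )
  } else {
    list(
      motif_spec("gc_le13", 200L, 100L, "gc_max", 13),
      motif_spec("gc_ge70", 200L, 100L, "gc_min", 70),
      motif_spec("at10", 130L, 20L, "at_repeat"),
      motif_spec("gchomo75", 130L, 30L, "gc_or_c_homopolymer_frac", 75)
    )
  }
  names(specs) <- vapply(specs, `[[`, character(1L), "name")
  specs
}

# Sliding-window sum of an 0/1 integer vector; result[i] = sum(x[i..i+k-1]).
sliding_sum <- function(x, k) {
  cs <- cumsum(x)
  n <- length(x) - k + 1L
  if (n < 1L) return(integer(0L))
  idx <- seq_len(n)
  cs[idx + k - 1L] - c(0L, cs)[idx]
}

#' Scan a reference for a bias motif
#'
#' A window starting at 0-based position s is a hit when its centered core
#' satisfies the motif predicate and the full window contains only included
#' bases. Overlapping hit windows are merged into maximal intervals, so the
#' returned extents are unions of full W-base windows (the whole window is
#' the motif, not just the core).
#'
#' @param ref A `ReferenceModel`.
#' @param spec A `MotifSpec`.
#' @return Merged interval data.frame labeled with the motif name.
#' @export
scan_motif <- function(ref, spec) {
  stopifnot(inherits(ref, "ReferenceModel"), inherits(spec, "MotifSpec"))
  W <- spec$window
  C <- spec$core
  off <- (W - C) %/% 2L
  hits <- vector("list", length(ref$names))
  for (i in seq_along(ref$names)) {
    ch <- ref$chars[[i]]
    L <- length(ch)
    if (L < W) next
    nwin <- L - W + 1L
    full <- sliding_sum(as.integer(ref$included[[i]]), W) == W
    core_ok <- switch(
      spec$predicate,
      gc_min = {
        t <- as.integer(ceiling(spec$threshold * C / 100))
        s <- sliding_sum(as.integer(ch == "G" | ch == "C"), C)
        s >= t
      },
      gc_max = {
        t <- as.integer(floor(spec$threshold * C / 100))
        s <- sliding_sum(as.integer(ch == "G" | ch == "C"), C)
        s <= t
      },
      at_repeat = {
        at <- ch == "A" | ch == "T"
        # pair indicator: positions i where (i, i+1) are alternating A/T
        d <- at[-L] & at[-1L] & ch[-L] != ch[-1L]
        if (C == 1L) at[seq_len(L - C + 1L)] else
          sliding_sum(as.integer(d), C - 1L)[seq_len(L - C + 1L)] == C - 1L
      },
      gc_or_c_homopolymer_frac = {
        t <- as.integer(ceiling(spec$threshold * C / 100))
        sliding_sum(as.integer(ch == "G"), C) >= t |
          sliding_sum(as.integer(ch == "C"), C) >= t
      }
    )
    ok <- full & core_ok[off + seq_len(nwin)]
    w <- which(ok)
    if (length(w) > 0L) {
      hits[[i]] <- genomic_intervals(ref$names[i], w - 1L, w - 1L + W,
                                     label = spec$name)
    }
  }
  res <- do.call(rbind, hits)
  if (is.null(res)) return(genomic_intervals())
  merge_intervals(res, label = spec$name)
}

#' Genomic extent of a motif's intervals
#'
#' Number of distinct included bases covered by the union of the intervals,
#' and that count as a fraction of all included bases.
#'
#' @param intervals Interval data.frame (e.g. from [scan_motif()]).
#' @param ref A `ReferenceModel`.
#' @return List with `base_count` and `fraction`.
#' @export
motif_extent <- function(intervals, ref) {
  validate_intervals(intervals, ref)
  if (nrow(intervals) == 0L) {
    return(list(base_count = 0L, fraction = 0))
  }
  merged <- merge_intervals(intervals)
  count <- 0
  for (ctg in unique(merged$contig)) {
    d <- merged[merged$contig == ctg, , drop = FALSE]
    ci <- c(0, cumsum(ref$included[[ctg]]))
    count <- count + sum(ci[d$end + 1L] - ci[d$start + 1L])
  }
  list(base_count = as.integer(count),
       fraction = count / ref$included_base_count)
}
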