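#' Downsample an alignment file to a target mean coverage
#'
#' Retains whole read pairs (all records sharing a QNAME are kept or dropped
#' as a unit, so mates are never split) independently with probability
#' `target_mean / current_mean`. Sampling is deterministic under a fixed
#' seed: the same seed yields a byte-identical retained-record set.
#'
#' @param alignments Path to a SAM text file (the simulator's native
#'   output; BAM input is first converted through `Rsamtools::asBam`'s
#'   inverse, `asSam`).
#' @param out Path for the filtered SAM.
#' @param current_mean Mean coverage of the input.
#' @param target_mean Desired mean coverage; must not exceed `current_mean`.
#' @param seed Integer seed.
#' @return `out`, invisibly.
#' @export
downsample_alignments <- function(alignments, out, current_mean, target_mean,
                                  seed) {
  if (target_mean > current_mean) {
    stop("target coverage (", target_mean,
         ") exceeds current coverage (", current_mean, ")")
  }
  stopifnot(target_mean > 0)
  sam <- alignments
  if (grepl("\\.bam$", alignments, ignore.case = TRUE)) {
    sam <- Rsamtools::asSam(alignments, tempfile(), overwrite = TRUE)
  }
  p <- target_mean / current_mean
  lines <- readLines(sam)
  is_header <- startsWith(lines, "@")
  body <- lines[!is_header]
  qn <- sub("\t.*$", "", body)
  uq <- unique(qn)
  set.seed(as.integer(seed))
  keep_q <- uq[stats::runif(length(uq)) < p]
  keep <- qn %in% keep_q
  writeLines(c(lines[is_header], body[keep]), out)
  invisible(out)
}

# In-memory pair-level downsampling of a record list (fast path used by the
# stability assay so the SAM is parsed once).
downsample_records <- function(records, p, seed) {
  uq <- unique(records$qname)
  set.seed(as.integer(seed))
  keep_q <- uq[stats::runif(length(uq)) < p]
  keep <- records$qname %in% keep_q
  lapply(records, `[`, keep)
}

#' Combine two coverage tracks
#'
#' Models a mixed-technology data set: per-base counts add, and so does the
#' mean. Both tracks must be computed on the same reference and mask.
#'
#' @param a,b `CoverageTrack`s on identical references.
#' @return A `CoverageTrack` for the merged data.
#' @export
combine_tracks <- function(a, b) {
  stopifnot(inherits(a, "CoverageTrack"), inherits(b, "CoverageTrack"))
  if (!identical(a$contigs, b$contigs) ||
      !identical(a$lengths, b$lengths) ||
      !identical(a$included, b$included)) {
    stop("coverage tracks were computed on different references or masks")
  }
  counts <- a$counts
  for (ctg in a$contigs) counts[[ctg]] <- counts[[ctg]] + b$counts[[ctg]]
  ref_like <- structure(list(names = a$contigs, lengths = a$lengths,
                             included = a$included,
                             included_base_count = a$included_base_count),
                        class = "ReferenceModel")
  coverage_track(counts, ref_like)
}

#' Technology-mixture undercoverage experiment
#'
#' Downsamples each component alignment set to `per_component_mean`,
#' combines the sampled tracks, and reports undercoverage fractions of the
#' mixture alongside each pure component downsampled to the matched total
#' depth — the comparison that shows whether two technologies' biases are
#' complementary (mixture better than both) or merely intermediate.
#'
#' @param a,b Paths to SAM files for the two components.
#' @param ref A `ReferenceModel`.
#' @param per_component_mean Sampled depth per component (default 50, for a
#'   100x total mixture).
#' @param thresholds Undercoverage thresholds.
#' @param seed Integer seed (component b uses `seed + 1`).
#' @return List with `mixture`, `component_a`, `component_b` undercoverage
#'   data.frames and the realized means.
#' @export
mix_experiment <- function(a, b, ref, per_component_mean = 50,
                           thresholds = c(0, 0.1, 0.25, 0.5), seed = 1L) {
  rec_a <- read_alignments(a, ref)
  rec_b <- read_alignments(b, ref)
  cov_a <- compute_coverage(rec_a, ref)
  cov_b <- compute_coverage(rec_b, ref)
  total <- 2 * per_component_mean
  samp <- function(rec, mu, target, sd) {
    if (target > mu) stop("target coverage ", target,
                          " exceeds available coverage ", round(mu, 2))
    compute_coverage(downsample_records(rec, target / mu, sd), ref)
  }
  half_a <- samp(rec_a, cov_a$mu, per_component_mean, seed)
  half_b <- samp(rec_b, cov_b$mu, per_component_mean, seed + 1L)
  full_a <- samp(rec_a, cov_a$mu, total, seed + 2L)
  full_b <- samp(rec_b, cov_b$mu, total, seed + 3L)
  mixed <- combine_tracks(half_a, half_b)
  list(
    mixture = undercoverage_fractions(relative_coverage(mixed), thresholds),
    component_a = undercoverage_fractions(relative_coverage(full_a), thresholds),
    component_b = undercoverage_fractions(relative_coverage(full_b), thresholds),
    mean_mixture = mixed$mu, mean_a = full_a$mu, mean_b = full_b$mu
  )
}

#' Subsample stability of motif relative coverage
#'
#' Repeatedly downsamples a data set to a low target depth and recomputes
#' the relative coverage of each motif, reporting the mean and standard
#' deviation across replicates next to the full-depth value. Motif
#' statistics aggregate many loci, so they remain stable at depths far below
#' what per-base statistics require; this assay quantifies that stability.
#'
#' @param alignments Path to a SAM/BAM file or a record list.
#' @param ref A `ReferenceModel`.
#' @param motifs Named list of interval data.frames (one per motif).
#' @param target_mean Depth of each random subset (default 0.5).
#' @param reps Number of replicates (default 10).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return Data.frame with `motif`, `full_value`, `mean`, `sd`,
#'   `max_abs_dev` (largest |replicate - full| across replicates).
#' @export
subsample_stability <- function(alignments, ref, motifs, target_mean = 0.5,
                                reps = 10L, seed = 1L) {
  stopifnot(reps >= 2L, is.list(motifs), length(motifs) > 0L)
  rec <- if (is.character(alignments)) read_alignments(alignments, ref) else
    alignments
  full_cov <- compute_coverage(rec, ref)
  if (target_mean > full_cov$mu) {
    stop("target coverage exceeds full-depth coverage")
  }
  p <- target_mean / full_cov$mu
  full_rel <- relative_coverage(full_cov)
  full_val <- vapply(motifs, function(m) motif_relative_coverage(full_rel, m),
                     numeric(1L))
  vals <- matrix(NA_real_, nrow = reps, ncol = length(motifs))
  for (r in seq_len(reps)) {
    sub <- downsample_records(rec, p, seed + r)
    rel <- relative_coverage(compute_coverage(sub, ref))
    vals[r, ] <- vapply(motifs, function(m) motif_relative_coverage(rel, m),
                        numeric(1L))
  }
  data.frame(
    motif = names(motifs),
    full_value = full_val,
    mean = colMeans(vals),
    sd = apply(vals, 2L, stats::sd),
    max_abs_dev = apply(abs(sweep(vals, 2L, full_val)), 2L, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
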