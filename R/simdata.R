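#' Configuration for the synthetic-data generator
#'
#' The generator emulates the bias phenomenology the assays measure:
#' fragment start positions are sampled with probability proportional to a
#' GC-dependent weight (producing GC coverage bias), per-base error rates
#' can be multiplied up in chosen GC or homopolymer contexts (producing
#' error bias), and arbitrary loci can be depressed (emulating
#' promoter-like or uncategorized coverage loss). Reads are emitted already
#' aligned, with an exact event log, so the assays can be validated against
#' ground truth without an aligner in the loop.
#'
#' Defaults describe the reference condition used throughout the package's
#' validation: a 1 Mb genome at 50% GC, 100-base single-end reads at
#' 50-fold depth, and Illumina-HiSeq-like error rates (mismatch 3.0e-3,
#' deletion 2.3e-4, insertion 1.7e-4).
#'
#' @param genome_length Total genome length in bases (single contig named
#'   `"sim"` unless `gc_tracts` carries several rows, which are
#'   concatenated).
#' @param gc_tracts Data.frame with columns `length` and `gc` (percent
#'   0..100); tracts are concatenated in order. `NULL` means one uniform
#'   tract of `genome_length` bases at 50% GC.
#' @param read_length Read length in bases.
#' @param paired Emit read pairs (two reads per fragment) instead of
#'   single-end reads.
#' @param fragment_length Outer distance between paired-read starts
#'   (default 300; ignored for single-end).
#' @param target_depth Target mean coverage.
#' @param coverage_bias `NULL` (uniform) or a function mapping a vector of
#'   integer GC percentages (of the 100-base window centered on the
#'   fragment start) to non-negative sampling weights.
#' @param error_rates Named numeric vector with `mismatch`, `deletion`,
#'   `insertion` per-base rates, each in [0, 1).
#' @param gc_error_multipliers `NULL` or a named list of functions
#'   (`mismatch`, `deletion`, `insertion`), each mapping per-base GC
#'   percentages to rate multipliers.
#' @param homopolymer_multipliers `NULL` or a named list of functions
#'   mapping per-base homopolymer run length (capped at 15) to rate
#'   multipliers.
#' @param planted_sequences `NULL` or data.frame with `type`
#'   (`"homopolymer"` or `"at_repeat"`), `start` (0-based), `length`, and
#'   `base` (for homopolymers) — sequence features written into the
#'   reference for motif and error-context tests.
#' @param planted_weights `NULL` or data.frame with `start`, `end`
#'   (0-based half-open) and `weight` — multiplicative depressions (or
#'   enrichments) applied to every fragment start whose read would overlap
#'   the interval.
#' @param seed Integer seed; the reference uses `seed` and read simulation
#'   `seed + 1`, so both are reproducible independently.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(genome_length = 1e6, gc_tracts = NULL,
                       read_length = 100L, paired = FALSE,
                       fragment_length = 300L, target_depth = 50,
                       coverage_bias = NULL,
                       error_rates = c(mismatch = 0.0030,
                                       deletion = 0.00023,
                                       insertion = 0.00017),
                       gc_error_multipliers = NULL,
                       homopolymer_multipliers = NULL,
                       planted_sequences = NULL, planted_weights = NULL,
                       seed = 1L) {
  genome_length <- as.integer(genome_length)
  if (is.null(gc_tracts)) {
    gc_tracts <- data.frame(length = genome_length, gc = 50)
  }
  stopifnot(all(c("length", "gc") %in% names(gc_tracts)))
  if (any(gc_tracts$gc < 0 | gc_tracts$gc > 100)) {
    stop("infeasible GC target: must be between 0 and 100 percent")
  }
  genome_length <- as.integer(sum(gc_tracts$length))
  stopifnot(genome_length >= read_length,
            all(error_rates >= 0), all(error_rates < 1),
            all(c("mismatch", "deletion", "insertion") %in%
                  names(error_rates)))
  if (!is.null(planted_weights)) {
    stopifnot(all(planted_weights$weight >= 0))
  }
  structure(list(
    genome_length = genome_length, gc_tracts = gc_tracts,
    read_length = as.integer(read_length), paired = isTRUE(paired),
    fragment_length = as.integer(fragment_length),
    target_depth = target_depth, coverage_bias = coverage_bias,
    error_rates = error_rates,
    gc_error_multipliers = gc_error_multipliers,
    homopolymer_multipliers = homopolymer_multipliers,
    planted_sequences = planted_sequences,
    planted_weights = planted_weights,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

#' Simulate a reference genome
#'
#' Draws each base independently with P(G) = P(C) = gc/2 within each GC
#' tract, then writes any planted sequence features over the draw. Realized
#' tract GC concentrates within 2 percentage points of target for tracts of
#' 10 kb or more. Deterministic under the config seed.
#'
#' @param config A `SimConfig`.
#' @param fasta_path Optional path; when given, the reference is also
#'   written as FASTA.
#' @return A `ReferenceModel` with a single contig `"sim"`.
#' @export
simulate_reference <- function(config, fasta_path = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  parts <- lapply(seq_len(nrow(config$gc_tracts)), function(i) {
    n <- config$gc_tracts$length[i]
    g <- config$gc_tracts$gc[i] / 100
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2))
  })
  ch <- unlist(parts, use.names = FALSE)
  ps <- config$planted_sequences
  if (!is.null(ps)) {
    for (k in seq_len(nrow(ps))) {
      s <- as.integer(ps$start[k])
      len <- as.integer(ps$length[k])
      stopifnot(s >= 0L, s + len <= length(ch))
      idx <- (s + 1L):(s + len)
      if (ps$type[k] == "homopolymer") {
        ch[idx] <- as.character(ps$base[k])
      } else if (ps$type[k] == "at_repeat") {
        ch[idx] <- rep_len(c("A", "T"), len)
      } else {
        stop("unknown planted sequence type: ", ps$type[k])
      }
    }
  }
  seqs <- c(sim = paste(ch, collapse = ""))
  ref <- new_reference_model(seqs)
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  }
  ref
}

# Per-base error-rate vectors for one contig: base rate x GC-context
# multiplier x homopolymer-context multiplier.
per_base_error_rates <- function(ref, ctg, config, gcw, runs) {
  L <- ref$lengths[[ctg]]
  gc_bin <- per_base_gc_bin(gcw, ctg, ref$lengths[ctg])[[ctg]]
  run_len <- per_base_run_length(runs, ctg, ref$lengths[ctg])[[ctg]]
  out <- list()
  for (type in c("mismatch", "deletion", "insertion")) {
    r <- rep(config$error_rates[[type]], L)
    f_gc <- config$gc_error_multipliers[[type]]
    if (!is.null(f_gc)) {
      m <- rep(1, L)
      ok <- !is.na(gc_bin)
      m[ok] <- f_gc(gc_bin[ok])
      r <- r * m
    }
    f_hp <- config$homopolymer_multipliers[[type]]
    if (!is.null(f_hp)) {
      m <- rep(1, L)
      ok <- !is.na(run_len)
      m[ok] <- f_hp(run_len[ok])
      r <- r * m
    }
    if (any(r >= 1)) stop("context multipliers push the ", type,
                          " rate to 1 or above")
    out[[type]] <- r
  }
  out
}

#' Simulate aligned reads with a ground-truth event log
#'
#' Fragment starts are sampled with probability proportional to
#' `coverage_bias(GC)` evaluated at the GC percentage of the 100-base window
#' centered on the start (uniform where the window is unavailable), further
#' multiplied by any planted locus weights for starts whose read overlaps
#' the locus. Errors are injected per base at the configured context-
#' dependent rates; emitted records carry the CIGAR and SEQ that make the
#' error-attribution conventions of [count_errors()] recover the injected
#' events exactly. Records are coordinate-sorted SAM. Deterministic under
#' `config$seed + 1`.
#'
#' @param ref A `ReferenceModel` (typically from [simulate_reference()]).
#' @param config A `SimConfig`.
#' @param sam_path Path for the output SAM (default: a tempfile).
#' @return A `SimReads` list: `sam` (path), `events` (data.frame `read`,
#'   `type`, `contig`, `pos` 0-based, `length`), `n_reads`, `event_counts`
#'   (named totals by type).
#' @export
simulate_alignments <- function(ref, config, sam_path = tempfile(fileext = ".sam")) {
  stopifnot(inherits(ref, "ReferenceModel"), inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  rl <- config$read_length
  gcw <- gc_percent_windows(ref)
  runs <- homopolymer_runs(ref)
  all_qname <- all_flag <- all_rname <- all_cigar <- all_seq <- character(0L)
  all_pos <- all_pnext <- all_tlen <- integer(0L)
  ev <- list()
  total_reads <- 0L
  for (ctg in ref$names) {
    L <- ref$lengths[[ctg]]
    span <- if (config$paired) config$fragment_length else rl
    if (L < span) next
    ndom <- L - span + 1L
    # start weights from the GC-bias function on centered windows
    w <- rep(1, ndom)
    if (!is.null(config$coverage_bias)) {
      gcv <- gcw$gc[[ctg]]
      s0 <- seq_len(ndom) - 1L               # 0-based starts
      ws <- s0 + 1L - 50L                    # 1-based window index
      ok <- ws >= 1L & ws <= length(gcv)
      gcb <- rep(NA_integer_, ndom)
      gcb[ok] <- gcv[ws[ok]]
      have <- !is.na(gcb)
      w[have] <- config$coverage_bias(gcb[have])
      if (any(w < 0)) stop("coverage_bias returned negative weights")
    }
    pw <- config$planted_weights
    if (!is.null(pw)) {
      for (k in seq_len(nrow(pw))) {
        lo <- max(0L, as.integer(pw$start[k]) - span + 1L)
        hi <- min(ndom - 1L, as.integer(pw$end[k]) - 1L)
        if (lo <= hi) {
          w[(lo + 1L):(hi + 1L)] <- w[(lo + 1L):(hi + 1L)] * pw$weight[k]
        }
      }
    }
    n_frag <- as.integer(round(config$target_depth * L /
                                 (rl * (if (config$paired) 2 else 1))))
    if (n_frag == 0L) next
    cw <- cumsum(w)
    u <- stats::runif(n_frag) * cw[ndom]
    starts <- sort(findInterval(u, cw))       # 0-based fragment starts
    rates <- per_base_error_rates(ref, ctg, config, gcw, runs)
    if (config$paired) {
      r1 <- starts
      r2 <- starts + span - rl
      read_starts <- c(rbind(r1, r2))
    } else {
      read_starts <- starts
    }
    sim <- simulate_reads_cpp(as.integer(read_starts), rl, ref$seqs[[ctg]],
                              rates$mismatch, rates$deletion,
                              rates$insertion)
    n_reads <- length(read_starts)
    if (config$paired) {
      frag_id <- rep(seq_along(starts), each = 2L)
      qname <- sprintf("%s_f%07d", ctg, frag_id)
      first <- rep(c(TRUE, FALSE), length(starts))
      flag <- ifelse(first, 99L, 147L)
      mate_pos <- ifelse(first, read_starts + span - rl, read_starts - span + rl)
      pnext <- as.integer(mate_pos) + 1L
      tlen <- ifelse(first, span, -span)
      ord <- order(read_starts)
    } else {
      qname <- sprintf("%s_r%07d", ctg, seq_len(n_reads))
      flag <- rep(0L, n_reads)
      pnext <- rep(0L, n_reads)
      tlen <- rep(0L, n_reads)
      ord <- seq_len(n_reads)
    }
    if (length(sim$ev_read) > 0L) {
      ev[[ctg]] <- data.frame(
        read = qname[sim$ev_read],
        type = c("mismatch", "deletion", "insertion")[sim$ev_type],
        contig = ctg,
        pos = sim$ev_pos,
        length = sim$ev_len,
        stringsAsFactors = FALSE
      )
    }
    all_qname <- c(all_qname, qname[ord])
    all_flag <- c(all_flag, as.character(flag[ord]))
    all_rname <- c(all_rname, rep(ctg, n_reads))
    all_pos <- c(all_pos, as.integer(read_starts[ord]) + 1L)
    all_cigar <- c(all_cigar, as.character(sim$cigar)[ord])
    all_seq <- c(all_seq, as.character(sim$seq)[ord])
    all_pnext <- c(all_pnext, pnext[ord])
    all_tlen <- c(all_tlen, tlen[ord])
    total_reads <- total_reads + n_reads
  }
  con <- file(sam_path, open = "wt")
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref$names, ref$lengths), con)
  if (total_reads > 0L) {
    paired <- config$paired
    writeLines(paste(all_qname, all_flag, all_rname, all_pos, 60L, all_cigar,
                     if (paired) "=" else "*",
                     if (paired) all_pnext else 0L,
                     if (paired) all_tlen else 0L,
                     all_seq, "*", sep = "\t"), con)
  }
  close(con)
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    events <- data.frame(read = character(0), type = character(0),
                         contig = character(0), pos = integer(0),
                         length = integer(0), stringsAsFactors = FALSE)
  }
  rownames(events) <- NULL
  counts <- vapply(c("mismatch", "deletion", "insertion"), function(t)
    sum(events$length[events$type == t]), numeric(1L))
  structure(list(sam = sam_path, events = events, n_reads = total_reads,
                 event_counts = counts),
            class = "SimReads")
}

#' @export
print.SimReads <- function(x, ...) {
  cat(sprintf("SimReads: %d reads -> %s; events: %d mismatch, %d deletion, %d insertion\n",
              x$n_reads, x$sam, x$event_counts[["mismatch"]],
              x$event_counts[["deletion"]], x$event_counts[["insertion"]]))
  invisible(x)
}
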