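# Fixtures are built in code: references from strings, SAM files from record
# tables, coverage/relative tracks from explicit count vectors.

write_test_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "wt")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    # wrap lines to exercise multi-line FASTA parsing
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  close(con)
  path
}

make_ref <- function(seqs, ...) new_reference_model(seqs, ...)

# Write a SAM file for a record table with columns rname, pos (1-based),
# cigar, seq, and optional qname/flag.
write_test_sam <- function(ref, records, path = tempfile(fileext = ".sam")) {
  con <- file(path, "wt")
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref$names, ref$lengths), con)
  n <- nrow(records)
  qname <- if (!is.null(records$qname)) records$qname else
    sprintf("r%04d", seq_len(n))
  flag <- if (!is.null(records$flag)) records$flag else rep(0L, n)
  if (n > 0L) {
    writeLines(paste(qname, flag, records$rname, records$pos, 60L,
                     records$cigar, "*", 0L, 0L, records$seq, "*",
                     sep = "\t"), con)
  }
  close(con)
  path
}

# Coverage track over a single-contig reference built from explicit counts.
make_track <- function(counts, seq = NULL) {
  if (is.null(seq)) seq <- strrep("A", length(counts))
  ref <- make_ref(c(chr = seq))
  coverage_track(list(chr = as.integer(counts)), ref)
}

# Relative-coverage track with the exact values given (for filter tests).
make_rel <- function(values, seq = NULL) {
  if (is.null(seq)) seq <- strrep("A", length(values))
  ref <- make_ref(c(chr = seq))
  structure(list(
    values = list(chr = as.numeric(values)),
    included = ref$included,
    contigs = ref$names,
    lengths = ref$lengths,
    included_base_count = ref$included_base_count,
    mu = 1
  ), class = "RelativeCoverageTrack")
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Logical base mask (single contig "x") for an interval set.
intervals_mask_helper <- function(intervals, ref) {
  m <- logical(ref$lengths[["x"]])
  for (k in seq_len(nrow(intervals))) {
    m[(intervals$start[k] + 1L):intervals$end[k]] <- TRUE
  }
  m
}

included_values <- function(rel) {
  unlist(mapply(function(v, i) v[i], rel$values, rel$included,
                SIMPLIFY = FALSE), use.names = FALSE)
}
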