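# Independent brute-force oracles, kept deliberately naive: every quantity is
# recomputed per window/element with explicit slices and integer arithmetic,
# with no sliding sums and no interval machinery.

brute_scan_motif <- function(chars, included, spec) {
  L <- length(chars)
  W <- spec$window
  C <- spec$core
  off <- (W - C) %/% 2L
  hit <- logical(L)
  if (L >= W) {
    for (s in 0:(L - W)) {
      win <- (s + 1L):(s + W)
      if (!all(included[win])) next
      core <- chars[(s + off + 1L):(s + off + C)]
      ok <- switch(spec$predicate,
        gc_min = 100L * sum(core == "G" | core == "C") >= spec$threshold * C,
        gc_max = 100L * sum(core == "G" | core == "C") <= spec$threshold * C,
        at_repeat = all(core %in% c("A", "T")) &&
          (C < 2L || all(core[-1L] != core[-C])),
        gc_or_c_homopolymer_frac =
          100L * sum(core == "G") >= spec$threshold * C ||
          100L * sum(core == "C") >= spec$threshold * C
      )
      if (ok) hit[win] <- TRUE
    }
  }
  # maximal runs of hit bases
  out <- NULL
  r <- rle(hit)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- which(r$values)
  if (length(keep) > 0L) {
    out <- data.frame(start = s[keep], end = e[keep])
  } else {
    out <- data.frame(start = integer(0), end = integer(0))
  }
  out
}

brute_n50 <- function(lengths) {
  lengths <- sort(lengths[lengths > 0], decreasing = TRUE)
  if (length(lengths) == 0L) return(NA_integer_)
  half <- sum(lengths) / 2
  acc <- 0
  for (l in lengths) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# Sequence generator with enough compositional variety to exercise every
# motif predicate: random GC level plus occasional planted AT tracts and
# G/C homopolymers.
varied_seq <- function(n) {
  gc <- stats::runif(1, 0.05, 0.95)
  ch <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  for (k in seq_len(3L)) {
    len <- sample(20:60, 1L)
    s <- sample(n - len, 1L)
    ch[s:(s + len - 1L)] <- rep_len(c("A", "T"), len)
  }
  for (k in seq_len(3L)) {
    len <- sample(15:40, 1L)
    s <- sample(n - len, 1L)
    ch[s:(s + len - 1L)] <- sample(c("C", "G"), 1L)
  }
  paste(ch, collapse = "")
}
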