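#' Load a reference genome and build its inclusion mask
#'
#' Reads a (possibly multi-contig, line-wrapped) FASTA file and applies the
#' region-selection policy used by every bias statistic in the package: only
#' contigs selected by the policy contribute, and every ambiguous base (any
#' character other than A, C, G, T after upper-casing) is excluded, because
#' reads cannot be mapped to ambiguous positions nor can such positions be
#' assessed for motif membership.
#'
#' @param fasta_path Path to a readable FASTA file.
#' @param contig_policy Either `"all"` (every contig is eligible) or
#'   `"named_subset"` (only contigs named in `contigs` are eligible; the
#'   others remain in the model but are fully masked). Use `"named_subset"`
#'   to restrict statistics to chromosomal/autosomal contigs while still
#'   aligning reads to the complete reference.
#' @param contigs Character vector of contig names to keep when
#'   `contig_policy = "named_subset"`.
#' @return A `ReferenceModel` object: a list with elements `names` (contig
#'   order as in the file), `seqs` (upper-cased character vector of
#'   sequences), `chars` (list of per-base character vectors), `included`
#'   (list of per-base logical masks), `lengths`, `policy` and
#'   `included_base_count`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTNACGT"), fa)
#' ref <- load_reference(fa)
#' ref$included_base_count  # 8: the N is masked
#' @export
load_reference <- function(fasta_path, contig_policy = c("all", "named_subset"),
                           contigs = NULL) {
  contig_policy <- match.arg(contig_policy)
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", fasta_path)
  }
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate contig names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  if (contig_policy == "named_subset") {
    if (is.null(contigs) || length(contigs) == 0L) {
      stop("contig_policy 'named_subset' requires a non-empty 'contigs' vector")
    }
    missing <- setdiff(contigs, nm)
    if (length(missing) > 0L) {
      stop("contigs not present in FASTA: ", paste(missing, collapse = ", "))
    }
  }
  new_reference_model(seqs, policy = contig_policy, selected = contigs)
}

#' Construct a ReferenceModel from in-memory sequences
#'
#' Used by [load_reference()] and by the simulator; also handy in tests.
#'
#' @param seqs Named character vector of contig sequences (any case).
#' @param policy `"all"` or `"named_subset"`.
#' @param selected Contig names retained under `"named_subset"`.
#' @return A `ReferenceModel`.
#' @export
new_reference_model <- function(seqs, policy = "all", selected = NULL) {
  stopifnot(is.character(seqs), length(seqs) > 0L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  nm <- names(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  eligible <- if (identical(policy, "named_subset")) nm %in% selected else
    rep(TRUE, length(nm))
  included <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    ok <- chars[[i]] %in% c("A", "C", "G", "T")
    if (!eligible[i]) ok[] <- FALSE
    included[[i]] <- ok
  }
  names(included) <- nm
  obj <- list(
    names = nm,
    seqs = seqs,
    chars = chars,
    included = included,
    lengths = vapply(chars, length, integer(1L)),
    policy = policy,
    selected = if (identical(policy, "named_subset")) selected else nm,
    included_base_count = sum(vapply(included, sum, numeric(1L)))
  )
  class(obj) <- "ReferenceModel"
  obj
}

#' @export
print.ReferenceModel <- function(x, ...) {
  cat("ReferenceModel:", length(x$names), "contig(s),",
      format(sum(x$lengths), big.mark = ","), "bases,",
      format(x$included_base_count, big.mark = ","), "included",
      sprintf("(policy: %s)\n", x$policy))
  invisible(x)
}

#' GC percentage of sliding windows
#'
#' Computes, for every window start where the whole window lies inside one
#' contig and contains only included bases, the integer GC percentage
#' `round(100 * (#G + #C) / window)`. Windows touching any masked base are
#' omitted (reported as `NA`), mirroring the exclusion of ambiguous regions
#' from all bias computations. Windows slide with step 1.
#'
#' @param ref A `ReferenceModel`.
#' @param window Window size in bases (default 100, the convention used by
#'   GC-bias curves and GC error profiles).
#' @return An object of class `gc_windows`: list with `window` and `gc`, the
#'   latter a per-contig integer vector indexed by 0-based window start
#'   (length `contig_length - window + 1`, `NA` where the window is invalid).
#' @export
gc_percent_windows <- function(ref, window = 100L) {
  stopifnot(inherits(ref, "ReferenceModel"), window >= 1L)
  window <- as.integer(window)
  gc <- vector("list", length(ref$names))
  names(gc) <- ref$names
  for (i in seq_along(ref$names)) {
    ch <- ref$chars[[i]]
    L <- length(ch)
    if (L < window) {
      gc[[i]] <- integer(0L)
      next
    }
    is_gc <- as.integer(ch == "G" | ch == "C")
    inc <- as.integer(ref$included[[i]])
    cg <- cumsum(is_gc)
    ci <- cumsum(inc)
    n <- L - window + 1L
    idx <- seq_len(n)
    gcount <- cg[idx + window - 1L] - c(0L, cg)[idx]
    icount <- ci[idx + window - 1L] - c(0L, ci)[idx]
    v <- as.integer(round(100 * gcount / window))
    v[icount < window] <- NA_integer_
    gc[[i]] <- v
  }
  structure(list(window = window, gc = gc), class = "gc_windows")
}

#' Maximal homopolymer runs of a reference
#'
#' Partitions every included, unambiguous base into maximal runs of identical
#' bases. Runs never span masked bases (a masked base terminates the run on
#' both sides), and length-1 runs are kept so that error binning by
#' homopolymer length covers every base.
#'
#' @param ref A `ReferenceModel`.
#' @return A data.frame with columns `contig`, `start` (0-based), `end`
#'   (exclusive), `base`, `length`.
#' @export
homopolymer_runs <- function(ref) {
  stopifnot(inherits(ref, "ReferenceModel"))
  out <- vector("list", length(ref$names))
  for (i in seq_along(ref$names)) {
    ch <- ref$chars[[i]]
    inc <- ref$included[[i]]
    if (!any(inc)) {
      out[[i]] <- NULL
      next
    }
    x <- ch
    # give each masked base a unique token so it forms its own (dropped) run
    bad <- which(!inc)
    if (length(bad) > 0L) x[bad] <- paste0(".", seq_along(bad))
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based starts
    keep <- r$values %in% c("A", "C", "G", "T")
    out[[i]] <- data.frame(
      contig = ref$names[i],
      start = starts[keep],
      end = ends[keep],
      base = r$values[keep],
      length = r$lengths[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), base = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# N50 of a vector of element lengths: the smallest L such that elements of
# length >= L account for at least half the summed length. NA on empty input.
length_n50 <- function(lengths) {
  lengths <- lengths[lengths > 0]
  if (length(lengths) == 0L) return(NA_integer_)
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  cum <- cumsum(s)
  s[which(cum >= total / 2)[1L]]
}

#' Homopolymer N50 of a genomic interval
#'
#' N50 of the lengths of homopolymer runs clipped to the interval: the
#' smallest length L such that (clipped) runs of length >= L cover at least
#' half of the interval's run-covered bases. Used to annotate undercovered
#' intervals in the discovery report.
#'
#' @param interval A list or one-row data.frame with `contig`, `start`
#'   (0-based), `end` (exclusive).
#' @param ref A `ReferenceModel`.
#' @param runs Optional precomputed output of [homopolymer_runs()] (saves
#'   recomputation when annotating many intervals).
#' @return Integer N50, or `NA` for a fully masked interval.
#' @export
homopolymer_n50 <- function(interval, ref, runs = NULL) {
  stopifnot(inherits(ref, "ReferenceModel"))
  if (is.null(runs)) runs <- homopolymer_runs(ref)
  ctg <- as.character(interval$contig)
  s <- as.integer(interval$start)
  e <- as.integer(interval$end)
  L <- ref$lengths[[ctg]]
  if (is.na(L) || s < 0L || e > L || s >= e) {
    stop("invalid interval ", ctg, ":", s, "-", e)
  }
  r <- runs[runs$contig == ctg & runs$end > s & runs$start < e, , drop = FALSE]
  if (nrow(r) == 0L) return(NA_integer_)
  clipped <- pmin(r$end, e) - pmax(r$start, s)
  length_n50(clipped)
}
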