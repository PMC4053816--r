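#' Coverage-depression ratios at transcription start sites
#'
#' For each TSS, computes the ratio of mean coverage in the surrounding 200
#' bases (`[tss - 100, tss + 100)`) to mean coverage in the surrounding
#' 3,000 bases (`[tss - 1500, tss + 1500)`). Windows are centered on the TSS
#' and symmetric (strand is ignored for placement); windows clipped at
#' contig ends are averaged over their included bases. A low ratio marks a
#' promoter whose immediate vicinity is selectively undercovered relative to
#' its broader neighborhood.
#'
#' @param cov A `CoverageTrack`.
#' @param tss_list Data.frame with columns `gene`, `contig`, `tss` (0-based
#'   position), e.g. from [read_tss_bed()].
#' @param near Half-width of the near window (default 100).
#' @param far Half-width of the far window (default 1500).
#' @return Data.frame of `PromoterRecord`s: `gene`, `contig`, `tss`,
#'   `near_mean`, `far_mean`, `ratio` (`NA` when the far window has zero
#'   mean coverage or no included bases).
#' @export
promoter_ratios <- function(cov, tss_list, near = 100L, far = 1500L) {
  stopifnot(inherits(cov, "CoverageTrack"),
            all(c("gene", "contig", "tss") %in% names(tss_list)))
  n <- nrow(tss_list)
  near_mean <- far_mean <- rep(NA_real_, n)
  win_mean <- function(ctg, lo, hi) {
    L <- cov$lengths[[ctg]]
    lo <- max(lo, 0L)
    hi <- min(hi, L)
    if (lo >= hi) return(NA_real_)
    idx <- (lo + 1L):hi
    keep <- cov$included[[ctg]][idx]
    if (!any(keep)) return(NA_real_)
    mean(cov$counts[[ctg]][idx][keep])
  }
  for (k in seq_len(n)) {
    ctg <- as.character(tss_list$contig[k])
    if (!ctg %in% cov$contigs) stop("TSS contig not in reference: ", ctg)
    tss <- as.integer(tss_list$tss[k])
    near_mean[k] <- win_mean(ctg, tss - near, tss + near)
    far_mean[k] <- win_mean(ctg, tss - far, tss + far)
  }
  ratio <- ifelse(!is.na(far_mean) & far_mean > 0, near_mean / far_mean,
                  NA_real_)
  data.frame(gene = as.character(tss_list$gene),
             contig = as.character(tss_list$contig),
             tss = as.integer(tss_list$tss),
             near_mean = near_mean, far_mean = far_mean, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Select the "bad promoters"
#'
#' Deduplicates multiple TSS entries per gene by keeping the entry with the
#' lowest coverage ratio, then emits the `n` genes with the lowest ratios as
#' 200-base intervals centered on the TSS (clipped at contig ends), labeled
#' with the gene name and carrying the ratio as score. Records with an
#' undefined ratio are excluded before ranking; ties are broken
#' lexicographically by gene name so selection is invariant to input order.
#'
#' @param records Output of [promoter_ratios()].
#' @param n Number of promoters to select (default 1000).
#' @param ref Optional `ReferenceModel` used to clip intervals at contig
#'   ends.
#' @param near Half-width of the emitted interval (default 100, giving
#'   200-base intervals).
#' @return Interval data.frame (`contig`, `start`, `end`, `label` = gene,
#'   `score` = ratio), ordered by ascending ratio.
#' @export
select_bad_promoters <- function(records, n = 1000L, ref = NULL,
                                 near = 100L) {
  stopifnot(is.data.frame(records),
            all(c("gene", "contig", "tss", "ratio") %in% names(records)))
  rec <- records[!is.na(records$ratio), , drop = FALSE]
  if (nrow(rec) == 0L) return(genomic_intervals())
  rec <- rec[order(rec$ratio, rec$gene, rec$tss), , drop = FALSE]
  rec <- rec[!duplicated(rec$gene), , drop = FALSE]
  if (n > nrow(rec)) {
    stop("requested ", n, " promoters but only ", nrow(rec),
         " distinct genes with defined ratios")
  }
  rec <- rec[seq_len(n), , drop = FALSE]
  start <- pmax(rec$tss - near, 0L)
  end <- rec$tss + near
  if (!is.null(ref)) end <- pmin(end, ref$lengths[rec$contig])
  genomic_intervals(rec$contig, start, end, label = rec$gene,
                    score = rec$ratio)
}

#' Read a TSS list from BED
#'
#' BED6 convention: the name field is the gene; a length-1 interval gives
#' the TSS directly, otherwise the strand-aware 5' end of the interval is
#' used (start for `+` or missing strand, `end - 1` for `-`).
#'
#' @param path BED file path.
#' @return Data.frame with `gene`, `contig`, `tss`.
#' @export
read_tss_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- if (length(parts) > 0L) min(lengths(parts)) else 0L
  if (length(parts) == 0L) {
    return(data.frame(gene = character(0), contig = character(0),
                      tss = integer(0), stringsAsFactors = FALSE))
  }
  get <- function(i) vapply(parts, `[[`, character(1L), i)
  contig <- get(1L)
  start <- as.integer(get(2L))
  end <- as.integer(get(3L))
  gene <- if (ncol >= 4L) get(4L) else sprintf("tss%05d", seq_along(start))
  strand <- if (ncol >= 6L) get(6L) else rep("+", length(start))
  tss <- ifelse(end - start == 1L, start,
                ifelse(strand == "-", end - 1L, start))
  data.frame(gene = gene, contig = contig, tss = as.integer(tss),
             stringsAsFactors = FALSE)
}
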