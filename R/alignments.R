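# SAM/BAM ingestion. All statistics consume alignments through this one
# reader so the record filter contract is applied uniformly: unmapped,
# secondary, supplementary and duplicate-flagged records are dropped; MAPQ-0
# records are kept (aligners randomly place multi-mapping reads, and those
# placements must count toward coverage of repetitive contexts).

#' Read filtered alignment records from a SAM or BAM file
#'
#' @param path Path to a SAM (text) or BAM file; SAM input is converted with
#'   `Rsamtools::asBam()` and must carry `@SQ` header lines.
#' @param ref Optional `ReferenceModel`; when given, a record aligned to a
#'   contig absent from the model is a hard error naming the contig.
#' @return List of vectors `qname`, `rname`, `pos` (1-based), `cigar`, `seq`.
#' @export
read_alignments <- function(path, ref = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE
    ),
    what = c("qname", "rname", "pos", "cigar", "seq")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  rec <- list(
    qname = res$qname,
    rname = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    seq = as.character(res$seq)
  )
  if (!is.null(ref)) {
    unknown <- setdiff(unique(rec$rname), ref$names)
    if (length(unknown) > 0L) {
      stop("alignment contig(s) not present in reference: ",
           paste(unknown, collapse = ", "))
    }
  }
  rec
}

# Run the CIGAR walker over records, per contig. Returns per-contig lists of
# counters plus skipped-record tallies.
accumulate_records <- function(records, ref, count_errors) {
  cov <- mm <- del <- ins <- span <- vector("list", length(ref$names))
  names(cov) <- names(mm) <- names(del) <- names(ins) <- names(span) <- ref$names
  n_malformed <- 0L
  n_noseq <- 0L
  for (ctg in ref$names) {
    idx <- which(records$rname == ctg)
    if (length(idx) == 0L) {
      z <- integer(ref$lengths[[ctg]])
      cov[[ctg]] <- z; mm[[ctg]] <- z; del[[ctg]] <- z
      ins[[ctg]] <- z; span[[ctg]] <- z
      next
    }
    w <- walk_alignments_cpp(records$pos[idx], records$cigar[idx],
                             records$seq[idx], ref$seqs[[ctg]], count_errors)
    cov[[ctg]] <- w$cov; mm[[ctg]] <- w$mm; del[[ctg]] <- w$del
    ins[[ctg]] <- w$ins; span[[ctg]] <- w$span
    n_malformed <- n_malformed + w$n_malformed
    n_noseq <- n_noseq + w$n_noseq
  }
  if (n_malformed > 0L) {
    message(n_malformed, " record(s) with malformed CIGAR skipped")
  }
  if (n_noseq > 0L) {
    message(n_noseq, " record(s) without read sequence skipped")
  }
  list(cov = cov, mm = mm, del = del, ins = ins, span = span,
       n_malformed = n_malformed, n_noseq = n_noseq)
}

# Write SAM text for a set of single-end records on one or more contigs.
write_sam_records <- function(path, ref, rname, pos1, cigar, seq,
                              qname = NULL, flag = NULL, mapq = 60L) {
  n <- length(pos1)
  if (is.null(qname)) qname <- sprintf("read%07d", seq_len(n))
  if (is.null(flag)) flag <- rep(0L, n)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref$names, ref$lengths), con)
  if (n > 0L) {
    writeLines(paste(qname, flag, rname, pos1, mapq, cigar, "*", 0L, 0L,
                     seq, "*", sep = "\t"), con)
  }
  invisible(path)
}
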