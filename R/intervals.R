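# Genomic intervals are plain data.frames with columns contig, start, end
# (0-based half-open, BED-compatible) plus optional label and score columns.

genomic_intervals <- function(contig = character(0), start = integer(0),
                              end = integer(0), label = NA_character_,
                              score = NULL) {
  df <- data.frame(contig = as.character(contig), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!length(label) %in% c(1L, nrow(df))) stop("label length mismatch")
  df$label <- rep_len(as.character(label), nrow(df))
  if (!is.null(score)) df$score <- rep_len(as.numeric(score), nrow(df))
  df
}

validate_intervals <- function(intervals, ref = NULL) {
  stopifnot(is.data.frame(intervals),
            all(c("contig", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0L) {
    stopifnot(all(intervals$start >= 0L), all(intervals$start < intervals$end))
    if (!is.null(ref)) {
      if (!all(intervals$contig %in% ref$names)) {
        stop("interval contig(s) not in reference: ",
             paste(setdiff(unique(intervals$contig), ref$names), collapse = ", "))
      }
      lens <- ref$lengths[intervals$contig]
      stopifnot(all(intervals$end <= lens))
    }
  }
  invisible(intervals)
}

# Merge overlapping/adjacent-by-overlap intervals per contig (union).
merge_intervals <- function(intervals, label = NA_character_) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0L) return(genomic_intervals())
  out <- lapply(split(intervals, intervals$contig), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    genomic_intervals(d$contig[1L], IRanges::start(ir) - 1L, IRanges::end(ir),
                      label = label)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig, res$start), , drop = FALSE]
}

# Per-contig logical vectors marking bases covered by the interval union.
intervals_to_mask <- function(intervals, ref) {
  validate_intervals(intervals, ref)
  m <- lapply(ref$lengths, function(L) logical(L))
  if (nrow(intervals) > 0L) {
    for (k in seq_len(nrow(intervals))) {
      ctg <- intervals$contig[k]
      m[[ctg]][(intervals$start[k] + 1L):intervals$end[k]] <- TRUE
    }
  }
  m
}

# Maximal runs of TRUE in per-contig logical vectors -> intervals.
mask_to_intervals <- function(mask, label = NA_character_) {
  out <- lapply(names(mask), function(ctg) {
    v <- mask[[ctg]]
    if (!any(v)) return(NULL)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    genomic_intervals(ctg, starts[keep], ends[keep], label = label)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(genomic_intervals())
  rownames(res) <- NULL
  res
}

#' Write intervals as BED
#'
#' Emits BED3+ records (0-based half-open starts, as stored internally) with
#' the `label` column as the BED name field and, when present, `score` as the
#' fifth column.
#'
#' @param intervals Interval data.frame (`contig`, `start`, `end`, optional
#'   `label`, `score`).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  cols <- list(intervals$contig, intervals$start, intervals$end)
  if (!is.null(intervals$label)) {
    cols <- c(cols, list(ifelse(is.na(intervals$label), ".", intervals$label)))
    if (!is.null(intervals$score)) cols <- c(cols, list(intervals$score))
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as an interval data.frame
#'
#' Accepts BED3 to BED6; column 4 becomes `label`, column 5 `score`. Track
#' and browser lines are skipped. Coordinates stay 0-based half-open.
#'
#' @param path BED file path.
#' @return Interval data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(genomic_intervals())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(parts))
  get <- function(i) vapply(parts, `[[`, character(1L), i)
  iv <- genomic_intervals(get(1L), as.integer(get(2L)), as.integer(get(3L)),
                          label = if (ncol >= 4L) get(4L) else NA_character_)
  if (ncol >= 5L) iv$score <- suppressWarnings(as.numeric(get(5L)))
  validate_intervals(iv)
}

#' Export the exclusion mask of a reference as BED
#'
#' Writes the complement of the inclusion mask (masked contigs and ambiguous
#' bases) as merged BED intervals.
#'
#' @param ref A `ReferenceModel`.
#' @param path Output path.
#' @export
write_excluded_bed <- function(ref, path) {
  excl <- lapply(ref$included, `!`)
  write_bed(mask_to_intervals(excl, label = "excluded"), path)
}
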