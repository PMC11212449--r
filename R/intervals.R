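#' Construct a table of genomic intervals
#'
#' All coordinates in this package are 0-based, half-open: an interval
#' covers bases `start .. end - 1` and its length is `end - start`.
#' Published 1-based inclusive coordinate pairs whose printed lengths equal
#' `end - start` (such as NUMT coordinates) can therefore be ingested
#' verbatim; formats that are genuinely 1-based inclusive (GFF3) are shifted
#' on read.
#'
#' @param chrom character vector of chromosome/contig identifiers.
#' @param start,end integer-like vectors; `0 <= start <= end` required.
#' @return a `data.frame` with columns `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing numbers")
  if (any(start < 0))
    stop("coordinate error: negative start")
  if (any(start > end))
    stop("coordinate error: start > end")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Length of genomic intervals
#'
#' @param iv interval table from [genomic_interval()] (or any data.frame
#'   with numeric `start` and `end` columns on the 0-based half-open
#'   convention).
#' @return numeric vector of lengths in bp (`end - start`).
#' @examples
#' interval_length(genomic_interval("2", 12212275, 12213020))  # 745
#' @export
interval_length <- function(iv) {
  iv <- genomic_interval(iv$chrom, iv$start, iv$end)
  iv$end - iv$start
}

#' Find overlapping pairs between two interval sets
#'
#' Overlap uses the shared half-open convention: `[0,10)` and `[10,20)` are
#' adjacent, not overlapping. Detection is delegated to
#' [IRanges::findOverlaps()] per chromosome.
#'
#' @param a,b interval tables (`chrom`, `start`, `end`).
#' @return data.frame with one row per overlapping pair: `query` (row index
#'   in `a`), `subject` (row index in `b`), `overlap_bp`, and `total`
#'   (TRUE when the `b` interval is fully contained in the `a` interval).
#' @export
intervals_overlap <- function(a, b) {
  a <- genomic_interval(a$chrom, a$start, a$end)
  b <- genomic_interval(b$chrom, b$start, b$end)
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    # half-open: use start .. end-1 in closed IRanges space; empty intervals
    # (start == end) cannot overlap anything and are dropped up front
    ia <- ia[a$end[ia] > a$start[ia]]
    ib <- ib[b$end[ib] > b$start[ib]]
    if (!length(ia) || !length(ib)) next
    ra <- IRanges::IRanges(start = a$start[ia] + 1, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1, end = b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb)
    if (!length(hits)) next
    qi <- ia[S4Vectors::queryHits(hits)]
    si <- ib[S4Vectors::subjectHits(hits)]
    ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
    out[[length(out) + 1L]] <- data.frame(
      query = qi, subject = si, overlap_bp = ov,
      total = b$start[si] >= a$start[qi] & b$end[si] <= a$end[qi])
  }
  if (!length(out))
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = numeric(), total = logical()))
  res <- do.call(rbind, out)
  res[order(res$query, res$subject), , drop = FALSE]
}
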