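#' Read a Tandem Repeats Finder .dat file
#'
#' Parses the TRF .dat dialect: `Sequence: <name>` header lines followed by
#' whitespace-separated record lines
#' `start end period copies consensus_size percent_match percent_indels
#' score A C G T entropy consensus array_sequence`. TRF reports 1-based
#' inclusive coordinates; they are converted to the package's 0-based
#' half-open convention on read. No pre-installed R package parses this
#' dialect, so the reader is implemented here.
#'
#' @param path .dat file.
#' @return data.frame with columns `chrom`, `start`, `end`, `period`,
#'   `copies`, `percent_match`, `consensus`; zero rows for an empty file.
#' @export
read_trf_dat <- function(path) {
  lines <- readLines(path)
  recs <- list()
  chrom <- NA_character_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(Tandem|Gary|Program|Version|Parameters:)", ln))
      next
    if (grepl("^Sequence:", ln)) {
      chrom <- sub("\\s.*$", "", sub("^Sequence:\\s*", "", ln))
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 14 || is.na(suppressWarnings(as.numeric(f[1]))))
      stop(sprintf("unparseable TRF record at line %d: %s", i, lines[i]))
    if (is.na(chrom))
      stop(sprintf("TRF record before any 'Sequence:' header at line %d", i))
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = chrom,
      start = as.numeric(f[1]) - 1,   # 1-based inclusive -> 0-based half-open
      end = as.numeric(f[2]),
      period = as.numeric(f[3]),
      copies = as.numeric(f[4]),
      percent_match = as.numeric(f[6]),
      consensus = f[14],
      stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      period = numeric(), copies = numeric(),
                      percent_match = numeric(), consensus = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Write tandem-repeat arrays in the TRF .dat dialect
#'
#' Inverse of [read_trf_dat()] for the fields this pipeline consumes; the
#' remaining numeric columns of the dialect are filled with neutral values.
#'
#' @param arrays data.frame as returned by [read_trf_dat()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trf_dat <- function(arrays, path) {
  out <- character()
  for (ch in unique(arrays$chrom)) {
    out <- c(out, paste("Sequence:", ch), "")
    a <- arrays[arrays$chrom == ch, , drop = FALSE]
    pm <- if (is.null(a$percent_match)) rep(100, nrow(a)) else a$percent_match
    out <- c(out, sprintf("%d %d %d %.1f %d %d 0 100 25 25 25 25 2.00 %s %s",
                          as.integer(a$start + 1), as.integer(a$end),
                          as.integer(a$period), a$copies,
                          as.integer(a$period), as.integer(round(pm)),
                          a$consensus, a$consensus))
  }
  writeLines(out, path)
  invisible(path)
}

#' Annotate exact tandem arrays in a sequence
#'
#' A deliberately minimal annotator used to exercise the .dat round-trip on
#' synthetic sequence: for each candidate period it scans for maximal runs
#' where every base equals the base one period earlier, and reports runs of
#' at least two full copies. It only finds exact (mutation-free) arrays and
#' is not a substitute for Tandem Repeats Finder on real sequence.
#'
#' @param seq character scalar (A/C/G/T).
#' @param periods integer vector of candidate monomer sizes.
#' @param chrom name used in the output.
#' @return data.frame in the [read_trf_dat()] layout.
#' @export
find_exact_tandems <- function(seq, periods, chrom = "seq") {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  recs <- list()
  for (p in sort(unique(as.integer(periods)))) {
    if (n < 2 * p) next
    eq <- x[(p + 1):n] == x[1:(n - p)]   # eq[i]: base i+p matches base i
    r <- rle(eq)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      run <- r$lengths[k]
      if (run < p) next                  # need >= 2 full copies
      s <- pos[k]                        # first matching offset (1-based)
      e <- pos[k] + run - 1 + p          # last base of the array
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = chrom, start = s - 1, end = e, period = p,
        copies = round((e - s + 1) / p, 1), percent_match = 100,
        consensus = paste(x[s:(s + p - 1)], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      period = numeric(), copies = numeric(),
                      percent_match = numeric(), consensus = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}
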