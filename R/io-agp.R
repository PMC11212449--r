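#' Write a scaffold layout as AGP 2.1 text
#'
#' Emits one AGP object per chromosome, alternating contig component rows
#' with fixed-size scaffold gap rows (gap type `scaffold`, evidence `map`,
#' linkage `yes`). Contigs whose orientation could not be determined are
#' written with orientation `?`. Output is bit-exact for a given layout and
#' gap policy.
#'
#' @param layout a [scaffold_layout] (or a data.frame with columns `chrom`,
#'   `order`, `contig`, `orientation`); only rows with a non-NA `order`
#'   (placed contigs) are written.
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param gap_length declared gap size between consecutive contigs (bp).
#' @param path optional output file; when NULL the lines are returned.
#' @return character vector of AGP lines (invisibly when `path` is given).
#' @export
write_agp <- function(layout, contig_lengths, gap_length = 100, path = NULL) {
  if (inherits(layout, "scaffold_layout")) layout <- layout$placement
  df <- layout[!is.na(layout$order), , drop = FALSE]
  lines <- "##agp-version\t2.1"
  for (ch in unique(df$chrom)) {
    rows <- df[df$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$order), , drop = FALSE]
    if (anyDuplicated(rows$contig))
      stop("contig appears more than once in chromosome ", ch)
    pos <- 0
    part <- 0L
    for (k in seq_len(nrow(rows))) {
      len <- contig_lengths[[rows$contig[k]]]
      if (is.null(len) || is.na(len))
        stop("no length for contig ", rows$contig[k])
      if (k > 1) {
        part <- part + 1L
        lines <- c(lines, paste(ch, pos + 1, pos + gap_length, part, "N",
                                gap_length, "scaffold", "yes", "map",
                                sep = "\t"))
        pos <- pos + gap_length
      }
      part <- part + 1L
      ori <- rows$orientation[k]
      if (is.na(ori) || !ori %in% c("+", "-")) ori <- "?"
      lines <- c(lines, paste(ch, pos + 1, pos + len, part, "W",
                              rows$contig[k], 1, len, ori, sep = "\t"))
      pos <- pos + len
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
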