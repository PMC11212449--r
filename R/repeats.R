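#' Classify tandem arrays into the 91 bp and 371 bp period families
#'
#' Family membership follows the period windows of the two major honey
#' bee tandem-repeat classes: `"91"` for periods 91-93 bp, `"371"` for
#' periods 367-371 bp, `"other"` otherwise. An array is "selected" when
#' it has strictly more than `min_copies` copies in tandem (counts are
#' also reported without the copy filter).
#'
#' @param arrays data.frame in [read_trf_dat()] layout (`period`,
#'   `copies`, ...).
#' @param min_copies copy-number threshold (strict inequality).
#' @return list `arrays` (input plus `family` and `selected` columns) and
#'   `counts` (data.frame per family: total and selected).
#' @export
classify_period_families <- function(arrays, min_copies = 10) {
  fam <- rep("other", nrow(arrays))
  fam[arrays$period >= 91 & arrays$period <= 93] <- "91"
  fam[arrays$period >= 367 & arrays$period <= 371] <- "371"
  arrays$family <- fam
  arrays$selected <- arrays$copies > min_copies
  counts <- do.call(rbind, lapply(c("91", "371", "other"), function(f)
    data.frame(family = f, total = sum(fam == f),
               selected = sum(fam == f & arrays$selected))))
  list(arrays = arrays, counts = counts)
}

#' Canonical rotation of a circular sequence
#'
#' A tandem-repeat monomer is circular: annotators report it starting at
#' an arbitrary phase. This returns the lexicographically least rotation
#' (Booth's algorithm), giving every rotation of the same circular
#' sequence an identical arbitrary start point.
#'
#' @param x character scalar over A/C/G/T/N (any alphabet works).
#' @return the canonical rotation of `x`.
#' @export
canonical_rotation <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (!nzchar(x)) stop("empty sequence")
  n <- nchar(x)
  doubled <- paste0(x, x)
  s <- utf8ToInt(doubled)          # 1-based; Booth indices below 0-based
  f <- rep(-1L, 2L * n)            # f[i+1] holds failure value for index i
  k <- 0L                          # candidate start of least rotation
  for (j in seq_len(2L * n - 1L)) {
    sj <- s[j + 1L]
    i <- f[j - k]                  # f[(j - k - 1) + 1]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  substr(doubled, k + 1L, k + n)
}

#' Identity between two repeat monomers, rotation- and strand-aware
#'
#' Monomers are compared after canonical rotation, on both strands, by
#' global pairwise alignment; the better strand's percent identity is
#' returned as a fraction.
#'
#' @param a,b character monomer sequences.
#' @return identity in `[0, 1]`.
#' @export
monomer_identity <- function(a, b) {
  ca <- canonical_rotation(toupper(a))
  pid_of <- function(x, y) {
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                        Biostrings::DNAString(y))
    Biostrings::pid(al) / 100
  }
  brc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(b))))
  max(pid_of(ca, canonical_rotation(toupper(b))),
      pid_of(ca, canonical_rotation(brc)))
}

#' Group repeat hits separated by less than the period size
#'
#' Single-linkage clustering of same-chromosome hit intervals: two hits
#' whose gap (next start minus previous end) is strictly smaller than the
#' repeat period belong to the same array locus. The copy count of a
#' cluster is its member count. Output does not depend on input order.
#'
#' @param hits data.frame `chrom`, `start`, `end` of per-monomer hits.
#' @param period repeat period size (bp).
#' @return data.frame `chrom`, `start`, `end`, `n_copies`, one row per
#'   cluster, plus a `cluster` column on the (sorted) input as attribute
#'   `assignment`.
#' @export
group_hits <- function(hits, period) {
  if (!nrow(hits))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_copies = integer()))
  h <- hits[order(hits$chrom, hits$start, hits$end), , drop = FALSE]
  cl <- integer(nrow(h))
  cur <- 0L
  for (i in seq_len(nrow(h))) {
    if (i == 1 || h$chrom[i] != h$chrom[i - 1] ||
        h$start[i] - max_end >= period) {
      cur <- cur + 1L
      max_end <- h$end[i]
    } else max_end <- max(max_end, h$end[i])
    cl[i] <- cur
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(h)), cl), function(idx)
    data.frame(chrom = h$chrom[idx[1]], start = min(h$start[idx]),
               end = max(h$end[idx]), n_copies = length(idx))))
  rownames(out) <- NULL
  attr(out, "assignment") <- cbind(h, cluster = cl)
  out
}

#' Call telomeric repeat arrays
#'
#' Arrays of the telomeric motif (default TTAGG, the accepted Hymenoptera
#' consensus) are classified `terminal` when they lie within
#' `end_window` of a chromosome end and `interstitial` otherwise. Motif
#' matching is rotation- and reverse-complement-aware (TTAGG on the other
#' strand reads CCTAA). Non-motif arrays within the end window are
#' reported as `terminal_candidate` (for example an AATAT array at a
#' chromosome start).
#'
#' @param arrays data.frame with `chrom`, `start`, `end`, `period`,
#'   `copies`, `consensus` (short-period arrays, periods 2-7 bp).
#' @param chrom_lengths named numeric (bp).
#' @param motif telomeric monomer.
#' @param end_window distance from a chromosome end counting as terminal
#'   (bp).
#' @return data.frame `chrom`, `end_side`, `start`, `end`, `copies`,
#'   `motif_match`, `classification`.
#' @export
call_telomeres <- function(arrays, chrom_lengths, motif = "TTAGG",
                           end_window = 10000) {
  canon <- canonical_rotation(toupper(motif))
  canon_rc <- canonical_rotation(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(motif)))))
  out <- list()
  for (i in seq_len(nrow(arrays))) {
    a <- arrays[i, ]
    L <- chrom_lengths[[a$chrom]]
    dist_start <- a$start
    dist_end <- L - a$end
    near_end <- dist_start <= end_window || dist_end <= end_window
    cc <- canonical_rotation(toupper(a$consensus))
    is_motif <- nchar(a$consensus) == nchar(motif) &&
      (cc == canon || cc == canon_rc)
    cls <- if (is_motif && near_end) "terminal"
    else if (is_motif) "interstitial"
    else if (near_end) "terminal_candidate"
    else NA_character_
    if (is.na(cls)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = a$chrom,
      end_side = if (dist_start <= dist_end) "proximal" else "distal",
      start = a$start, end = a$end, copies = a$copies,
      motif_match = is_motif, classification = cls,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), end_side = character(),
                      start = numeric(), end = numeric(),
                      copies = numeric(), motif_match = logical(),
                      classification = character()))
  do.call(rbind, out)
}

#' Locate marker-repeat loci (AluI/AvaI-style) from search hits
#'
#' Groups externally produced hit intervals of a marker consensus
#' sequence into array loci with copy counts ([group_hits()]) and
#' annotates each locus with its distance to the nearest chromosome end.
#'
#' @param hits data.frame `chrom`, `start`, `end` of hits for one marker
#'   consensus (e.g. BLAST output as BED).
#' @param period marker monomer size (bp), used as the grouping distance.
#' @param chrom_lengths named numeric (bp).
#' @return data.frame `chrom`, `start`, `end`, `n_copies`,
#'   `end_distance`.
#' @export
map_marker_repeats <- function(hits, period, chrom_lengths) {
  loci <- group_hits(hits, period)
  if (!nrow(loci)) {
    loci$end_distance <- numeric()
    return(loci)
  }
  loci$end_distance <- vapply(seq_len(nrow(loci)), function(i)
    min(loci$start[i], chrom_lengths[[loci$chrom[i]]] - loci$end[i]), 0)
  loci
}
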