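#' Depth ratio of an indel region against its flanks
#'
#' Normalises a sample's sequencing depth over a presence/absence indel
#' by the depth of the sequence flanking it: the ratio between the mean
#' per-base depth inside the indel interval and the mean over the two
#' flanks combined. A haploid sample carrying the indel has a ratio near
#' 1, a sample lacking it a ratio near 0. Flank width defaults to the
#' indel length on each side, capped at 5 kb and floored at 500 bp.
#'
#' @param track data.frame `pos`, `depth`: per-base depth covering the
#'   indel and flanks (positions 0-based).
#' @param variant one-row data.frame/list with `start`, `end` of the
#'   indel on the genome in which it is present.
#' @param flank flank width in bp (default as above).
#' @return list `indel_depth`, `flank_depth`, `ratio` (NA with
#'   `no_call = TRUE` when the flank depth is zero).
#' @export
depth_ratio <- function(track, variant, flank = NULL) {
  len <- variant$end - variant$start
  if (is.null(flank)) flank <- min(max(len, 500), 5000)
  inside <- track$pos >= variant$start & track$pos < variant$end
  in_flank <- (track$pos >= variant$start - flank &
                 track$pos < variant$start) |
    (track$pos >= variant$end & track$pos < variant$end + flank)
  if (!any(inside) || !any(in_flank))
    stop("depth track does not cover the indel and its flanks")
  d_in <- mean(track$depth[inside])
  d_fl <- mean(track$depth[in_flank])
  if (d_fl == 0)
    return(list(indel_depth = d_in, flank_depth = 0, ratio = NA_real_,
                no_call = TRUE))
  list(indel_depth = d_in, flank_depth = d_fl, ratio = d_in / d_fl,
       no_call = FALSE)
}

# exact 1-D 2-means: best split over the sorted order minimises total
# within-cluster sum of squares
.kmeans2_exact <- function(x) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  best <- Inf; best_split <- 1L
  for (k in seq_len(n - 1)) {
    lo <- xs[seq_len(k)]; hi <- xs[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best) { best <- ss; best_split <- k }
  }
  assign <- integer(n)
  assign[ord] <- rep(1:2, c(best_split, n - best_split))
  centres <- c(mean(xs[seq_len(best_split)]), mean(xs[(best_split + 1):n]))
  list(assignment = assign, centres = centres, withinss = best)
}

#' Presence/absence calls from depth ratios by exact 2-means
#'
#' One-dimensional K-means with K = 2 on the per-sample depth ratios,
#' solved exactly by enumerating split points over the sorted ratios
#' (no initialisation nondeterminism). The cluster with the larger
#' centre is called `present`, the other `absent`. When the two centres
#' are closer than `separation_floor` the variant is considered
#' monomorphic in the panel and every sample receives the call of the
#' dominant (larger) cluster. Samples with undefined ratios are
#' `no-call`.
#'
#' @param ratios named numeric vector of depth ratios (NA allowed).
#' @param separation_floor minimum centre separation for a two-cluster
#'   interpretation.
#' @return data.frame `sample`, `ratio`, `cluster`, `call` plus attribute
#'   `centres`.
#' @export
kmeans2_call <- function(ratios, separation_floor = 0.3) {
  ok <- !is.na(ratios)
  if (sum(ok) < 2) stop("need at least 2 samples with defined ratios")
  km <- .kmeans2_exact(unname(ratios[ok]))
  call <- rep("no-call", length(ratios))
  cluster <- rep(NA_integer_, length(ratios))
  cluster[ok] <- km$assignment
  hi_cluster <- which.max(km$centres)
  if (abs(diff(km$centres)) < separation_floor) {
    dominant <- which.max(tabulate(km$assignment, 2))
    lab <- if (km$centres[dominant] >= 0.5) "present" else "absent"
    call[ok] <- lab
  } else {
    call[ok] <- ifelse(km$assignment == hi_cluster, "present", "absent")
  }
  out <- data.frame(
    sample = if (!is.null(names(ratios))) names(ratios) else
      seq_along(ratios),
    ratio = as.numeric(ratios), cluster = cluster, call = call,
    stringsAsFactors = FALSE)
  attr(out, "centres") <- km$centres
  out
}

#' Size spectrum of assembly-vs-assembly indels
#'
#' Retains indels strictly larger than `min_size` that do not overlap a
#' contig-boundary exclusion interval, and counts how many exceed each
#' reporting threshold.
#'
#' @param indels data.frame `chrom`, `start`, `end` (on the genome of
#'   presence) with `length` (bp; absolute value used) - `length`
#'   defaults to `end - start`.
#' @param boundaries data.frame `chrom`, `start`, `end` of contig
#'   boundary intervals to exclude (may be empty).
#' @param min_size strict lower bound on indel size (bp).
#' @param thresholds sizes for the "larger than" counts.
#' @return list `retained` (data.frame), `n_retained`,
#'   `threshold_counts` (named), `histogram` (table of log10-size bins).
#' @export
indel_size_spectrum <- function(indels, boundaries = NULL, min_size = 40,
                                thresholds = c(1000, 10000)) {
  if (is.null(indels$length)) indels$length <- indels$end - indels$start
  indels$length <- abs(indels$length)
  keep <- indels$length > min_size
  if (!is.null(boundaries) && nrow(boundaries)) {
    ov <- intervals_overlap(indels, boundaries)
    keep[unique(ov$query)] <- FALSE
  }
  retained <- indels[keep, , drop = FALSE]
  counts <- vapply(thresholds, function(t) sum(retained$length > t), 0)
  names(counts) <- paste0("gt_", thresholds)
  breaks <- c(min_size, 100, 300, 1000, 3000, 10000, Inf)
  hist <- table(cut(retained$length, breaks = breaks))
  list(retained = retained, n_retained = nrow(retained),
       threshold_counts = counts, histogram = hist)
}

#' Annotate indels with overlapping exons
#'
#' @param indels data.frame `chrom`, `start`, `end`.
#' @param exons data.frame `chrom`, `start`, `end` (0-based half-open; a
#'   GFF3 exon's 1-based inclusive coordinates must be converted with
#'   `start - 1`).
#' @return data.frame `indel`, `exon`, `overlap_bp`, `total` (exon fully
#'   contained in the indel); zero rows when nothing overlaps.
#' @export
exon_overlap_report <- function(indels, exons) {
  ov <- intervals_overlap(indels, exons)
  names(ov)[names(ov) == "query"] <- "indel"
  names(ov)[names(ov) == "subject"] <- "exon"
  ov
}
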