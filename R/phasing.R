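#' @title Genotype-vector utilities
#' @description A genotype vector is the pattern, across the drones of one
#'   colony, of which queen haplotype each drone inherited at a site or
#'   segment, coded 0/1 with NA for missing. Two vectors are
#'   "wildcard-compatible" when they agree at every drone where both are
#'   observed; the Hamming distance between vectors ignores entries missing
#'   in either.
#' @param a,b integer vectors of 0/1/NA.
#' @return `hamming()`: the number of observed disagreeing entries;
#'   `gv_compatible()`: logical.
#' @export
hamming <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  sum(a[ok] != b[ok])
}

#' @rdname hamming
#' @export
gv_compatible <- function(a, b) hamming(a, b) == 0

#' Group consecutive SNPs with identical genotype vectors into bins
#'
#' Scans sites in position order and grows a bin while each new site's
#' vector is wildcard-compatible with the bin's consensus (missing entries
#' are filled in as the bin grows). Because the allele labelling of each
#' SNP is arbitrary (no grand-parental genotypes), a vector and its
#' complement describe the same inheritance pattern: a site joins the
#' current bin when it is compatible either as-is or after
#' complementation. A bin is a maximal such run: a segment with no
#' observed crossover in the colony. Bin length is the span from first to
#' last member SNP.
#'
#' @param pos numeric vector of site positions (contig-local, sorted).
#' @param gt integer matrix, sites x drones, of 0/1/NA haplotype codes.
#' @param contig contig identifier carried into the output.
#' @return list with `bins` (data.frame `contig`, `start`, `end`,
#'   `n_snps`) and `vectors` (bins x drones matrix); empty input gives
#'   zero bins.
#' @export
build_bins <- function(pos, gt, contig = "contig") {
  stopifnot(length(pos) == nrow(gt))
  if (!length(pos))
    return(list(bins = data.frame(contig = character(), start = numeric(),
                                  end = numeric(), n_snps = integer()),
                vectors = matrix(NA_integer_, 0, ncol(gt),
                                 dimnames = list(NULL, colnames(gt)))))
  if (is.unsorted(pos)) stop("sites must be sorted by position")
  nb <- 0L
  starts <- ends <- numeric(); counts <- integer()
  vecs <- list()
  cur <- NULL
  for (i in seq_along(pos)) {
    v <- gt[i, ]
    if (!is.null(cur) && !gv_compatible(cur, v) &&
        gv_compatible(cur, 1L - v))
      v <- 1L - v
    if (!is.null(cur) && gv_compatible(cur, v)) {
      fill <- is.na(cur) & !is.na(v)
      cur[fill] <- v[fill]
      ends[nb] <- pos[i]
      counts[nb] <- counts[nb] + 1L
    } else {
      nb <- nb + 1L
      starts[nb] <- ends[nb] <- pos[i]
      counts[nb] <- 1L
      cur <- v
    }
    vecs[[nb]] <- cur
  }
  list(bins = data.frame(contig = contig, start = starts, end = ends,
                         n_snps = counts, stringsAsFactors = FALSE),
       vectors = do.call(rbind, vecs))
}

#' Phase successive bins by recombination minimisation
#'
#' Without grand-parental genotypes the phase of each bin is only defined
#' up to complementation. Scanning left to right, each bin after the first
#' keeps either its vector or the complement, whichever is at smaller
#' Hamming distance from the previous phased vector (ties keep the
#' unflipped vector). Because each junction is minimised independently,
#' this greedy scan attains the global minimum number of recombination
#' events over all phase assignments.
#'
#' @param bins output of [build_bins()] (fields `bins`, `vectors`).
#' @return an object of class `phased_contig`: `bins`, `vectors` (phased),
#'   `flipped` (which bins were complemented), `junctions` (per-junction
#'   Hamming distances, length `n_bins - 1`).
#' @export
phase_contig <- function(bins) {
  v <- bins$vectors
  nb <- nrow(v)
  stopifnot(nb >= 1)
  flipped <- logical(nb)
  junc <- numeric(max(nb - 1, 0))
  if (nb > 1) {
    for (k in 2:nb) {
      d0 <- hamming(v[k - 1, ], v[k, ])
      d1 <- hamming(v[k - 1, ], 1L - v[k, ])
      if (d1 < d0) {
        v[k, ] <- 1L - v[k, ]
        flipped[k] <- TRUE
        junc[k - 1] <- d1
      } else junc[k - 1] <- d0
    }
  }
  structure(list(contig = bins$bins$contig[1], bins = bins$bins,
                 vectors = v, flipped = flipped, junctions = junc),
            class = "phased_contig")
}

#' @export
print.phased_contig <- function(x, ...) {
  cat(sprintf("<phased_contig> %s: %d bins, %d recombination events\n",
              x$contig, nrow(x$bins), sum(x$junctions)))
  invisible(x)
}

#' Total recombination events of a phased contig
#' @param pc a `phased_contig`.
#' @return numeric scalar.
#' @export
total_events <- function(pc) sum(pc$junctions)

# rebuild junction distances after bin removal/merging
.rejunction <- function(pc) {
  nb <- nrow(pc$vectors)
  pc$junctions <- if (nb > 1)
    vapply(seq_len(nb - 1), function(k)
      hamming(pc$vectors[k, ], pc$vectors[k + 1, ]), 0) else numeric()
  pc
}

#' Detect and remove non-crossover gene-conversion bins
#'
#' A short bin sandwiched between two bins can be a gene-conversion tract
#' masquerading as a double crossover. Scanning left to right and
#' iterating to a fixed point, a bin B of length below `threshold` with
#' flanks A and C is flagged when (i) A and C have identical phased
#' vectors, in which case A, B and C are merged into one bin, or (ii) the
#' events entering and leaving B exceed the events needed to go directly
#' from A to C, `H(A,B) + H(B,C) > H(A,C)`, in which case B is removed and
#' A, C left adjacent. First and last bins are never flagged.
#'
#' @param pc a `phased_contig`.
#' @param threshold bin length (bp) below which a bin can be flagged.
#' @return list with `pc` (the merged `phased_contig`) and `flagged`
#'   (data.frame of removed bins: `contig`, `start`, `end`, `n_snps`,
#'   `rule`).
#' @export
detect_nco_conversions <- function(pc, threshold = 2000) {
  stopifnot(inherits(pc, "phased_contig"))
  flagged <- list()
  repeat {
    nb <- nrow(pc$vectors)
    if (nb < 3) break
    hit <- FALSE
    for (k in 2:(nb - 1)) {
      blen <- pc$bins$end[k] - pc$bins$start[k]
      if (blen >= threshold) next
      a <- pc$vectors[k - 1, ]; b <- pc$vectors[k, ]; c <- pc$vectors[k + 1, ]
      if (gv_compatible(a, c)) {
        flagged[[length(flagged) + 1L]] <-
          cbind(pc$bins[k, ], rule = "identical_flanks")
        merged_bin <- data.frame(
          contig = pc$bins$contig[k - 1], start = pc$bins$start[k - 1],
          end = pc$bins$end[k + 1],
          n_snps = pc$bins$n_snps[k - 1] + pc$bins$n_snps[k + 1])
        merged_vec <- a
        fill <- is.na(merged_vec) & !is.na(c)
        merged_vec[fill] <- c[fill]
        before <- seq_len(nb) < k - 1
        after <- seq_len(nb) > k + 1
        pc$bins <- rbind(pc$bins[before, , drop = FALSE], merged_bin,
                         pc$bins[after, , drop = FALSE])
        pc$vectors <- rbind(pc$vectors[before, , drop = FALSE], merged_vec,
                            pc$vectors[after, , drop = FALSE])
        pc$flipped <- rep(FALSE, nrow(pc$vectors))
        hit <- TRUE
        break
      }
      if (hamming(a, b) + hamming(b, c) > hamming(a, c)) {
        flagged[[length(flagged) + 1L]] <-
          cbind(pc$bins[k, ], rule = "excess_events")
        keep <- setdiff(seq_len(nb), k)
        pc$bins <- pc$bins[keep, , drop = FALSE]
        pc$vectors <- pc$vectors[keep, , drop = FALSE]
        pc$flipped <- rep(FALSE, nrow(pc$vectors))
        hit <- TRUE
        break
      }
    }
    if (!hit) break
  }
  pc <- .rejunction(pc)
  rownames(pc$bins) <- NULL
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(contig = character(), start = numeric(), end = numeric(),
               n_snps = integer(), rule = character())
  rownames(flagged) <- NULL
  list(pc = pc, flagged = flagged)
}

#' End genotype vectors of a phased contig
#'
#' The first and last phased bin vectors anchor the contig during
#' scaffolding. A contig is orientable from crossover data only when it
#' contains at least one internal crossover, i.e. at least two bins.
#'
#' @param pc a `phased_contig`.
#' @return list `left`, `right` (phased vectors) and `orientable`.
#' @export
contig_end_vectors <- function(pc) {
  stopifnot(inherits(pc, "phased_contig"))
  nb <- nrow(pc$vectors)
  if (!nb) stop("contig has no bins")
  list(left = pc$vectors[1, ], right = pc$vectors[nb, ],
       orientable = nb >= 2)
}
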