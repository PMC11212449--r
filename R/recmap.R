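#' Project phased bins onto a chromosome layout
#'
#' Lays the per-contig phased bins of every colony along each chromosome
#' of a layout frame, flipping bin coordinates and bin order for contigs
#' placed in reverse orientation, and re-phasing each contig against the
#' previous one (a contig's phase is arbitrary, so the global complement
#' minimising the junction Hamming distance is chosen, left to right).
#'
#' @param frame layout frame: data.frame `chrom`, `order`, `contig`,
#'   `orientation` (`"+"`/`"-"`/NA, NA treated as `"+"`), `offset`
#'   (scaffold start of the contig, bp) and `length`. See
#'   [truth_layout_frame()] and [layout_frame()].
#' @param phased named list per colony: `phased[[colony]][[contig]]` is a
#'   [phase_contig()] result (usually after [detect_nco_conversions()]).
#' @return list per colony per chromosome: `bins` (data.frame `start`,
#'   `end` in layout coordinates) and `vectors` (bins x drones).
#' @export
project_bins <- function(frame, phased) {
  frame <- frame[!is.na(frame$order), , drop = FALSE]
  out <- list()
  for (colony in names(phased)) {
    pcs <- phased[[colony]]
    out[[colony]] <- list()
    for (ch in unique(frame$chrom)) {
      rows <- frame[frame$chrom == ch, , drop = FALSE]
      rows <- rows[order(rows$order), , drop = FALSE]
      bins_all <- NULL; vecs_all <- NULL
      for (k in seq_len(nrow(rows))) {
        pc <- pcs[[rows$contig[k]]]
        if (is.null(pc) || !nrow(pc$vectors)) next
        b <- pc$bins; v <- pc$vectors
        flip <- identical(rows$orientation[k], "-")
        if (flip) {
          len <- rows$length[k]
          new_start <- len - b$end
          b$end <- len - b$start
          b$start <- new_start
          idx <- rev(seq_len(nrow(b)))
          b <- b[idx, , drop = FALSE]
          v <- v[idx, , drop = FALSE]
        }
        b$start <- b$start + rows$offset[k]
        b$end <- b$end + rows$offset[k]
        if (!is.null(vecs_all)) {
          prev <- vecs_all[nrow(vecs_all), ]
          if (hamming(prev, 1L - v[1, ]) < hamming(prev, v[1, ]))
            v <- 1L - v
        }
        bins_all <- rbind(bins_all, b[, c("start", "end")])
        vecs_all <- rbind(vecs_all, v)
      }
      if (!is.null(bins_all))
        out[[colony]][[ch]] <- list(bins = bins_all, vectors = vecs_all)
    }
  }
  out
}

#' Layout frame from the simulator's truth
#'
#' @param frag a [fragment_into_contigs()] result.
#' @return a layout frame in true chromosome coordinates (offsets are the
#'   contigs' true starts, orientation `-` for flipped contigs).
#' @export
truth_layout_frame <- function(frag) {
  lt <- frag$layout_truth
  data.frame(chrom = lt$chrom, order = lt$order, contig = lt$contig,
             orientation = ifelse(lt$flipped, "-", "+"),
             offset = lt$chrom_start, length = lt$length,
             stringsAsFactors = FALSE)
}

#' Layout frame from an estimated scaffold layout
#'
#' @param layout a [order_and_orient()] result.
#' @param contig_lengths named lengths (bp).
#' @param gap_length assumed gap between consecutive contigs (bp).
#' @return a layout frame in scaffold coordinates.
#' @export
layout_frame <- function(layout, contig_lengths, gap_length = 100) {
  pl <- layout$placement
  pl <- pl[!is.na(pl$order), , drop = FALSE]
  out <- list()
  for (ch in unique(pl$chrom)) {
    rows <- pl[pl$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$order), , drop = FALSE]
    len <- as.numeric(contig_lengths[rows$contig])
    offset <- cumsum(c(0, utils::head(len + gap_length, -1)))
    out[[ch]] <- data.frame(chrom = ch, order = rows$order,
                            contig = rows$contig,
                            orientation = rows$orientation,
                            offset = offset, length = len,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Call crossover events from projected bins
#'
#' For each drone and each pair of adjacent bins at which the drone's
#' phased alleles differ (both observed), one crossover event is emitted
#' on the inter-bin interval: from the last SNP of the left bin to the
#' first SNP of the right bin.
#'
#' @param projection a [project_bins()] result.
#' @return data.frame `colony`, `drone`, `chrom`, `start`, `end`.
#' @export
call_crossovers <- function(projection) {
  out <- list()
  for (colony in names(projection)) {
    for (ch in names(projection[[colony]])) {
      pr <- projection[[colony]][[ch]]
      nb <- nrow(pr$bins)
      if (nb < 2) next
      for (k in seq_len(nb - 1)) {
        a <- pr$vectors[k, ]; b <- pr$vectors[k + 1, ]
        diff <- which(!is.na(a) & !is.na(b) & a != b)
        if (!length(diff)) next
        out[[length(out) + 1L]] <- data.frame(
          colony = colony, drone = colnames(pr$vectors)[diff],
          chrom = ch, start = pr$bins$end[k], end = pr$bins$start[k + 1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(colony = character(), drone = character(),
                      chrom = character(), start = numeric(),
                      end = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genetic-map summary from crossover events
#'
#' Pools events over colonies: the genetic size of a chromosome in
#' Morgans is its event count divided by the number of meioses (replicate
#' drones count once), the recombination rate is
#' `100 * Morgans / physical Mb`, and crossovers per chromosome per
#' meiosis is the per-chromosome Morgans figure.
#'
#' @param events data.frame as from [call_crossovers()].
#' @param n_meioses total number of distinct drones.
#' @param chrom_sizes named numeric, physical size per chromosome (bp).
#' @return object of class `genetic_map`: `per_chromosome` data.frame and
#'   totals (`physical_mb`, `morgans`, `cm_per_mb`, `co_per_chromosome`).
#' @export
map_length <- function(events, n_meioses, chrom_sizes) {
  if (n_meioses <= 0) stop("n_meioses must be positive")
  cnt <- table(factor(events$chrom, levels = names(chrom_sizes)))
  per <- data.frame(chrom = names(chrom_sizes),
                    physical_mb = as.numeric(chrom_sizes) / 1e6,
                    n_events = as.numeric(cnt))
  per$morgans <- per$n_events / n_meioses
  per$cm_per_mb <- 100 * per$morgans / per$physical_mb
  tot_m <- sum(per$morgans); tot_mb <- sum(per$physical_mb)
  structure(list(per_chromosome = per, physical_mb = tot_mb,
                 morgans = tot_m,
                 cm_per_mb = 100 * tot_m / tot_mb,
                 co_per_chromosome = tot_m / nrow(per),
                 n_meioses = n_meioses),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(paste0("<genetic_map> %.0f Mb, %.1f Morgans over %.0f meioses: ",
                     "%.1f cM/Mb, %.1f CO/chromosome\n"),
              x$physical_mb, x$morgans, x$n_meioses, x$cm_per_mb,
              x$co_per_chromosome))
  invisible(x)
}

#' Genetic-map arithmetic from published totals
#'
#' The identities used in genetic-map comparison tables: recombination
#' rate `cM/Mb = 100 * Morgans / Mb` and mean crossovers per chromosome
#' per meiosis `Morgans / n_chromosomes`.
#'
#' @param physical_mb genome physical size (Mb).
#' @param genetic_morgans genetic size (Morgans).
#' @param n_chromosomes number of chromosomes (optional).
#' @return list `cm_per_mb` and (when `n_chromosomes` given)
#'   `co_per_chromosome`.
#' @export
genetic_map_stats <- function(physical_mb, genetic_morgans,
                              n_chromosomes = NULL) {
  out <- list(cm_per_mb = 100 * genetic_morgans / physical_mb)
  if (!is.null(n_chromosomes))
    out$co_per_chromosome <- genetic_morgans / n_chromosomes
  out
}

#' Windowed recombination-rate track
#'
#' Each crossover event distributes unit mass uniformly over its
#' localisation interval (a zero-length interval gives its whole mass to
#' the containing window); the rate of a window is
#' `(mass / n_meioses) * 100 / window Mb`, using the true (possibly
#' short) size of the last window.
#'
#' @param events data.frame with `chrom`, `start`, `end`.
#' @param n_meioses number of meioses.
#' @param chrom_sizes named numeric (bp).
#' @param window window width (bp).
#' @return data.frame `chrom`, `start`, `end`, `mass`, `cm_per_mb`.
#' @export
windowed_recombination_rate <- function(events, n_meioses, chrom_sizes,
                                        window = 1e6) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    mass <- numeric(length(starts))
    ev <- events[events$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      s <- ev$start[k]; e <- ev$end[k]
      if (e <= s) {
        w <- min(max(findInterval(s, starts), 1), length(starts))
        mass[w] <- mass[w] + 1
      } else {
        ov <- pmin(e, ends) - pmax(s, starts)
        ov[ov < 0] <- 0
        mass <- mass + ov / (e - s)
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            mass = mass,
                            cm_per_mb = (mass / n_meioses) * 100 /
                              ((ends - starts) / 1e6))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' GC content in fixed windows
#'
#' @param seqs a [Biostrings::DNAStringSet] (one entry per chromosome).
#' @param window window width (bp).
#' @return data.frame `chrom`, `start`, `end`, `gc` (fraction of G+C over
#'   unambiguous bases; NA when a window has no unambiguous base).
#' @export
gc_content_windows <- function(seqs, window = 5e5) {
  out <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    L <- length(s)
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    v <- Biostrings::Views(s, start = starts + 1, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends, gc = gc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag recombination hotspots between informative SNPs
#'
#' Events are localised to intervals between adjacent informative SNPs;
#' an interval where the pooled event count is strictly greater than the
#' threshold is flagged. On a correct assembly such pile-ups are rare, so
#' flagged intervals - particularly at contig junctions - diagnose
#' mis-assembled (inverted) segments that inflate the genetic map.
#'
#' @param events data.frame with `chrom`, `start`, `end` (events pooled
#'   over colonies).
#' @param threshold flag intervals with more than this many events.
#' @return data.frame `chrom`, `start`, `end`, `n_events` of flagged
#'   intervals.
#' @export
detect_hotspots <- function(events, threshold = 5) {
  if (!nrow(events))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_events = integer()))
  key <- paste(events$chrom, events$start, events$end)
  tab <- table(key)
  hot <- names(tab)[tab > threshold]
  if (!length(hot))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_events = integer()))
  parts <- do.call(rbind, strsplit(hot, " "))
  res <- data.frame(chrom = parts[, 1], start = as.numeric(parts[, 2]),
                    end = as.numeric(parts[, 3]),
                    n_events = as.integer(tab[hot]))
  res[order(res$chrom, res$start), , drop = FALSE]
}
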