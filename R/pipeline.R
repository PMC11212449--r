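#' Convert genotype strings to haplotype codes
#'
#' @param gt character matrix of haploid genotype codes (`"0"`, `"1"`,
#'   `"."`).
#' @return integer matrix with NA for missing.
#' @export
gt_codes <- function(gt) {
  out <- suppressWarnings(matrix(as.integer(gt), nrow(gt),
                                 dimnames = dimnames(gt)))
  out
}

#' Map chromosome-coordinate sites onto contigs
#'
#' @param sites data.frame `chrom`, `start` (chromosome coordinates).
#' @param frag a [fragment_into_contigs()] result.
#' @return data.frame `contig`, `pos` (contig-local, flip-aware) aligned
#'   to the rows of `sites`; NA for sites falling in no contig (inside a
#'   breaking repeat array).
#' @export
map_sites_to_contigs <- function(sites, frag) {
  lt <- frag$layout_truth
  contig <- rep(NA_character_, nrow(sites))
  pos <- rep(NA_real_, nrow(sites))
  for (k in seq_len(nrow(lt))) {
    sel <- sites$chrom == lt$chrom[k] & sites$start >= lt$chrom_start[k] &
      sites$start < lt$chrom_end[k]
    if (!any(sel)) next
    contig[sel] <- lt$contig[k]
    pos[sel] <- if (lt$flipped[k]) lt$chrom_end[k] - 1 - sites$start[sel]
    else sites$start[sel] - lt$chrom_start[k]
  }
  data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
}

#' Bin and phase every contig of every colony
#'
#' For each colony and each contig with informative sites: group sites
#' into bins ([build_bins()]), phase by recombination minimisation
#' ([phase_contig()]) and remove non-crossover gene-conversion bins
#' ([detect_nco_conversions()]).
#'
#' @param colonies filtered colonies (as the `colonies` element of a
#'   [filter_biological()] result).
#' @param frag a [fragment_into_contigs()] result (defines the contigs).
#' @param nco_threshold conversion-bin length threshold (bp); `NULL`
#'   skips the conversion filter.
#' @return list per colony: `phased` (named list of `phased_contig`) and
#'   `flagged` (data.frame of removed bins with a `colony` column).
#' @export
phase_colonies <- function(colonies, frag, nco_threshold = 2000) {
  out <- list()
  for (co in colonies) {
    v <- co$vcf
    cmap <- map_sites_to_contigs(v$sites, frag)
    gt <- gt_codes(v$gt[, co$drones, drop = FALSE])
    phased <- list(); flagged <- list()
    for (tig in sort(unique(stats::na.omit(cmap$contig)))) {
      idx <- which(cmap$contig == tig)
      idx <- idx[order(cmap$pos[idx])]
      bins <- build_bins(cmap$pos[idx], gt[idx, , drop = FALSE], tig)
      pc <- phase_contig(bins)
      if (!is.null(nco_threshold)) {
        res <- detect_nco_conversions(pc, nco_threshold)
        pc <- res$pc
        if (nrow(res$flagged))
          flagged[[length(flagged) + 1L]] <-
            cbind(colony = co$colony, res$flagged)
      }
      phased[[tig]] <- pc
    }
    out[[co$colony]] <- list(
      colony = co$colony, phased = phased,
      flagged = if (length(flagged)) do.call(rbind, flagged) else
        data.frame(colony = character(), contig = character(),
                   start = numeric(), end = numeric(), n_snps = integer(),
                   rule = character()))
  }
  out
}

#' Collect contig end vectors across colonies
#'
#' @param phase_result output of [phase_colonies()].
#' @return named list per contig: `L`, `R` (per-colony phased end
#'   vectors) and `orientable` (at least two bins in some colony), ready
#'   for [order_and_orient()].
#' @export
collect_contig_ends <- function(phase_result) {
  contigs <- sort(unique(unlist(lapply(phase_result, function(cr)
    names(cr$phased)))))
  ends <- list()
  for (tig in contigs) {
    L <- list(); R <- list(); orientable <- FALSE
    for (colony in names(phase_result)) {
      pc <- phase_result[[colony]]$phased[[tig]]
      if (is.null(pc) || !nrow(pc$vectors)) next
      ev <- contig_end_vectors(pc)
      L[[colony]] <- ev$left
      R[[colony]] <- ev$right
      orientable <- orientable || ev$orientable
    }
    ends[[tig]] <- list(L = L, R = R, orientable = orientable)
  }
  ends
}

#' Run the full scaffolding pipeline on a simulated data set
#'
#' Quality filtering (hard site filters, then the biological discard
#' rules), per-contig binning/phasing/conversion-filtering per colony,
#' contig-end collection and greedy crossover-minimising scaffolding.
#'
#' @param sim a [simulate_colonies()] result.
#' @param frag a [fragment_into_contigs()] result.
#' @param nco_threshold conversion-bin length threshold (bp).
#' @param accept_threshold adoption threshold for unassigned contigs.
#' @param assignment optional replacement for `frag$assignment`.
#' @return list: `qc` (report), `colonies` (filtered), `phase`
#'   (per-colony phased contigs), `ends`, `layout` (scaffold_layout),
#'   `status` (placement classification).
#' @export
run_scaffold_pipeline <- function(sim, frag, nco_threshold = 2000,
                                  accept_threshold = 1,
                                  assignment = NULL) {
  filtered <- lapply(sim$colonies, function(co) {
    co$vcf <- filter_site_quality(co$vcf)
    co
  })
  bio <- filter_biological(filtered)
  phs <- phase_colonies(bio$colonies, frag, nco_threshold)
  ends <- collect_contig_ends(phs)
  if (is.null(assignment)) assignment <- frag$assignment
  layout <- order_and_orient(ends, assignment, accept_threshold)
  informative <- lapply(ends, function(e) length(e$L) > 0)
  all_ctg <- unique(c(names(informative), layout$placement$contig))
  informative <- stats::setNames(
    all_ctg %in% names(informative)[vapply(informative, isTRUE, TRUE)],
    all_ctg)
  status <- classify_placement(layout, as.list(informative))
  list(qc = bio$report, colonies = bio$colonies, phase = phs,
       ends = ends, layout = layout, status = status)
}

#' Fraction of true contig adjacencies recovered by a layout
#'
#' @param layout a `scaffold_layout`.
#' @param frag the [fragment_into_contigs()] truth.
#' @return list `recovered`, `n_truth`, `fraction`.
#' @export
adjacency_recovery <- function(layout, frag) {
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lt <- frag$layout_truth
  truth <- unlist(lapply(split(lt, lt$chrom), function(g) {
    g <- g[order(g$order), ]
    if (nrow(g) < 2) return(character())
    pair_key(g$contig[-nrow(g)], g$contig[-1])
  }))
  pl <- layout$placement
  pl <- pl[!is.na(pl$order), , drop = FALSE]
  est <- unlist(lapply(split(pl, pl$chrom), function(g) {
    g <- g[order(g$order), ]
    if (nrow(g) < 2) return(character())
    pair_key(g$contig[-nrow(g)], g$contig[-1])
  }))
  rec <- sum(truth %in% est)
  list(recovered = rec, n_truth = length(truth),
       fraction = if (length(truth)) rec / length(truth) else NA_real_)
}

#' Orientation accuracy of orientable placed contigs
#'
#' Orientations are compared up to a global flip of each chromosome path
#' (a reversed path is the same layout).
#'
#' @param layout a `scaffold_layout`.
#' @param frag the truth.
#' @param ends contig-end structure (for orientable flags).
#' @return list `correct`, `n_orientable`, `fraction`.
#' @export
orientation_accuracy <- function(layout, frag, ends) {
  lt <- frag$layout_truth
  truth_ori <- stats::setNames(ifelse(lt$flipped, "-", "+"), lt$contig)
  truth_ord <- stats::setNames(lt$order, lt$contig)
  pl <- layout$placement
  pl <- pl[!is.na(pl$order), , drop = FALSE]
  correct <- 0L; n <- 0L
  for (ch in unique(pl$chrom)) {
    g <- pl[pl$chrom == ch, , drop = FALSE]
    g <- g[order(g$order), ]
    tord <- truth_ord[g$contig]
    reversed <- nrow(g) > 1 && !is.unsorted(rev(tord))
    for (k in seq_len(nrow(g))) {
      tig <- g$contig[k]
      if (!isTRUE(ends[[tig]]$orientable)) next
      if (is.na(g$orientation[k])) next
      n <- n + 1L
      want <- truth_ori[[tig]]
      got <- g$orientation[k]
      if (reversed) got <- if (got == "+") "-" else "+"
      if (got == want) correct <- correct + 1L
    }
  }
  list(correct = correct, n_orientable = n,
       fraction = if (n) correct / n else NA_real_)
}

#' Evaluate conversion-tract detection against the simulated truth
#'
#' A planted gene-conversion tract counts as detectable when it is
#' shorter than the threshold, lies within a single contig, and contains
#' at least one site retained after quality control in its colony. It
#' counts as detected when a flagged conversion bin of the same colony
#' overlaps it on the chromosome.
#'
#' @param sim the [simulate_colonies()] result (for the truth).
#' @param frag the fragmentation truth.
#' @param phase_result a [phase_colonies()] result.
#' @param colonies the filtered colonies used for phasing.
#' @param threshold tract length bound (bp).
#' @return list `n_detectable`, `n_detected`, `fraction`.
#' @export
nco_detection_stats <- function(sim, frag, phase_result, colonies,
                                threshold = 2000) {
  tr <- sim$truth$conversions
  tr <- tr[tr$end - tr$start < threshold, , drop = FALSE]
  lt <- frag$layout_truth
  n_detectable <- 0L; n_detected <- 0L
  for (colony in names(phase_result)) {
    co_tr <- tr[tr$colony == colony, , drop = FALSE]
    if (!nrow(co_tr)) next
    co <- colonies[[colony]]
    sites <- co$vcf$sites
    fl <- phase_result[[colony]]$flagged
    # flagged bins back to chromosome coordinates
    if (nrow(fl)) {
      m <- match(fl$contig, lt$contig)
      chrom <- lt$chrom[m]
      fs <- ifelse(lt$flipped[m], lt$chrom_end[m] - fl$end - 1,
                   lt$chrom_start[m] + fl$start)
      fe <- ifelse(lt$flipped[m], lt$chrom_end[m] - fl$start,
                   lt$chrom_start[m] + fl$end + 1)
      fl_iv <- data.frame(chrom = chrom, start = fs, end = fe)
    } else fl_iv <- NULL
    for (k in seq_len(nrow(co_tr))) {
      t1 <- co_tr[k, ]
      inside <- sites$chrom == t1$chrom & sites$start >= t1$start &
        sites$start < t1$end
      if (!any(inside)) next
      in_contig <- lt$chrom == t1$chrom & lt$chrom_start <= t1$start &
        lt$chrom_end >= t1$end
      if (!any(in_contig)) next
      n_detectable <- n_detectable + 1L
      if (!is.null(fl_iv)) {
        hit <- fl_iv$chrom == t1$chrom & fl_iv$start < t1$end &
          fl_iv$end > t1$start
        if (any(hit)) n_detected <- n_detected + 1L
      }
    }
  }
  list(n_detectable = n_detectable, n_detected = n_detected,
       fraction = if (n_detectable) n_detected / n_detectable else
         NA_real_)
}

#' Which true crossovers are recovered by a set of called events
#'
#' A true crossover is recovered when an event of the same colony, drone
#' and chromosome has a localisation interval containing its position.
#'
#' @param events data.frame from [call_crossovers()] in true chromosome
#'   coordinates (project on [truth_layout_frame()]).
#' @param truth_co the simulator's `truth$crossovers`.
#' @return logical vector along the rows of `truth_co`.
#' @export
recovered_crossovers <- function(events, truth_co) {
  vapply(seq_len(nrow(truth_co)), function(k) {
    t1 <- truth_co[k, ]
    any(events$colony == t1$colony & events$drone == t1$drone &
          events$chrom == t1$chrom & events$start <= t1$pos &
          events$end >= t1$pos)
  }, TRUE)
}
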