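#' Simulate a genome with planted tandem-repeat arrays
#'
#' Plants the two major honey-bee tandem-repeat families on each
#' chromosome: a 371 bp-like family (period 367-371) and a 91 bp-like
#' family (period 91-93), with configured totals and numbers of "selected"
#' arrays (strictly more than ten copies). A configured number of long
#' 371-family arrays per chromosome exceeds the read-length proxy and will
#' break the assembly into contigs. Telomeric TTAGG arrays (at least 842
#' copies) are planted at chromosome ends, one interstitial TTAGG and one
#' terminal AATAT array mirror the minor observations the telomere caller
#' must classify. Every array carries its own random monomer.
#'
#' @param cfg a [sim_config].
#' @param sequence when TRUE, also build chromosome sequences (random
#'   uniform A/C/G/T outside arrays; arrays are tandem copies of the
#'   monomer with a per-copy substitution rate of
#'   `cfg$monomer_mutation_rate`).
#' @return list with `arrays` (data.frame: `chrom`, `start`, `end`,
#'   `period`, `copies`, `consensus`, `family`, `breaker`, `telomere`) and,
#'   when requested, `sequences` (a [Biostrings::DNAStringSet]).
#' @export
simulate_genome <- function(cfg, sequence = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  chroms <- names(cfg$chromosome_lengths)
  nchr <- length(chroms)
  rand_monomer <- function(p)
    paste(sample(c("A", "C", "G", "T"), p, replace = TRUE), collapse = "")

  rows <- list()
  add <- function(chrom, start, period, copies, consensus, family,
                  breaker = FALSE, telomere = FALSE) {
    len <- round(period * copies)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = start + len, period = period,
      copies = copies, consensus = consensus, family = family,
      breaker = breaker, telomere = telomere, stringsAsFactors = FALSE)
  }

  # telomeric arrays at chromosome extremities
  for (ci in seq_len(nchr)) {
    ch <- chroms[ci]
    L <- cfg$chromosome_lengths[[ci]]
    motif_start <- if (ci == nchr) "AATAT" else "TTAGG"
    cp <- sample(842:1500, 1)
    add(ch, 0, 5, cp, motif_start, "other", telomere = TRUE)
    cp2 <- sample(842:1500, 1)
    add(ch, L - 5 * cp2, 5, cp2, "TTAGG", "other", telomere = TRUE)
  }
  # one interstitial TTAGG, well inside chromosome 1
  add(chroms[1], round(cfg$chromosome_lengths[[1]] * 0.42), 5,
      sample(15:117, 1), "TTAGG", "other")

  nb <- cfg$breaks_per_chromosome
  if (nb * nchr > cfg$repeat_selected[["f371"]])
    stop("more breaker arrays than selected 371-family arrays")
  # breaker arrays: evenly spaced with jitter so contigs have similar sizes
  for (ci in seq_len(nchr)) {
    ch <- chroms[ci]
    L <- cfg$chromosome_lengths[[ci]]
    if (nb == 0) next
    anchors <- (seq_len(nb) / (nb + 1)) * L
    jit <- stats::runif(nb, -0.04, 0.04) * L
    for (b in seq_len(nb)) {
      p <- sample(367:371, 1)
      cp <- ceiling(cfg$read_length / p) + sample(2:10, 1)
      add(ch, round(anchors[b] + jit[b]), p, cp, rand_monomer(p), "371",
          breaker = TRUE)
    }
  }
  # interior arrays, uniform over chromosomes
  interior <- function(n, period_range, copies_range, family) {
    if (n <= 0) return()
    ch_idx <- sample(nchr, n, replace = TRUE)
    for (k in seq_len(n)) {
      ch <- chroms[ch_idx[k]]
      L <- cfg$chromosome_lengths[[ch_idx[k]]]
      p <- sample(period_range, 1)
      # fractional part stays below 1 so the strict >10 copy threshold is
      # decided by the integer part alone
      cp <- sample(copies_range, 1) + round(stats::runif(1, 0, 0.9), 1)
      add(ch, round(stats::runif(1, 0.02 * L, 0.95 * L)), p, cp,
          rand_monomer(p), family)
    }
  }
  sel371 <- cfg$repeat_selected[["f371"]] - nb * nchr
  max_cp_371 <- floor((cfg$read_length - 1) / 371)
  interior(sel371, 367:371, 11:max_cp_371, "371")
  interior(cfg$repeat_totals[["f371"]] - cfg$repeat_selected[["f371"]],
           367:371, 2:9, "371")
  interior(cfg$repeat_selected[["f91"]], 91:93, 11:95, "91")
  interior(cfg$repeat_totals[["f91"]] - cfg$repeat_selected[["f91"]],
           91:93, 2:9, "91")

  arrays <- do.call(rbind, rows)
  # resolve overlaps deterministically: sort and push arrays right
  out <- list()
  for (ch in chroms) {
    a <- arrays[arrays$chrom == ch, , drop = FALSE]
    a <- a[order(a$start, -a$end), , drop = FALSE]
    for (k in seq_len(nrow(a))[-1]) {
      if (a$start[k] < a$end[k - 1] + 200) {
        shift <- a$end[k - 1] + 200 - a$start[k]
        a$start[k] <- a$start[k] + shift
        a$end[k] <- a$end[k] + shift
      }
    }
    if (any(a$end > cfg$chromosome_lengths[[ch]])) {
      over <- a$end > cfg$chromosome_lengths[[ch]] & !a$telomere
      a <- a[!over, , drop = FALSE]
    }
    out[[ch]] <- a
  }
  arrays <- do.call(rbind, out)
  rownames(arrays) <- NULL

  res <- list(cfg = cfg, arrays = arrays)
  if (sequence) {
    mutate_copy <- function(mono, rate) {
      x <- strsplit(mono, "")[[1]]
      hit <- stats::runif(length(x)) < rate
      if (any(hit))
        x[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(x, collapse = "")
    }
    seqs <- lapply(chroms, function(ch) {
      L <- cfg$chromosome_lengths[[ch]]
      base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      a <- arrays[arrays$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(a))) {
        ncop <- ceiling(a$copies[k])
        copies <- vapply(seq_len(ncop), function(i)
          mutate_copy(a$consensus[k], cfg$monomer_mutation_rate), "")
        tandem <- substr(paste(copies, collapse = ""), 1,
                         a$end[k] - a$start[k])
        base[(a$start[k] + 1):a$end[k]] <- strsplit(tandem, "")[[1]]
      }
      paste(base, collapse = "")
    })
    res$sequences <- Biostrings::DNAStringSet(
      stats::setNames(unlist(seqs), chroms))
  }
  res
}

#' Fragment simulated chromosomes into contigs at long repeat arrays
#'
#' Chromosomes break at every array strictly longer than the read-length
#' proxy (`cfg$read_length`): such arrays cannot be assembled and the
#' flanking sequence becomes separate contigs. Contigs are renamed in a
#' shuffled order and randomly flipped; the true layout is recorded. A
#' configurable fraction of contigs is withheld from the a-priori
#' chromosome-assignment table to exercise placement from crossover data
#' alone. Both contig ends facing a breaking array carry that array's
#' period and monomer as terminal-repeat annotations.
#'
#' @param cfg a [sim_config].
#' @param genome output of [simulate_genome()].
#' @return list with `layout_truth` (chrom, order, contig, flipped,
#'   chrom_start, chrom_end, length, left/right terminal-array period and
#'   consensus in *contig* orientation), `assignment` (contig -> chrom
#'   table with some contigs withheld) and `contig_lengths`.
#' @export
fragment_into_contigs <- function(cfg, genome) {
  set.seed(cfg$seed + 2L)
  arrays <- genome$arrays
  rows <- list()
  for (ch in names(cfg$chromosome_lengths)) {
    L <- cfg$chromosome_lengths[[ch]]
    br <- arrays[arrays$chrom == ch &
                   (arrays$end - arrays$start) > cfg$read_length, ,
                 drop = FALSE]
    br <- br[order(br$start), , drop = FALSE]
    bounds <- rbind(data.frame(start = c(0, br$end),
                               end = c(br$start, L)))
    if (any(bounds$end <= bounds$start))
      stop("contig break policy produced a zero-length contig on ", ch)
    for (k in seq_len(nrow(bounds))) {
      left <- if (k == 1) NA_integer_ else k - 1L
      right <- if (k == nrow(bounds)) NA_integer_ else k
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, order = k, chrom_start = bounds$start[k],
        chrom_end = bounds$end[k],
        left_period = if (is.na(left)) NA_real_ else br$period[left],
        left_consensus = if (is.na(left)) NA_character_ else
          br$consensus[left],
        right_period = if (is.na(right)) NA_real_ else br$period[right],
        right_consensus = if (is.na(right)) NA_character_ else
          br$consensus[right],
        stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, rows)
  n <- nrow(layout)
  layout$contig <- sprintf("tig%05d", sample.int(n))
  layout$flipped <- sample(c(TRUE, FALSE), n, replace = TRUE)
  layout$length <- layout$chrom_end - layout$chrom_start
  # terminal annotations in contig orientation (flip swaps ends)
  flip <- layout$flipped
  tmp_p <- layout$left_period[flip]
  tmp_c <- layout$left_consensus[flip]
  layout$left_period[flip] <- layout$right_period[flip]
  layout$left_consensus[flip] <- layout$right_consensus[flip]
  layout$right_period[flip] <- tmp_p
  layout$right_consensus[flip] <- tmp_c
  assignment <- data.frame(contig = layout$contig, chrom = layout$chrom,
                           stringsAsFactors = FALSE)
  n_withhold <- round(cfg$assignment_missing_frac * n)
  withheld <- character()
  if (n_withhold > 0) {
    withheld <- sample(layout$contig, n_withhold)
    assignment <- assignment[!assignment$contig %in% withheld, , drop = FALSE]
  }
  list(layout_truth = layout[order(layout$chrom, layout$order), ],
       assignment = assignment, withheld = withheld,
       contig_lengths = stats::setNames(layout$length, layout$contig))
}

#' Extract contig sequences from a simulated genome
#'
#' @param genome output of [simulate_genome()] with `sequence = TRUE`.
#' @param frag output of [fragment_into_contigs()].
#' @return a [Biostrings::DNAStringSet], flipped contigs reverse-complemented.
#' @export
contig_sequences <- function(genome, frag) {
  stopifnot(!is.null(genome$sequences))
  lt <- frag$layout_truth
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(lt)), function(k) {
    s <- Biostrings::subseq(genome$sequences[[lt$chrom[k]]],
                            lt$chrom_start[k] + 1, lt$chrom_end[k])
    if (lt$flipped[k]) s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, ""))
  names(seqs) <- lt$contig
  seqs
}

#' Default presence/absence indel panel
#'
#' Two medium-size indels shaped after nuclear-mitochondrial insertions
#' that differ between subspecies: one near-fixed in the first population
#' and rare elsewhere, one near-fixed in the second population and
#' segregating at low frequency in the third.
#'
#' @param cfg a [sim_config].
#' @return data.frame with `id`, `chrom`, `start`, `end` and one
#'   `freq_<population>` column per population.
#' @export
default_indel_panel <- function(cfg) {
  ch <- names(cfg$chromosome_lengths)
  panel <- data.frame(
    id = c("numtA", "numtB"),
    chrom = ch[c(1, min(2, length(ch)))],
    start = c(1e6, 2e6), end = c(1e6 + 745, 2e6 + 576),
    stringsAsFactors = FALSE)
  freqs <- rbind(c(1, 2 / 30, 0), c(0, 29 / 30, 4 / 15))
  colnames(freqs) <- paste0("freq_", names(cfg$populations))
  cbind(panel, freqs)
}

#' Simulate per-sample depth profiles over an indel panel
#'
#' Per-base depth is Poisson with the sample's mean depth over flanking
#' sequence; over the indel interval it is Poisson with the same mean when
#' the indel is present in the sample and Poisson with mean scaled by the
#' residual mis-mapping fraction when absent.
#'
#' @param cfg a [sim_config].
#' @param panel indel panel as from [default_indel_panel()].
#' @param lambda per-sample mean depth; scalar or one value per sample
#'   (defaults to `cfg$depth_lambda` for all samples).
#' @return list with `profiles` (list `[[indel id]][[sample]]` of
#'   data.frames `pos`, `depth` spanning the indel and its flanks) and
#'   `truth` (sample, population, indel, present).
#' @export
simulate_depth_profiles <- function(cfg, panel = default_indel_panel(cfg),
                                    lambda = NULL) {
  set.seed(cfg$seed + 3L)
  pops <- cfg$populations
  samples <- unlist(lapply(names(pops), function(p)
    sprintf("%s%02d", p, seq_len(pops[[p]]))))
  pop_of <- rep(names(pops), pops)
  if (is.null(lambda)) lambda <- cfg$depth_lambda
  lam <- rep_len(lambda, length(samples))
  if (any(lam <= 0)) stop("depth_lambda must be > 0")
  profiles <- list(); truth <- list()
  for (vi in seq_len(nrow(panel))) {
    id <- panel$id[vi]
    len <- panel$end[vi] - panel$start[vi]
    flank <- min(max(len, 500), 5000)
    pos <- (panel$start[vi] - flank):(panel$end[vi] + flank - 1)
    inside <- pos >= panel$start[vi] & pos < panel$end[vi]
    profiles[[id]] <- list()
    for (si in seq_along(samples)) {
      fr <- panel[[paste0("freq_", pop_of[si])]][vi]
      present <- stats::runif(1) < fr
      mu <- rep(lam[si], length(pos))
      if (!present) mu[inside] <- lam[si] * cfg$background_mismap
      profiles[[id]][[samples[si]]] <- data.frame(
        pos = pos, depth = stats::rpois(length(pos), mu))
      truth[[length(truth) + 1L]] <- data.frame(
        sample = samples[si], population = pop_of[si], indel = id,
        present = present, lambda = lam[si], stringsAsFactors = FALSE)
    }
  }
  list(panel = panel, profiles = profiles, truth = do.call(rbind, truth))
}
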