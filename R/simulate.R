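#' Configuration for the meiosis/genome simulator
#'
#' The defaults reproduce the structure of the drone-sequencing study the
#' pipeline is built for: three colonies of 15, 15 and 13 drones (43
#' meioses), with three drones of the first colony sequenced in duplicate;
#' queen-heterozygous biallelic SNPs at about 1 per kb; crossovers Poisson
#' at 23 cM/Mb with no interference; short non-crossover gene-conversion
#' tracts (geometric length, mean 500 bp, so most fall under the 2 kb
#' detection threshold); a small genotyping error and missingness rate; and
#' a genome carrying the two major tandem-repeat families (371 bp and
#' 91 bp periods), long arrays of which break the assembly into contigs.
#' The genome is scaled down to four 5 Mb chromosomes so that every
#' analysis runs in seconds while keeping tens of crossovers per
#' chromosome.
#'
#' @param seed integer RNG seed; identical configs give identical output.
#' @param chromosome_lengths numeric vector of chromosome lengths (bp).
#' @param snp_density expected queen-heterozygous SNPs per bp.
#' @param colonies list of `c(n_drones, n_replicates)` per colony.
#' @param recombination_rate genome-wide rate in cM/Mb.
#' @param nco_rate expected gene-conversion tracts per meiosis per
#'   chromosome.
#' @param nco_tract_mean mean conversion tract length (bp, geometric).
#' @param genotyping_error_rate probability a haploid drone call is flipped.
#' @param missing_rate probability a call is missing.
#' @param bad_site_frac fraction of sites given failing FS/MQ/SOR
#'   annotations (exercises the hard filters).
#' @param repeat_totals named vector: total planted arrays per family
#'   (`f371`, `f91`) genome-wide.
#' @param repeat_selected named vector: how many arrays per family carry
#'   strictly more than ten copies.
#' @param breaks_per_chromosome long (assembly-breaking) 371-family arrays
#'   per chromosome; counted inside `repeat_totals`/`repeat_selected`.
#' @param monomer_mutation_rate per-base substitution rate applied to each
#'   repeat copy when sequence is generated.
#' @param read_length read-length proxy: arrays strictly longer than this
#'   break the assembly into contigs.
#' @param assignment_missing_frac fraction of contigs withheld from the
#'   a-priori chromosome-assignment table.
#' @param depth_lambda mean per-base sequencing depth for depth simulation.
#' @param background_mismap residual depth fraction over an absent indel.
#' @param populations named integer vector of haploid sample counts per
#'   population for indel genotyping.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chromosome_lengths = rep(5e6, 4),
                       snp_density = 1e-3,
                       colonies = list(c(15, 3), c(15, 0), c(13, 0)),
                       recombination_rate = 23,
                       nco_rate = 1,
                       nco_tract_mean = 500,
                       genotyping_error_rate = 0.002,
                       missing_rate = 0.001,
                       bad_site_frac = 0.01,
                       repeat_totals = c(f371 = 131, f91 = 345),
                       repeat_selected = c(f371 = 74, f91 = 43),
                       breaks_per_chromosome = 4,
                       monomer_mutation_rate = 0.01,
                       read_length = 10000,
                       assignment_missing_frac = 0.1,
                       depth_lambda = 30,
                       background_mismap = 0.02,
                       populations = c(mellifera = 35, ligustica = 30,
                                       caucasica = 15)) {
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  stopifnot(snp_density > 0, recombination_rate >= 0, nco_rate >= 0,
            nco_tract_mean >= 1,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  cfg <- list(seed = seed, chromosome_lengths = chromosome_lengths,
              snp_density = snp_density, colonies = colonies,
              recombination_rate = recombination_rate, nco_rate = nco_rate,
              nco_tract_mean = nco_tract_mean,
              genotyping_error_rate = genotyping_error_rate,
              missing_rate = missing_rate, bad_site_frac = bad_site_frac,
              repeat_totals = repeat_totals,
              repeat_selected = repeat_selected,
              breaks_per_chromosome = breaks_per_chromosome,
              monomer_mutation_rate = monomer_mutation_rate,
              read_length = read_length,
              assignment_missing_frac = assignment_missing_frac,
              depth_lambda = depth_lambda,
              background_mismap = background_mismap,
              populations = populations)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d chromosomes (%.1f Mb), %d colonies ",
                     "(%d meioses), %g cM/Mb, seed %d\n"),
              length(x$chromosome_lengths),
              sum(x$chromosome_lengths) / 1e6, length(x$colonies),
              sum(vapply(x$colonies, `[`, 0, 1)), x$recombination_rate,
              as.integer(x$seed)))
  invisible(x)
}

# Haplotype mosaic of one meiosis: 0/1 indicator of the inherited queen
# haplotype at each position, given crossover positions and conversion
# tracts. Conversion tracts flip the haplotype over [start, end).
.mosaic_at <- function(pos, start_hap, co_pos, tracts) {
  h <- (start_hap + findInterval(pos, sort(co_pos))) %% 2L
  if (!is.null(tracts) && nrow(tracts)) {
    for (k in seq_len(nrow(tracts))) {
      inside <- pos >= tracts$start[k] & pos < tracts$end[k]
      h[inside] <- 1L - h[inside]
    }
  }
  h
}

#' Simulate drone colonies and their genotype calls
#'
#' Draws a master list of queen-heterozygous SNP sites, then for every
#' colony an independent queen phase and one recombinant meiosis per drone:
#' crossover counts are Poisson with mean equal to the chromosome's genetic
#' length in Morgans, crossover positions uniform, and gene-conversion
#' tracts flip the inherited haplotype over a geometric-length tract.
#' Genotyping errors flip haploid calls and missingness blanks them;
#' replicate drones reuse a drone's true meiosis with independent
#' error/missingness draws. The queen is included as sample `queen`
#' (genotype `0/1` at every simulated site).
#'
#' @param cfg a [sim_config].
#' @return an object of class `colony_sim`: list with `sites` (master site
#'   table), `colonies` (per colony: a [vcf_sites] with queen + drone +
#'   replicate columns, plus `drones` and `replicate_of`), and `truth`
#'   (queen phases, crossover positions, conversion tracts).
#' @export
simulate_colonies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- names(cfg$chromosome_lengths)
  sites <- do.call(rbind, lapply(chroms, function(ch) {
    L <- cfg$chromosome_lengths[[ch]]
    n <- stats::rpois(1, cfg$snp_density * L)
    if (n == 0)
      stop("snp_density yields 0 sites on ", ch, "; increase density")
    data.frame(chrom = ch, start = sort(sample.int(L, n) - 1))
  }))
  ns <- nrow(sites)
  ra <- matrix(sample(c("A", "C", "G", "T"), 2 * ns, replace = TRUE),
               ncol = 2)
  same <- ra[, 1] == ra[, 2]
  while (any(same)) {   # ref != alt
    ra[same, 2] <- sample(c("A", "C", "G", "T"), sum(same), replace = TRUE)
    same <- ra[, 1] == ra[, 2]
  }
  sites$ref <- ra[, 1]
  sites$alt <- ra[, 2]

  bad <- stats::runif(ns) < cfg$bad_site_frac
  fs <- stats::runif(ns, 0, 10); mq <- stats::runif(ns, 55, 60)
  sor <- stats::runif(ns, 0.3, 1.5)
  if (any(bad)) {
    which_stat <- sample(3, sum(bad), replace = TRUE)
    fs[bad][which_stat == 1] <- stats::runif(sum(which_stat == 1), 61, 200)
    mq[bad][which_stat == 2] <- stats::runif(sum(which_stat == 2), 10, 49)
    sor[bad][which_stat == 3] <- stats::runif(sum(which_stat == 3), 3.1, 9)
  }
  qual <- round(stats::runif(ns, 500, 3000))

  M_chr <- cfg$recombination_rate / 100 * cfg$chromosome_lengths / 1e6
  colonies <- vector("list", length(cfg$colonies))
  co_truth <- list(); nco_truth <- list(); phases <- list()

  for (ci in seq_along(cfg$colonies)) {
    nd <- cfg$colonies[[ci]][1]
    nrep <- if (length(cfg$colonies[[ci]]) > 1) cfg$colonies[[ci]][2] else 0
    colony_id <- paste0("colony", ci)
    drone_ids <- sprintf("c%dd%02d", ci, seq_len(nd))
    # queen phase: allele code carried by haplotype 0 at each site
    hap0 <- sample(0:1, ns, replace = TRUE)
    phases[[colony_id]] <- hap0
    true_hap <- matrix(NA_integer_, ns, nd, dimnames = list(NULL, drone_ids))
    for (di in seq_len(nd)) {
      for (ch in chroms) {
        idx <- which(sites$chrom == ch)
        L <- cfg$chromosome_lengths[[ch]]
        nco <- stats::rpois(1, M_chr[[ch]])
        co_pos <- if (nco) sort(stats::runif(nco, 0, L)) else numeric()
        ntr <- stats::rpois(1, cfg$nco_rate)
        tracts <- NULL
        if (ntr) {
          ts <- stats::runif(ntr, 0, L)
          tl <- stats::rgeom(ntr, 1 / cfg$nco_tract_mean) + 1
          tracts <- data.frame(start = ts, end = pmin(ts + tl, L))
        }
        start_hap <- sample(0:1, 1)
        true_hap[idx, di] <- .mosaic_at(sites$start[idx], start_hap,
                                        co_pos, tracts)
        if (nco)
          co_truth[[length(co_truth) + 1L]] <- data.frame(
            colony = colony_id, drone = drone_ids[di], chrom = ch,
            pos = co_pos)
        if (ntr)
          nco_truth[[length(nco_truth) + 1L]] <- data.frame(
            colony = colony_id, drone = drone_ids[di], chrom = ch,
            start = tracts$start, end = tracts$end)
      }
    }
    true_allele <- ifelse(true_hap == 1L,
                          1L - matrix(hap0, ns, nd), matrix(hap0, ns, nd))
    observe <- function(allele_mat) {
      obs <- allele_mat
      flip <- matrix(stats::runif(length(obs)) < cfg$genotyping_error_rate,
                     nrow(obs))
      obs[flip] <- 1L - obs[flip]
      out <- matrix(as.character(obs), nrow(obs),
                    dimnames = dimnames(allele_mat))
      out[matrix(stats::runif(length(obs)) < cfg$missing_rate,
                 nrow(obs))] <- "."
      out
    }
    gt_drones <- observe(true_allele)
    replicate_of <- character()
    if (nrep > 0) {
      rep_ids <- sprintf("c%dd%02dr", ci, seq_len(nrep))
      gt_rep <- observe(true_allele[, seq_len(nrep), drop = FALSE])
      colnames(gt_rep) <- rep_ids
      replicate_of <- stats::setNames(drone_ids[seq_len(nrep)], rep_ids)
      gt_drones <- cbind(gt_drones, gt_rep)
    }
    gt <- cbind(queen = rep("0/1", ns), gt_drones)
    st <- sites
    st$qual <- qual; st$fs <- fs; st$mq <- mq; st$sor <- sor
    colonies[[ci]] <- list(colony = colony_id,
                           vcf = vcf_sites(st, gt),
                           drones = drone_ids,
                           replicate_of = replicate_of,
                           true_hap = true_hap)
    names(colonies)[ci] <- colony_id
  }

  empty_co <- data.frame(colony = character(), drone = character(),
                         chrom = character(), pos = numeric())
  structure(list(
    cfg = cfg, sites = sites, colonies = colonies,
    truth = list(
      queen_phase = phases,
      crossovers = if (length(co_truth)) do.call(rbind, co_truth) else empty_co,
      conversions = if (length(nco_truth)) do.call(rbind, nco_truth) else
        cbind(empty_co[0, 1:3], data.frame(start = numeric(), end = numeric())))),
    class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  cat(sprintf("<colony_sim> %d sites, %d colonies, %d true crossovers\n",
              nrow(x$sites), length(x$colonies), nrow(x$truth$crossovers)))
  invisible(x)
}
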