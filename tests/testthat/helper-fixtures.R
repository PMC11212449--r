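# Shared fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Default study conditions: 3 colonies of 15/15/13 drones (3 replicates in
# colony 1), 4 x 5 Mb chromosomes, 1 SNP/kb, 23 cM/Mb, 0.2% genotyping
# error, 20 contigs, seed 42.
default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    cfg <- sim_config(seed = 42)
    sim <- simulate_colonies(cfg)
    genome <- simulate_genome(cfg)
    frag <- fragment_into_contigs(cfg, genome)
    res <- run_scaffold_pipeline(sim, frag)
    .fixture_cache$run <- list(cfg = cfg, sim = sim, genome = genome,
                               frag = frag, res = res)
  }
  .fixture_cache$run
}

# Random phasing instance: bins x drones 0/1 matrix plus positions.
random_bin_instance <- function(n_bins, n_drones) {
  v <- matrix(sample(0:1, n_bins * n_drones, replace = TRUE),
              n_bins, n_drones,
              dimnames = list(NULL, paste0("d", seq_len(n_drones))))
  pos <- sort(sample.int(1e6, n_bins))
  list(bins = data.frame(contig = "t", start = pos, end = pos,
                         n_snps = 1L),
       vectors = v)
}

# Exhaustive minimum recombination count over all 2^(B-1) phase choices.
exhaustive_phase_min <- function(vectors) {
  nb <- nrow(vectors)
  if (nb < 2) return(0)
  best <- Inf
  for (mask in 0:(2^(nb - 1) - 1)) {
    flips <- c(FALSE, bitwAnd(mask, 2^(seq_len(nb - 1) - 1)) > 0)
    v <- vectors
    v[flips, ] <- 1L - v[flips, ]
    tot <- sum(vapply(seq_len(nb - 1), function(k)
      hamming(v[k, ], v[k + 1, ]), 0))
    best <- min(best, tot)
  }
  best
}

# Random scaffolding instance with the statistical structure of the
# simulated study: a hidden true order of contigs whose end vectors evolve
# by crossover flips - common inside the megabase-scale contigs
# (internal_mean per colony) and rare across the short repeat-array gaps
# between them (junction_mean) - then each contig gets a random global
# phase complement and a random end swap (orientation) and names are
# shuffled.
random_contig_instance <- function(n_contigs, n_drones = 10,
                                   n_colonies = 2, internal_mean = 2.5,
                                   junction_mean = 0.15) {
  tigs <- sprintf("t%02d", sample.int(n_contigs))
  ends <- lapply(tigs, function(x)
    list(L = list(), R = list(), orientable = TRUE))
  names(ends) <- tigs
  # the physical orientation (end swap) is a property of the contig; the
  # phase complement is arbitrary per contig AND per colony
  swap <- sample(c(TRUE, FALSE), n_contigs, replace = TRUE)
  for (cn in paste0("colony", seq_len(n_colonies))) {
    cur <- sample(0:1, n_drones, replace = TRUE)
    for (k in seq_len(n_contigs)) {
      left <- cur
      n_int <- stats::rpois(1, internal_mean)
      if (n_int > 0) {
        who <- sample(n_drones, min(n_int, n_drones))
        cur[who] <- 1L - cur[who]
      }
      right <- cur
      comp <- sample(c(TRUE, FALSE), 1)
      if (comp) { left <- 1L - left; right <- 1L - right }
      ends[[tigs[k]]]$L[[cn]] <- if (swap[k]) right else left
      ends[[tigs[k]]]$R[[cn]] <- if (swap[k]) left else right
      n_j <- stats::rpois(1, junction_mean)
      if (n_j > 0) {
        who <- sample(n_drones, min(n_j, n_drones))
        cur[who] <- 1L - cur[who]
      }
    }
  }
  list(ends = ends, true_order = tigs, swapped = swap)
}

# Total junction cost of a greedy layout (sum over accepted joins).
greedy_total_cost <- function(ends) {
  layout <- order_and_orient(
    ends, data.frame(contig = names(ends), chrom = "chr1"))
  if (is.null(layout$joins)) 0 else sum(layout$joins$cost)
}

# Quadratic brute-force interval overlap oracle (half-open).
overlap_oracle <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1)
      out[[length(out) + 1L]] <- data.frame(query = i, subject = j)
  }
  if (!length(out)) return(data.frame(query = integer(),
                                      subject = integer()))
  do.call(rbind, out)
}

# A small three-colony genotype fixture builder for the QC rules.
make_colony <- function(colony, sites, queen, drones_gt,
                        replicate_of = character()) {
  gt <- cbind(queen = queen, drones_gt)
  list(colony = colony, vcf = vcf_sites(sites, gt),
       drones = setdiff(colnames(drones_gt), names(replicate_of)),
       replicate_of = replicate_of)
}
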