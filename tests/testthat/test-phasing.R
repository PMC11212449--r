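gvm <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

test_that("bins are maximal runs of phase-equivalent genotype vectors", {
  # AAABB pattern across 4 drones: two bins of 3 and 2 SNPs
  gt <- gvm(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 0, 1, 1),
            c(0, 1, 1, 0), c(0, 1, 1, 0))
  b <- build_bins(c(100, 200, 300, 400, 500), gt, "tigZ")
  expect_equal(b$bins$n_snps, c(3L, 2L))
  expect_equal(b$bins$start, c(100, 400))
  expect_equal(b$bins$end, c(300, 500))
  # a complemented vector continues the same inheritance segment
  gt2 <- gvm(c(0, 0, 1, 1), c(1, 1, 0, 0), c(0, 0, 1, 1))
  b2 <- build_bins(c(1, 2, 3), gt2)
  expect_equal(nrow(b2$bins), 1)
  expect_equal(b2$bins$n_snps, 3L)
  # single constant vector spans first to last SNP
  gt3 <- gvm(c(0, 1), c(0, 1), c(0, 1))
  b3 <- build_bins(c(10, 50, 90), gt3)
  expect_equal(nrow(b3$bins), 1)
  expect_equal(c(b3$bins$start, b3$bins$end), c(10, 90))
  # a missing entry sandwiched between identical vectors is absorbed
  gt4 <- gvm(c(0, 0, 1), c(NA, 0, 1), c(0, 0, 1))
  b4 <- build_bins(c(1, 2, 3), gt4)
  expect_equal(nrow(b4$bins), 1)
  expect_equal(b4$vectors[1, ], c(0, 0, 1))
  # empty input
  b5 <- build_bins(numeric(), matrix(NA_integer_, 0, 3))
  expect_equal(nrow(b5$bins), 0)
})

test_that("phasing picks per-junction complements that minimise recombination", {
  b <- list(bins = data.frame(contig = "t", start = c(0, 10),
                              end = c(5, 15), n_snps = 1L),
            vectors = gvm(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  pc <- phase_contig(b)
  expect_equal(pc$junctions, 0)
  expect_true(pc$flipped[2])
  b2 <- list(bins = data.frame(contig = "t", start = c(0, 10, 20),
                               end = c(5, 15, 25), n_snps = 1L),
             vectors = gvm(c(0, 0, 0, 0), c(0, 0, 1, 1), c(1, 1, 0, 0)))
  pc2 <- phase_contig(b2)
  expect_equal(pc2$junctions, c(2, 0))
  expect_equal(pc2$vectors[3, ], c(0, 0, 1, 1))
})

test_that("greedy phasing attains the exhaustive minimum", {
  set.seed(77)
  for (rep in 1:60) {
    inst <- random_bin_instance(sample(2:10, 1), 8)
    pc <- phase_contig(inst)
    expect_equal(total_events(pc), exhaustive_phase_min(inst$vectors))
  }
})

test_that("complementing all input vectors leaves junction counts unchanged", {
  set.seed(78)
  for (rep in 1:20) {
    inst <- random_bin_instance(sample(2:8, 1), 10)
    inst2 <- inst
    inst2$vectors <- 1L - inst2$vectors
    expect_equal(phase_contig(inst)$junctions,
                 phase_contig(inst2)$junctions)
  }
})

test_that("conversion bins are flagged by the two rules and merged", {
  # short bin between identical flanks: rule (i), flanks merged
  mkpc <- function(vectors, starts, ends) {
    phase_contig(list(
      bins = data.frame(contig = "t", start = starts, end = ends,
                        n_snps = 1L),
      vectors = vectors))
  }
  pc <- mkpc(gvm(c(0, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 0)),
             c(0, 5000, 7000), c(4000, 6000, 12000))
  before <- total_events(pc)
  res <- detect_nco_conversions(pc)
  expect_equal(res$flagged$rule, "identical_flanks")
  expect_equal(nrow(res$pc$bins), 1)
  expect_equal(c(res$pc$bins$start, res$pc$bins$end), c(0, 12000))
  expect_equal(before - total_events(res$pc), 2)  # 2 x H(A,B)
  # rule (ii): events through B exceed the A-to-C distance
  pc2 <- mkpc(gvm(c(0, 0, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 1)),
              c(0, 5000, 6600), c(4000, 6500, 12000))
  res2 <- detect_nco_conversions(pc2)
  expect_equal(res2$flagged$rule, "excess_events")
  expect_equal(nrow(res2$pc$bins), 2)     # B removed, A and C unmerged
  # a 5 kb bin between identical flanks is left alone
  pc3 <- mkpc(gvm(c(0, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 0)),
              c(0, 5000, 11000), c(4000, 10000, 15000))
  res3 <- detect_nco_conversions(pc3)
  expect_equal(nrow(res3$flagged), 0)
  expect_equal(nrow(res3$pc$bins), 3)
  # first and last bins are never flagged
  pc4 <- mkpc(gvm(c(0, 1, 0, 0), c(0, 0, 0, 0), c(0, 1, 0, 0)),
              c(0, 100, 200), c(50, 150, 250))
  expect_equal(nrow(detect_nco_conversions(pc4)$flagged), 1)
  # total recombination never increases through merging
  set.seed(79)
  for (rep in 1:20) {
    inst <- random_bin_instance(sample(3:9, 1), 6)
    pc <- phase_contig(inst)
    expect_lte(total_events(detect_nco_conversions(pc)$pc),
               total_events(pc))
  }
})

test_that("contig end vectors expose orientability", {
  one <- phase_contig(list(
    bins = data.frame(contig = "t", start = 0, end = 10, n_snps = 2L),
    vectors = gvm(c(0, 1, 0))))
  ev <- contig_end_vectors(one)
  expect_false(ev$orientable)
  expect_identical(ev$left, ev$right)
  two <- phase_contig(list(
    bins = data.frame(contig = "t", start = c(0, 20), end = c(10, 30),
                      n_snps = 1L),
    vectors = gvm(c(0, 1, 0), c(0, 1, 1))))
  ev2 <- contig_end_vectors(two)
  expect_true(ev2$orientable)
  expect_gte(hamming(ev2$left, ev2$right), 1)
})

test_that("orientable contigs are exactly those containing a true crossover", {
  cfg <- sim_config(seed = 31, genotyping_error_rate = 0, missing_rate = 0,
                    nco_rate = 0, chromosome_lengths = rep(2e6, 2),
                    breaks_per_chromosome = 3)
  sim <- simulate_colonies(cfg)
  genome <- simulate_genome(cfg)
  frag <- fragment_into_contigs(cfg, genome)
  res <- run_scaffold_pipeline(sim, frag)
  co <- sim$truth$crossovers
  lt <- frag$layout_truth
  for (k in seq_len(nrow(lt))) {
    tig <- lt$contig[k]
    if (!tig %in% names(res$ends)) next
    snps <- sim$sites[sim$sites$chrom == lt$chrom[k] &
                        sim$sites$start >= lt$chrom_start[k] &
                        sim$sites$start < lt$chrom_end[k], ]
    if (!nrow(snps)) next
    # a crossover is observable when SNPs flank it within the contig
    inside <- co$chrom == lt$chrom[k] & co$pos > min(snps$start) &
      co$pos < max(snps$start)
    expect_equal(res$ends[[tig]]$orientable, any(inside),
                 info = tig)
  }
})
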