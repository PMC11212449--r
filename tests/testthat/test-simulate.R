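test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, chromosome_lengths = c(c1 = 2e5),
                    snp_density = 5e-4)
  s1 <- simulate_colonies(cfg)
  s2 <- simulate_colonies(cfg)
  expect_identical(s1$colonies$colony1$vcf$gt, s2$colonies$colony1$vcf$gt)
  expect_identical(s1$truth$crossovers, s2$truth$crossovers)
  path1 <- withr::local_tempfile(); path2 <- withr::local_tempfile()
  write_vcf_genotypes(s1$colonies$colony2$vcf, path1)
  write_vcf_genotypes(s2$colonies$colony2$vcf, path2)
  expect_identical(readLines(path1), readLines(path2))
  d1 <- simulate_depth_profiles(cfg)
  d2 <- simulate_depth_profiles(cfg)
  expect_identical(d1$profiles, d2$profiles)
})

test_that("without recombination, conversion or error every drone is constant", {
  cfg <- sim_config(seed = 2, chromosome_lengths = rep(2e5, 2),
                    snp_density = 5e-4, recombination_rate = 0,
                    nco_rate = 0, genotyping_error_rate = 0,
                    missing_rate = 0)
  sim <- simulate_colonies(cfg)
  for (co in sim$colonies) {
    gt <- gt_codes(co$vcf$gt[, co$drones])
    hap0 <- sim$truth$queen_phase[[co$colony]]
    # remove per-site allele labelling: XOR with the queen phase gives the
    # inherited haplotype, which must be constant per chromosome
    hap <- (gt + hap0) %% 2
    for (ch in unique(sim$sites$chrom)) {
      idx <- sim$sites$chrom == ch
      expect_true(all(apply(hap[idx, , drop = FALSE], 2,
                            function(x) length(unique(x)) == 1)))
    }
  }
  expect_equal(nrow(sim$truth$crossovers), 0)
})

test_that("crossover counts are Poisson with mean set by the map length", {
  # 20 Mb at 23 cM/Mb: expected 4.6 crossovers per meiosis
  cfg <- sim_config(seed = 4, chromosome_lengths = c(big = 2e7),
                    snp_density = 1e-5, colonies = list(c(300, 0)),
                    nco_rate = 0)
  sim <- simulate_colonies(cfg)
  counts <- table(factor(sim$truth$crossovers$drone,
                         levels = sim$colonies$colony1$drones))
  m <- mean(counts)
  se <- sqrt(4.6 / 300)
  expect_lt(abs(m - 4.6), 3 * se)
  # goodness of fit against the known Poisson law
  brks <- c(-0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, Inf)
  obs <- table(cut(as.numeric(counts), brks))
  p <- diff(ppois(brks, 4.6))
  gof <- suppressWarnings(chisq.test(obs, p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("replicate drones share the meiosis and differ only by injected error", {
  cfg <- sim_config(seed = 6, chromosome_lengths = c(c1 = 3e5),
                    snp_density = 1e-3, missing_rate = 0,
                    genotyping_error_rate = 0.01)
  sim <- simulate_colonies(cfg)
  co <- sim$colonies$colony1
  expect_length(co$replicate_of, 3)
  for (r in names(co$replicate_of)) {
    orig <- co$vcf$gt[, co$replicate_of[[r]]]
    rep_ <- co$vcf$gt[, r]
    disagree <- mean(orig != rep_)
    # two independent 1% error streams disagree at about 2% of sites
    expect_lt(disagree, 0.05)
    expect_gt(disagree, 0.001)
  }
  # error-free replicates are identical
  cfg0 <- sim_config(seed = 6, chromosome_lengths = c(c1 = 3e5),
                     snp_density = 1e-3, missing_rate = 0,
                     genotyping_error_rate = 0)
  sim0 <- simulate_colonies(cfg0)
  co0 <- sim0$colonies$colony1
  for (r in names(co0$replicate_of))
    expect_identical(co0$vcf$gt[, r], co0$vcf$gt[, co0$replicate_of[[r]]])
})

test_that("contig fragmentation breaks chromosomes at long arrays only", {
  cfg <- sim_config(seed = 3)
  genome <- simulate_genome(cfg)
  frag <- fragment_into_contigs(cfg, genome)
  lt <- frag$layout_truth
  n_break <- sum(genome$arrays$end - genome$arrays$start > cfg$read_length)
  expect_equal(nrow(lt), n_break + length(cfg$chromosome_lengths))
  expect_equal(unname(table(lt$chrom)[names(cfg$chromosome_lengths)]),
               rep(cfg$breaks_per_chromosome + 1L, 4), ignore_attr = TRUE)
  # no arrays -> one contig per chromosome
  cfg2 <- sim_config(seed = 3, read_length = 1e9)
  frag2 <- fragment_into_contigs(cfg2, genome)
  expect_equal(nrow(frag2$layout_truth), length(cfg$chromosome_lengths))
  # flip bookkeeping: flipped contigs swap their terminal-array annotation
  flipped <- lt[lt$flipped & lt$order == 1, ]
  if (nrow(flipped))
    expect_true(all(is.na(flipped$right_period)))
  unflipped <- lt[!lt$flipped & lt$order == 1, ]
  if (nrow(unflipped))
    expect_true(all(is.na(unflipped$left_period)))
})

test_that("depth profiles are Poisson around the configured mean", {
  cfg <- sim_config(seed = 8, depth_lambda = 30)
  dp <- simulate_depth_profiles(cfg)
  tr <- dp$truth
  present <- tr[tr$present & tr$indel == "numtA", ]
  expect_gt(nrow(present), 10)
  v <- dp$panel[dp$panel$id == "numtA", ]
  for (s in present$sample[1:5]) {
    prof <- dp$profiles$numtA[[s]]
    inside <- prof$pos >= v$start & prof$pos < v$end
    m <- mean(prof$depth[inside])
    se <- sqrt(30 / sum(inside))
    expect_lt(abs(m - 30), 3 * se)
  }
  # absent with zero background mis-mapping gives exactly zero depth
  cfg0 <- sim_config(seed = 8, background_mismap = 0)
  dp0 <- simulate_depth_profiles(cfg0)
  tr0 <- dp0$truth
  absent <- tr0[!tr0$present & tr0$indel == "numtA", ]
  prof <- dp0$profiles$numtA[[absent$sample[1]]]
  inside <- prof$pos >= v$start & prof$pos < v$end
  expect_true(all(prof$depth[inside] == 0))
  expect_error(simulate_depth_profiles(cfg, lambda = 0), "> 0")
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(chromosome_lengths = c(0, 1e6)), "> 0")
  cfg <- sim_config(seed = 1, chromosome_lengths = c(tiny = 50),
                    snp_density = 1e-6)
  expect_error(simulate_colonies(cfg), "0 sites")
})
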