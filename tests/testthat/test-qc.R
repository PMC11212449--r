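sites1 <- function(n, ref = "A", alt = "T") {
  data.frame(chrom = "chr1", start = seq_len(n) * 100, ref = ref,
             alt = alt, qual = 1000, fs = 1, mq = 59, sor = 1)
}

test_that("hard site filters use strict thresholds and drop missing calls", {
  s <- sites1(5)
  s$fs <- c(61, 60, 1, 1, 1)
  s$mq <- c(60, 50, 49, 55, 55)
  s$sor <- c(1, 3, 1, 3.01, 1)
  gt <- matrix("0", 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  gt[5, 2] <- "."
  v <- vcf_sites(s, gt)
  out <- filter_site_quality(v)
  # FS=61 out; FS=60/MQ=50/SOR=3 all pass; MQ=49 out; SOR=3.01 out;
  # missing genotype out
  expect_equal(out$sites$start, s$start[2])
  expect_equal(attr(out, "qc")[["removed_annotation"]], 3)
  expect_equal(attr(out, "qc")[["removed_missing"]], 1)
  # absent annotations pass unless strict
  s2 <- sites1(2); s2$fs <- NA
  v2 <- vcf_sites(s2, matrix("0", 2, 1, dimnames = list(NULL, "a")))
  expect_equal(nrow(filter_site_quality(v2)$sites), 2)
  expect_error(filter_site_quality(v2, strict = TRUE), "lack")
})

test_that("biological discard rules match an independent rule-by-rule oracle", {
  n <- 12
  mk_gt <- function(...) {
    g <- matrix("0", n, 4, dimnames = list(NULL, c("d1", "d2", "d3", "d4")))
    g[, c(2, 4)] <- "1"   # polymorphic default
    args <- list(...)
    for (a in args) g[a$i, a$j] <- a$v
    g
  }
  s <- sites1(n)
  s$alt[7] <- "T,G"
  queen1 <- rep("0/1", n)
  queen1[3] <- "0/0"                               # rule ii at site 3
  g1 <- mk_gt(list(i = 2, j = 1:4, v = c("0", "0", "0", "0")),  # rule i
              list(i = 4, j = 2, v = "0/1"),                    # rule iii
              list(i = 7, j = 1, v = "2"))                      # rule v
  g1 <- cbind(g1, d1r = g1[, "d1"])
  g1[5, "d1r"] <- "1"; g1[5, "d1"] <- "0"          # replicate discordance
  # rule iv at site 6: colony 1 sees {A,T}; other queens carry only A/C
  colony1 <- make_colony("colony1", s, queen1, g1,
                         replicate_of = c(d1r = "d1"))
  s2 <- sites1(n); s2$alt[6] <- "C"
  queen2 <- rep("0/1", n); queen2[6] <- "0/0"
  # colony 3 queen carries A/G at site 7 so that the three-colony allele
  # union covers colony 1's G and only rule (v) fires there
  s3 <- sites1(n); s3$alt[6] <- "C"; s3$alt[7] <- "G"
  colony2 <- make_colony("colony2", s2, queen2, mk_gt())
  colony3 <- make_colony("colony3", s3, queen2, mk_gt())
  res <- filter_biological(list(colony1, colony2, colony3))
  fail1 <- res$colonies$colony1$fail_rule
  expect_equal(fail1[2], "non_polymorphic")
  expect_equal(fail1[3], "queen_homozygous")
  expect_equal(fail1[4], "drone_heterozygous")
  expect_equal(fail1[5], "replicate_discordant")
  expect_equal(fail1[6], "cross_colony_inconsistent")
  expect_equal(fail1[7], "queen_drone_allele_mismatch")
  expect_true(all(is.na(fail1[c(1, 8:12)])))
  # independent brute-force application of each rule, first failure wins
  oracle <- local({
    codes_to_bases <- function(codes, ref, alt)
      c(ref, strsplit(alt, ",")[[1]])[as.integer(codes) + 1]
    split_gt <- function(g) setdiff(strsplit(g, "/")[[1]], ".")
    vapply(seq_len(n), function(i) {
      d <- lapply(g1[i, c("d1", "d2", "d3", "d4")], split_gt)
      q <- split_gt(queen1[i])
      if (length(unique(unlist(d))) <= 1) return("non_polymorphic")
      if (length(unique(q)) < 2) return("queen_homozygous")
      if (any(vapply(d, function(a) length(unique(a)) > 1, TRUE)))
        return("drone_heterozygous")
      if (g1[i, "d1"] != g1[i, "d1r"]) return("replicate_discordant")
      mine <- unique(codes_to_bases(unique(c(q, unlist(d))),
                                    s$ref[i], s$alt[i]))
      oth <- unique(c(
        codes_to_bases(unique(split_gt(queen2[i])), s2$ref[i], s2$alt[i]),
        codes_to_bases(unique(split_gt(queen2[i])), s3$ref[i], s3$alt[i])))
      if (!length(intersect(mine, oth)) || length(setdiff(mine, oth)))
        return("cross_colony_inconsistent")
      db <- codes_to_bases(unique(unlist(d)), s$ref[i], s$alt[i])
      qb <- codes_to_bases(q, s$ref[i], s$alt[i])
      if (length(setdiff(db, qb))) return("queen_drone_allele_mismatch")
      NA_character_
    }, "")
  })
  expect_identical(fail1, oracle)
  # report partitions the input
  rep_ <- res$report
  expect_equal(sum(rep_$counts) + rep_$n_retained, rep_$n_input)
  expect_equal(sum(rep_$fractions) + rep_$retained_fraction, 1)
})

test_that("biological filtering is idempotent and clean on error-free data", {
  cfg <- sim_config(seed = 21, chromosome_lengths = c(c1 = 3e5),
                    snp_density = 1e-3, genotyping_error_rate = 0,
                    missing_rate = 0)
  sim <- simulate_colonies(cfg)
  res1 <- filter_biological(sim$colonies)
  expect_equal(sum(res1$report$counts[c("drone_heterozygous",
                                        "cross_colony_inconsistent",
                                        "queen_drone_allele_mismatch")]), 0)
  res2 <- filter_biological(res1$colonies)
  expect_equal(res2$report$n_retained, res1$report$n_retained)
  expect_identical(res2$colonies$colony1$vcf$gt,
                   res1$colonies$colony1$vcf$gt)
  # single colony: rule (iv) skipped with a warning
  expect_warning(filter_biological(sim$colonies[1]), "single colony")
})

test_that("polishing filter keeps confident non-reference variants only", {
  calls <- data.frame(
    qual = c(19, 30, 30, 25, 20, 30),
    gt = c("1/1", "0/1", "0/1", "1/1", "1/1", "0/1"),
    ad_ref = c(0, 0, 2, 5, 0, NA))
  expect_warning(out <- polishing_variant_filter(calls), "allele depths")
  # QUAL 19 rejected; 0/1 with ref reads rejected; het without AD skipped
  expect_equal(sort(rownames(out)), sort(c("2", "4", "5")))
})
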