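test_that("junction cost minimises over the two relative phases per colony", {
  eA <- list(colony1 = c(0, 0, 1, 1, 0), colony2 = c(1, 1, 0, 0))
  eB_same <- list(colony1 = c(0, 0, 1, 1, 0), colony2 = c(1, 1, 0, 0))
  expect_equal(junction_cost(eA, eB_same)$cost, 0)
  # complement symmetry: 00110 vs 11001 costs 0 via the flip
  jc <- junction_cost(list(c1 = c(0, 0, 1, 1, 0)),
                      list(c1 = c(1, 1, 0, 0, 1)))
  expect_equal(jc$cost, 0)
  expect_true(jc$rel_flip)
  # no shared colony
  expect_null(junction_cost(list(c1 = c(0, 1)), list(c2 = c(0, 1))))
  # random vectors: equals brute-force minimum over both orientations
  set.seed(91)
  for (rep in 1:50) {
    a <- sample(0:1, 8, replace = TRUE); b <- sample(0:1, 8, replace = TRUE)
    jc <- junction_cost(list(x = a), list(x = b))
    expect_equal(jc$cost, min(sum(a != b), sum(a != (1 - b))))
  }
  # cost is symmetric in its end pair
  set.seed(92)
  for (rep in 1:20) {
    a <- list(c1 = sample(0:1, 6, TRUE), c2 = sample(0:1, 5, TRUE))
    b <- list(c1 = sample(0:1, 6, TRUE), c2 = sample(0:1, 5, TRUE))
    expect_equal(junction_cost(a, b)$cost, junction_cost(b, a)$cost)
  }
})

test_that("two truth-adjacent contigs join in truth order at zero cost", {
  set.seed(93)
  inst <- random_contig_instance(2, n_drones = 12, junction_mean = 0)
  layout <- order_and_orient(
    inst$ends, data.frame(contig = names(inst$ends), chrom = "chr1"))
  pl <- layout$placement
  expect_equal(sort(pl$contig[order(pl$order)]), sort(inst$true_order))
  expect_equal(layout$joins$cost, 0)
})

test_that("greedy chaining equals the exhaustive minimum on small instances", {
  set.seed(94)
  for (rep in 1:40) {
    inst <- random_contig_instance(sample(3:5, 1), n_drones = 14,
                                   n_colonies = sample(2:3, 1))
    greedy <- greedy_total_cost(inst$ends)
    exact <- exact_order(inst$ends, sort(names(inst$ends)))$cost
    expect_equal(greedy, exact)
  }
})

test_that("total junction cost is invariant under reversing a chromosome", {
  set.seed(95)
  inst <- random_contig_instance(5, n_drones = 10)
  ends_rev <- lapply(inst$ends, function(e) list(L = e$R, R = e$L,
                                                 orientable = e$orientable))
  expect_equal(greedy_total_cost(inst$ends), greedy_total_cost(ends_rev))
})

test_that("placement status reflects the available evidence", {
  run <- default_run()
  st <- run$res$status
  # contigs withheld from the a-priori table are placed by crossover data
  # alone, hence unlocalised; assigned contigs are placed
  expect_true(all(st$status[st$contig %in% run$frag$withheld] ==
                    "unlocalised"))
  expect_true(all(st$status[!st$contig %in% run$frag$withheld] ==
                    "placed"))
  expect_true(all(table(st$contig) == 1))
  # withholding assignments pushes genotype-only contigs to unlocalised
  frag2 <- run$frag
  withheld <- frag2$layout_truth$contig[c(3, 9)]
  frag2$assignment <- frag2$assignment[
    !frag2$assignment$contig %in% withheld, ]
  res2 <- run_scaffold_pipeline(run$sim, frag2)
  st2 <- res2$status
  got <- st2[st2$contig %in% withheld, ]
  expect_true(all(got$status == "unlocalised"))
  expect_true(all(is.na(got$order)))
  truth_chrom <- run$frag$layout_truth$chrom[
    match(got$contig, run$frag$layout_truth$contig)]
  expect_equal(got$chrom, truth_chrom)
  # assignment without genotype data is unlocalised; neither is unplaced
  ends <- run$res$ends
  fake <- c(ends, list(tignope = list(L = list(), R = list(),
                                      orientable = FALSE)))
  lay <- order_and_orient(fake, run$frag$assignment)
  inf <- as.list(stats::setNames(
    c(rep(TRUE, length(ends)), FALSE), names(fake)))
  st3 <- classify_placement(lay, inf)
  expect_equal(st3$status[st3$contig == "tignope"], "unplaced")
  asg2 <- rbind(run$frag$assignment,
                data.frame(contig = "tignope", chrom = "chr1"))
  lay2 <- order_and_orient(fake, asg2)
  st4 <- classify_placement(lay2, inf)
  expect_equal(st4$status[st4$contig == "tignope"], "unlocalised")
  expect_equal(st4$chrom[st4$contig == "tignope"], "chr1")
})

test_that("boundary repeat arrays orient contigs the map cannot", {
  arr <- function(period, consensus) list(period = period,
                                          consensus = consensus)
  set.seed(96)
  m258 <- paste(sample(c("A", "C", "G", "T"), 258, TRUE), collapse = "")
  m1296 <- paste(sample(c("A", "C", "G", "T"), 1296, TRUE), collapse = "")
  m371 <- paste(sample(c("A", "C", "G", "T"), 371, TRUE), collapse = "")
  # distinct periods at the two ends give a unique orientation
  expect_equal(orient_by_boundary_repeats(
    list(left = arr(258, m258), right = arr(1296, m1296)),
    list(left = arr(258, m258), right = arr(1296, m1296))), "+")
  expect_equal(orient_by_boundary_repeats(
    list(left = arr(1296, m1296), right = arr(258, m258)),
    list(left = arr(258, m258), right = arr(1296, m1296))), "-")
  # same family at both ends is ambiguous
  expect_equal(orient_by_boundary_repeats(
    list(left = arr(371, m371), right = arr(371, m371)),
    list(left = arr(371, m371), right = arr(371, m371))), "unknown")
  # no terminal arrays
  expect_equal(orient_by_boundary_repeats(
    list(left = NULL, right = NULL),
    list(left = arr(258, m258), right = NULL)), "unknown")
  # a rotated monomer still matches its source array
  rot <- paste0(substr(m258, 101, 258), substr(m258, 1, 100))
  expect_equal(orient_by_boundary_repeats(
    list(left = arr(258, rot), right = arr(1296, m1296)),
    list(left = arr(258, m258), right = arr(1296, m1296))), "+")
})

test_that("planted boundary arrays recover the truth orientation of contigs", {
  run <- default_run()
  lt <- run$frag$layout_truth
  # treat each interior contig as unoriented and re-derive its orientation
  # from the terminal arrays it shares with its neighbours
  arr_at <- function(g, k, side)
    list(period = g[[paste0(side, "_period")]][k],
         consensus = g[[paste0(side, "_consensus")]][k])
  for (ch in unique(lt$chrom)) {
    g <- lt[lt$chrom == ch, ]
    g <- g[order(g$order), ]
    for (k in 2:(nrow(g) - 1)) {
      contig_arr <- list(left = arr_at(g, k, "left"),
                         right = arr_at(g, k, "right"))
      # neighbour end facing this contig, in each neighbour's own
      # orientation as laid out on the chromosome
      nb <- list(
        left = arr_at(g, k - 1, if (g$flipped[k - 1]) "left" else "right"),
        right = arr_at(g, k + 1, if (g$flipped[k + 1]) "right" else "left"))
      expect_equal(orient_by_boundary_repeats(contig_arr, nb),
                   if (g$flipped[k]) "-" else "+",
                   info = g$contig[k])
    }
  }
})
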