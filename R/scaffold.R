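#' Recombination cost of joining two contig ends
#'
#' For every colony in which both ends carry a phased end vector, the cost
#' is the smaller Hamming distance between the first end's vector and the
#' second end's vector or its complement (phase is only defined up to
#' complementation within a contig). Costs are summed over shared
#' colonies; the minimising relative phase per colony is recorded and
#' reconciled by majority vote weighted by that colony's cost margin.
#'
#' @param endA,endB named lists, one 0/1/NA vector per colony.
#' @return list with `cost` (summed), `n_colonies`, `n_informative`
#'   (observed drone entries compared), `per_colony` (data.frame) and
#'   `rel_flip` (majority relative phase); `NULL` when the ends share no
#'   colony.
#' @export
junction_cost <- function(endA, endB) {
  shared <- intersect(names(endA), names(endB))
  shared <- shared[vapply(shared, function(cn)
    !is.null(endA[[cn]]) && !is.null(endB[[cn]]), TRUE)]
  if (!length(shared)) return(NULL)
  per <- do.call(rbind, lapply(shared, function(cn) {
    a <- endA[[cn]]; b <- endB[[cn]]
    d0 <- hamming(a, b); d1 <- hamming(a, 1L - b)
    data.frame(colony = cn, d_same = d0, d_flip = d1,
               flip = d1 < d0, margin = abs(d0 - d1),
               n_obs = sum(!is.na(a) & !is.na(b)))
  }))
  votes <- tapply(per$margin, per$flip, sum)
  rel_flip <- isTRUE(as.logical(names(votes)[which.max(votes)]))
  list(cost = sum(pmin(per$d_same, per$d_flip)),
       n_colonies = nrow(per), n_informative = sum(per$n_obs),
       per_colony = per, rel_flip = rel_flip)
}

# all candidate end pairings among a set of contigs;
# ends[[contig]] = list(L = <per-colony vectors>, R = ..., orientable)
.candidate_joins <- function(ends, contigs) {
  out <- list()
  n <- length(contigs)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (ea in c("L", "R")) for (eb in c("L", "R")) {
      jc <- junction_cost(ends[[contigs[i]]][[ea]],
                          ends[[contigs[j]]][[eb]])
      if (is.null(jc)) next
      out[[length(out) + 1L]] <- list(
        a = contigs[i], ea = ea, b = contigs[j], eb = eb,
        cost = jc$cost, n_informative = jc$n_informative)
    }
  }
  out
}

# greedy Kruskal-style path building over candidate joins; returns the
# accepted joins (each a list a, ea, b, eb, cost)
.greedy_chain <- function(cands, contigs) {
  if (!length(cands)) return(list())
  ord <- order(vapply(cands, `[[`, 0, "cost"),
               -vapply(cands, `[[`, 0, "n_informative"),
               vapply(cands, `[[`, "", "a"),
               vapply(cands, `[[`, "", "b"),
               vapply(cands, `[[`, "", "ea"),
               vapply(cands, `[[`, "", "eb"))
  used <- character()
  comp <- stats::setNames(contigs, contigs)   # union-find over contig names
  find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
  joins <- list()
  for (k in ord) {
    cd <- cands[[k]]
    keyA <- paste0(cd$a, ".", cd$ea); keyB <- paste0(cd$b, ".", cd$eb)
    if (keyA %in% used || keyB %in% used) next
    ra <- find(cd$a); rb <- find(cd$b)
    if (ra == rb) next                       # would close a cycle
    comp[[ra]] <- rb
    used <- c(used, keyA, keyB)
    joins[[length(joins) + 1L]] <- cd
    if (length(joins) == length(contigs) - 1) break
  }
  joins
}

# walk the joined path; returns data.frame(order, contig, orientation)
.walk_path <- function(joins, contigs, orientable) {
  if (!length(contigs)) return(NULL)
  adj <- list()
  for (jn in joins) {
    keyA <- paste0(jn$a, ".", jn$ea); keyB <- paste0(jn$b, ".", jn$eb)
    adj[[keyA]] <- keyB
    adj[[keyB]] <- keyA
  }
  used_ends <- names(adj)
  deg_tab <- table(c(vapply(joins, `[[`, "", "a"),
                     vapply(joins, `[[`, "", "b")))
  deg <- ifelse(contigs %in% names(deg_tab),
                as.integer(deg_tab[contigs]), 0L)
  free_start <- sort(contigs[deg < 2])
  # deterministic start: lexicographically smallest path-endpoint contig
  visited <- character()
  rows <- list()
  remaining <- contigs
  while (length(remaining)) {
    start <- sort(intersect(free_start, remaining))[1]
    if (is.na(start)) start <- sort(remaining)[1]
    cur <- start
    # enter via the free end (the one not used in a join), prefer L
    enter <- if (!paste0(cur, ".L") %in% used_ends) "L" else "R"
    repeat {
      ori <- if (!orientable[[cur]]) NA_character_ else
        if (enter == "L") "+" else "-"
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cur, orientation = ori, stringsAsFactors = FALSE)
      remaining <- setdiff(remaining, cur)
      exit_end <- paste0(cur, ".", if (enter == "L") "R" else "L")
      nxt <- adj[[exit_end]]
      if (is.null(nxt)) break
      cur <- sub("\\.[LR]$", "", nxt)
      enter <- sub("^.*\\.", "", nxt)
      if (!cur %in% remaining) break
    }
  }
  df <- do.call(rbind, rows)
  df$order <- seq_len(nrow(df))
  df[, c("order", "contig", "orientation")]
}

#' Order and orient contigs into chromosomes by crossover minimisation
#'
#' Within each a-priori chromosome group, contig ends are joined greedily:
#' the free end pair with the smallest summed [junction_cost()] is joined
#' next, skipping joins that reuse an end or close a cycle, until a single
#' path remains; the path gives contig order and, for contigs with at
#' least one internal crossover, orientation. Contigs without an a-priori
#' assignment are first matched against every group and adopted when
#' their best end cost is at most `accept_threshold` per shared colony;
#' contigs failing that stay unplaced. Ties are broken by the larger
#' number of informative comparisons, then lexicographically.
#'
#' @param ends named list: `ends[[contig]]` is a list with `L` and `R`
#'   (per-colony phased end vectors) and `orientable` (logical).
#' @param assignment data.frame `contig`, `chrom`: the a-priori table.
#' @param accept_threshold maximum cost per shared colony for adopting an
#'   unassigned contig into a chromosome.
#' @return an object of class `scaffold_layout`: `placement` (data.frame
#'   `chrom`, `order`, `contig`, `orientation`, `assigned`, `adopted`)
#'   including unplaced contigs with NA chromosome, and `joins` (accepted
#'   junctions with costs).
#' @export
order_and_orient <- function(ends, assignment, accept_threshold = 1) {
  contigs <- names(ends)
  orientable <- lapply(ends, `[[`, "orientable")
  groups <- split(assignment$contig, assignment$chrom)
  groups <- lapply(groups, intersect, contigs)
  floating <- setdiff(contigs, unlist(groups))
  adopted <- character()
  for (fc in floating) {
    best <- Inf; best_ch <- NA_character_
    for (ch in names(groups)) {
      for (gc in groups[[ch]]) for (ea in c("L", "R")) for (eb in c("L", "R")) {
        jc <- junction_cost(ends[[fc]][[ea]], ends[[gc]][[eb]])
        if (is.null(jc)) next
        rel <- jc$cost / jc$n_colonies
        if (rel < best) { best <- rel; best_ch <- ch }
      }
    }
    if (is.finite(best) && best <= accept_threshold) {
      groups[[best_ch]] <- c(groups[[best_ch]], fc)
      adopted <- c(adopted, fc)
    }
  }
  placement <- list(); all_joins <- list()
  for (ch in names(groups)) {
    gctg <- sort(groups[[ch]])
    if (!length(gctg)) next
    cands <- .candidate_joins(ends, gctg)
    joins <- .greedy_chain(cands, gctg)
    path <- .walk_path(joins, gctg, orientable)
    path$chrom <- ch
    placement[[ch]] <- path
    for (jn in joins) all_joins[[length(all_joins) + 1L]] <-
      data.frame(chrom = ch, a = jn$a, ea = jn$ea, b = jn$b, eb = jn$eb,
                 cost = jn$cost, stringsAsFactors = FALSE)
  }
  pl <- do.call(rbind, placement)
  unplaced <- setdiff(contigs, pl$contig)
  if (length(unplaced))
    pl <- rbind(pl, data.frame(order = NA_integer_, contig = unplaced,
                               orientation = NA_character_,
                               chrom = NA_character_))
  pl$assigned <- pl$contig %in% assignment$contig
  pl$adopted <- pl$contig %in% adopted
  rownames(pl) <- NULL
  structure(list(placement = pl[, c("chrom", "order", "contig",
                                    "orientation", "assigned", "adopted")],
                 joins = if (length(all_joins)) do.call(rbind, all_joins)
                 else NULL),
            class = "scaffold_layout")
}

#' @export
print.scaffold_layout <- function(x, ...) {
  pl <- x$placement
  cat(sprintf("<scaffold_layout> %d contigs on %d chromosomes (%d unplaced)\n",
              sum(!is.na(pl$order)), length(unique(stats::na.omit(pl$chrom))),
              sum(is.na(pl$chrom))))
  invisible(x)
}

#' Exhaustive minimum-recombination contig order (validation solver)
#'
#' Enumerates every signed order of a small contig set (all permutations
#' times end orientations, global flip collapsed) and returns the minimum
#' total junction cost. Exponential: intended for at most 8 contigs, as an
#' independent check of the greedy chaining.
#'
#' @param ends as in [order_and_orient()].
#' @param contigs contig names to order.
#' @return list `cost` (minimal total) and `order` (signed layout as
#'   data.frame `contig`, `enter_end`).
#' @export
exact_order <- function(ends, contigs) {
  n <- length(contigs)
  stopifnot(n >= 1, n <= 8)
  if (n == 1) return(list(cost = 0, order = data.frame(
    contig = contigs, enter_end = "L")))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  # precompute all pairwise end costs once (no shared colony -> Inf)
  cm <- array(Inf, c(n, 2, n, 2))
  side <- c(L = 1L, R = 2L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (ea in c("L", "R")) for (eb in c("L", "R")) {
      jc <- junction_cost(ends[[contigs[i]]][[ea]],
                          ends[[contigs[j]]][[eb]])
      if (!is.null(jc)) cm[i, side[[ea]], j, side[[eb]]] <- jc$cost
    }
  }
  idx <- stats::setNames(seq_len(n), contigs)
  best <- Inf; best_layout <- NULL
  for (p in perms(contigs)) {
    if (p[1] > p[n]) next   # global flip symmetry
    pi <- idx[p]
    for (mask in 0:(2^n - 1)) {
      enter <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, 2L, 1L)
      total <- 0
      for (k in seq_len(n - 1)) {
        total <- total + cm[pi[k], 3L - enter[k], pi[k + 1], enter[k + 1]]
        if (total >= best) break
      }
      if (total < best) {
        best <- total
        best_layout <- data.frame(contig = p,
                                  enter_end = c("L", "R")[enter])
      }
    }
  }
  list(cost = best, order = best_layout)
}

#' Classify contig placement status
#'
#' `placed`: ordered on a chromosome by crossover data and carrying an
#' a-priori assignment. `unlocalised`: chromosome known from exactly one
#' evidence source - an a-priori assignment without usable genotype data,
#' or adoption by crossover data alone; such contigs keep their chromosome
#' but lose their order index. `unplaced`: neither source.
#'
#' @param layout a `scaffold_layout`.
#' @param informative named logical: does the contig have phased genotype
#'   data.
#' @return data.frame `contig`, `chrom`, `order`, `orientation`, `status`.
#' @export
classify_placement <- function(layout, informative) {
  pl <- layout$placement
  status <- character(nrow(pl))
  for (k in seq_len(nrow(pl))) {
    has_geno <- isTRUE(informative[[pl$contig[k]]])
    if (!is.na(pl$order[k]) && pl$assigned[k] && has_geno)
      status[k] <- "placed"
    else if (pl$assigned[k] || (pl$adopted[k] && has_geno))
      status[k] <- "unlocalised"
    else status[k] <- "unplaced"
  }
  out <- pl[, c("contig", "chrom", "order", "orientation")]
  out$status <- status
  out$order[status != "placed"] <- NA_integer_
  out$chrom[status == "unplaced"] <- NA_character_
  out
}

#' Orient a contig from its boundary tandem-repeat arrays
#'
#' Contigs end in long tandem arrays that broke the assembly; the array at
#' a contig end should match the array facing it at the neighbouring
#' contig's end. An orientation is accepted when every available facing
#' pair matches by exact period size and monomer identity at or above
#' `identity_threshold` (rotation- and strand-aware), and the opposite
#' orientation does not also match.
#'
#' @param contig_arrays list `left`, `right`: each NULL or a list/row with
#'   `period` and `consensus` for the contig's terminal arrays (in contig
#'   orientation).
#' @param neighbour_arrays list `left`, `right`: the facing terminal
#'   arrays of the previous and next contig in the layout.
#' @param identity_threshold minimum monomer identity (0-1).
#' @return `"+"`, `"-"` or `"unknown"`.
#' @export
orient_by_boundary_repeats <- function(contig_arrays, neighbour_arrays,
                                       identity_threshold = 0.95) {
  m <- function(a, b) {
    if (is.null(a) || is.null(b) || is.na(a$period) || is.na(b$period))
      return(NA)
    a$period == b$period &&
      monomer_identity(a$consensus, b$consensus) >= identity_threshold
  }
  pair_ok <- function(x, y) {
    res <- c(m(x$left, y$left), m(x$right, y$right))
    res <- res[!is.na(res)]
    if (!length(res)) return(NA)
    all(res)
  }
  fwd <- pair_ok(contig_arrays, neighbour_arrays)
  swapped <- list(left = contig_arrays$right, right = contig_arrays$left)
  rev <- pair_ok(swapped, neighbour_arrays)
  if (isTRUE(fwd) && !isTRUE(rev)) return("+")
  if (isTRUE(rev) && !isTRUE(fwd)) return("-")
  "unknown"
}
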