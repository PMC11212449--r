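#' Site-quality hard filter
#'
#' Removes sites failing the hard annotation filters `FS > 60`, `MQ < 50`
#' or `SOR > 3` (strict inequalities, as used for GATK-style SNP call
#' sets), then removes any site with one or more missing genotypes.
#' Absent annotations pass the annotation checks; with `strict = TRUE`
#' they raise an error instead.
#'
#' @param x a [vcf_sites] object.
#' @param strict error on missing FS/MQ/SOR annotations.
#' @return the retained `vcf_sites`, with an attribute `qc` giving counts
#'   removed by the annotation filter and by missingness.
#' @export
filter_site_quality <- function(x, strict = FALSE) {
  stopifnot(inherits(x, "vcf_sites"))
  s <- x$sites
  unavail <- is.na(s$fs) | is.na(s$mq) | is.na(s$sor)
  if (strict && any(unavail))
    stop(sum(unavail), " sites lack FS/MQ/SOR annotations")
  fail_ann <- (!is.na(s$fs) & s$fs > 60) |
    (!is.na(s$mq) & s$mq < 50) |
    (!is.na(s$sor) & s$sor > 3)
  miss <- rowSums(x$gt == "." | x$gt == "./.") > 0
  keep <- !fail_ann & !miss
  out <- x[keep, ]
  attr(out, "qc") <- c(removed_annotation = sum(fail_ann),
                       removed_missing = sum(miss & !fail_ann),
                       retained = sum(keep))
  out
}

# split a genotype string into allele codes; "." -> character(0)
.alleles <- function(gt) {
  a <- strsplit(gt, "/", fixed = TRUE)
  lapply(a, function(v) v[v != "."])
}

# translate allele codes at one site to bases using ref/alt
.code_to_base <- function(codes, ref, alt) {
  lut <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
  lut[as.integer(codes) + 1L]
}

#' Biological SNP discard rules for drone colonies
#'
#' Applies, per colony and in order, the five biological discard rules for
#' queen/drone SNP sets: (i) non-polymorphic among the colony's drones,
#' (ii) homozygous in the queen, (iii) heterozygous in any drone,
#' (iv) inconsistent with the other colonies (the colony's observed
#' alleles are disjoint from, or extend beyond, the union of queen alleles
#' in the other colonies), and (v) a drone allele absent from the colony
#' queen's two alleles. Sites at which replicate drone pairs disagree are
#' discarded as a separate category, checked after the within-colony rules
#' and before the cross-colony rule. Each discarded site is attributed to
#' its first-failing rule, so the categories partition the discards.
#' Replicate columns are dropped from the retained output once concordance
#' has been checked.
#'
#' @param colonies list of colonies as in a [simulate_colonies()] result:
#'   each a list with `vcf` (a [vcf_sites] whose first column is `queen`),
#'   `drones` (primary drone sample names) and `replicate_of` (named map
#'   replicate sample -> drone sample). All colonies must share the site
#'   list.
#' @return list with `colonies` (per colony: the retained `vcf_sites`,
#'   queen + primary drones only, and the per-site first-failing rule for
#'   discarded sites) and `report` (a `qc_report`).
#' @export
filter_biological <- function(colonies) {
  stopifnot(length(colonies) >= 1)
  if (length(colonies) == 1)
    warning("single colony supplied: cross-colony rule (iv) skipped")
  rules <- c("non_polymorphic", "queen_homozygous", "drone_heterozygous",
             "replicate_discordant", "cross_colony_inconsistent",
             "queen_drone_allele_mismatch")
  # queen allele bases per colony, keyed by site, for rule (iv); colonies
  # may hold different site subsets after upstream filtering
  site_key <- function(v) paste(v$sites$chrom, v$sites$start)
  queen_bases <- lapply(colonies, function(co) {
    v <- co$vcf
    qa <- .alleles(v$gt[, "queen"])
    stats::setNames(lapply(seq_along(qa), function(i)
      unique(.code_to_base(qa[[i]], v$sites$ref[i], v$sites$alt[i]))),
      site_key(v))
  })
  # allele-set bitmasks (A=1, C=2, G=4, T=8, other=16) make the set
  # comparisons of rules (iv) and (v) vectorisable
  base_mask <- function(b) {
    m <- match(b, c("A", "C", "G", "T"))
    as.integer(ifelse(is.na(m), 16L, bitwShiftL(1L, m - 1L)))
  }
  queen_masks <- lapply(queen_bases, function(qb)
    vapply(qb, function(b) Reduce(bitwOr, base_mask(b), 0L), 0L))
  out <- vector("list", length(colonies))
  counts <- stats::setNames(numeric(length(rules)), rules)
  n_input <- 0; n_retained <- 0
  for (ci in seq_along(colonies)) {
    co <- colonies[[ci]]
    v <- co$vcf
    ns <- nrow(v$sites)
    n_input <- n_input + ns
    dr <- v$gt[, co$drones, drop = FALSE]
    keys <- site_key(v)
    qgt <- v$gt[, "queen"]
    # fast vectorised path for biallelic sites with haploid 0/1/. drones
    c0 <- dr == "0"; c1 <- dr == "1"
    simple_cell <- c0 | c1 | dr == "."
    complex_site <- rowSums(!simple_cell) > 0 |
      grepl(",", v$sites$alt, fixed = TRUE) |
      !qgt %in% c("0/0", "0/1", "1/0", "1/1", "0", "1")
    has0 <- rowSums(c0) > 0; has1 <- rowSums(c1) > 0
    rmask <- base_mask(v$sites$ref); amask <- base_mask(v$sites$alt)
    q_has0 <- grepl("0", qgt, fixed = TRUE)
    q_has1 <- grepl("1", qgt, fixed = TRUE)
    qmask <- bitwOr(ifelse(q_has0, rmask, 0L), ifelse(q_has1, amask, 0L))
    dmask <- bitwOr(ifelse(has0, rmask, 0L), ifelse(has1, amask, 0L))
    cmask <- bitwOr(qmask, dmask)
    r4 <- rep(FALSE, ns)
    if (length(co$replicate_of)) {
      rg <- v$gt[, names(co$replicate_of), drop = FALSE]
      og <- v$gt[, co$replicate_of, drop = FALSE]
      r4 <- rowSums(rg != "." & og != "." & rg != og) > 0
    }
    r5 <- rep(FALSE, ns)
    others <- integer(ns)
    if (length(colonies) > 1) {
      for (cj in seq_along(colonies)[-ci]) {
        mj <- queen_masks[[cj]]
        idx <- match(keys, names(mj))
        others <- bitwOr(others, ifelse(is.na(idx), 0L, mj[idx]))
      }
      r5 <- others > 0L & (bitwAnd(cmask, others) == 0L |
                             bitwAnd(cmask, others) != cmask)
    }
    fail <- rep(NA_character_, ns)
    # assign in reverse priority so earlier rules overwrite later ones
    fail[bitwAnd(dmask, qmask) != dmask] <- rules[6]
    fail[r5] <- rules[5]
    fail[r4] <- rules[4]
    fail[!(q_has0 & q_has1)] <- rules[2]
    fail[!(has0 & has1)] <- rules[1]
    # generic per-site path for heterozygous/multi-allelic/odd sites
    qa <- NULL
    for (i in which(complex_site)) {
      if (is.null(qa)) qa <- .alleles(qgt)
      fail[i] <- NA_character_
      d_all <- unlist(.alleles(dr[i, ]))
      if (length(unique(d_all)) <= 1) { fail[i] <- rules[1]; next }
      if (length(unique(qa[[i]])) < 2) { fail[i] <- rules[2]; next }
      het <- vapply(.alleles(dr[i, ]), function(a)
        length(unique(a)) > 1, TRUE)
      if (any(het)) { fail[i] <- rules[3]; next }
      if (r4[i]) { fail[i] <- rules[4]; next }
      colony_bases <- unique(.code_to_base(unique(c(qa[[i]], d_all)),
                                           v$sites$ref[i], v$sites$alt[i]))
      if (length(colonies) > 1) {
        other_bases <- unique(unlist(lapply(seq_along(colonies)[-ci],
                                            function(cj)
          queen_bases[[cj]][[keys[i]]])))
        if (length(other_bases) &&
            (!length(intersect(colony_bases, other_bases)) ||
             length(setdiff(colony_bases, other_bases)))) {
          fail[i] <- rules[5]; next
        }
      }
      qbase <- .code_to_base(qa[[i]], v$sites$ref[i], v$sites$alt[i])
      dbase <- .code_to_base(unique(d_all), v$sites$ref[i], v$sites$alt[i])
      if (length(setdiff(dbase, qbase))) fail[i] <- rules[6]
    }
    keep <- is.na(fail)
    n_retained <- n_retained + sum(keep)
    tab <- table(factor(fail[!keep], levels = rules))
    counts <- counts + as.numeric(tab)
    out[[ci]] <- list(colony = co$colony,
                      vcf = co$vcf[keep, c("queen", co$drones)],
                      drones = co$drones,
                      replicate_of = character(),
                      fail_rule = fail)
    names(out)[ci] <- co$colony
  }
  report <- structure(list(
    counts = counts, n_input = n_input, n_retained = n_retained,
    fractions = counts / n_input, retained_fraction = n_retained / n_input),
    class = "qc_report")
  list(colonies = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d sites in, %d retained (%.1f%%)\n",
              x$n_input, x$n_retained, 100 * x$retained_fraction))
  for (r in names(x$counts))
    cat(sprintf("  %-28s %8d (%.2f%%)\n", r, x$counts[[r]],
                100 * x$fractions[[r]]))
  invisible(x)
}

#' Variant filter for assembly polishing
#'
#' Retains correction candidates from a diploid-coded variant call set
#' against a draft assembly: quality at least 20 and either a homozygous
#' alternate genotype or a heterozygous genotype with zero reads
#' supporting the reference allele. Heterozygous calls lacking a
#' reference-supporting read count are skipped with a warning.
#'
#' @param calls data.frame with columns `qual`, `gt` (diploid strings) and
#'   `ad_ref` (reads supporting the reference allele; may be NA).
#' @return the retained rows of `calls`.
#' @export
polishing_variant_filter <- function(calls) {
  gt <- gsub("|", "/", calls$gt, fixed = TRUE)
  hom_alt <- vapply(.alleles(gt), function(a)
    length(a) > 0 && all(a != "0") && length(unique(a)) == 1, TRUE)
  het <- vapply(.alleles(gt), function(a)
    length(unique(a)) > 1, TRUE)
  no_ad <- het & is.na(calls$ad_ref)
  if (any(no_ad))
    warning(sum(no_ad), " heterozygous call(s) lack allele depths; skipped")
  keep <- calls$qual >= 20 &
    (hom_alt | (het & !is.na(calls$ad_ref) & calls$ad_ref == 0))
  calls[keep, , drop = FALSE]
}
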