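#' @title VCF site tables
#' @description A `vcf_sites` object holds biallelic (or multi-allelic) SNP
#'   sites with per-sample genotype codes and the site-level annotations the
#'   hard filters need (QUAL, FS, MQ, SOR). Genotype codes are kept as VCF
#'   allele-index strings: haploid `"0"`/`"1"`, diploid `"0/0"`, `"0/1"`,
#'   `"1/1"`, missing `"."`/`"./."`. Positions are stored 0-based (column
#'   `start`); each site spans one base.
#' @param sites data.frame with columns `chrom`, `start`, `ref`, `alt` and
#'   optionally `qual`, `fs`, `mq`, `sor` (absent annotations may be NA).
#' @param gt character matrix, sites x samples, with column names.
#' @return an object of class `vcf_sites`.
#' @export
vcf_sites <- function(sites, gt) {
  stopifnot(is.data.frame(sites), is.matrix(gt),
            nrow(sites) == nrow(gt), !is.null(colnames(gt)))
  for (col in c("qual", "fs", "mq", "sor"))
    if (is.null(sites[[col]])) sites[[col]] <- NA_real_
  sites$start <- as.numeric(sites$start)
  rownames(sites) <- NULL
  rownames(gt) <- NULL
  structure(list(sites = sites, gt = gt), class = "vcf_sites")
}

#' @export
print.vcf_sites <- function(x, ...) {
  cat(sprintf("<vcf_sites> %d sites x %d samples (%s)\n",
              nrow(x$sites), ncol(x$gt),
              paste(utils::head(colnames(x$gt), 5), collapse = ", ")))
  invisible(x)
}

#' @export
dim.vcf_sites <- function(x) c(nrow(x$sites), ncol(x$gt))

#' Subset a vcf_sites object by site and/or sample
#'
#' @param x a `vcf_sites` object.
#' @param i site index (logical or integer).
#' @param j sample index or names.
#' @param ... ignored.
#' @export
`[.vcf_sites` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_len(ncol(x$gt))
  vcf_sites(x$sites[i, , drop = FALSE], x$gt[i, j, drop = FALSE])
}

#' Read genotypes from a VCF file
#'
#' Thin wrapper around [vcfR::read.vcfR()] returning a [vcf_sites] table.
#' Diploid phased separators are normalised to `/`; `"./."` and `"."` map
#' to missing. INFO annotations FS, MQ and SOR are parsed when present and
#' left `NA` (unavailable) otherwise.
#'
#' @param path VCF 4.x file (may be gzipped).
#' @param samples optional character vector restricting (and ordering) the
#'   samples; unknown names are an error.
#' @return a `vcf_sites` object; `start` is the 0-based site position.
#' @export
read_vcf_genotypes <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!"GT" %in% rownames(v@gt) && !length(grep("GT", v@gt[, "FORMAT"])))
    stop("VCF has no GT format field")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s))
      stop("sample(s) not found in VCF: ", paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[is.na(gt) | gt == "./." | gt == "."] <- "."
  info <- fix$INFO
  grab <- function(key) {
    val <- rep(NA_real_, length(info))
    pat <- paste0("(^|;)", key, "=[^;]+")
    hit <- !is.na(info) & grepl(pat, info)
    mm <- regmatches(info[hit], regexpr(pat, info[hit]))
    val[hit] <- suppressWarnings(as.numeric(sub(paste0(".*", key, "="), "", mm)))
    val
  }
  sites <- data.frame(
    chrom = fix$CHROM,
    start = as.numeric(fix$POS) - 1,
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    fs = grab("FS"), mq = grab("MQ"), sor = grab("SOR"),
    stringsAsFactors = FALSE)
  vcf_sites(sites, gt)
}

#' Write a vcf_sites table as VCF 4.2 text
#'
#' @param x a `vcf_sites` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(x, path) {
  stopifnot(inherits(x, "vcf_sites"))
  s <- x$sites
  fmt_num <- function(v) ifelse(is.na(v), NA, format(v, trim = TRUE,
                                                     scientific = FALSE))
  info <- apply(cbind(FS = fmt_num(s$fs), MQ = fmt_num(s$mq),
                      SOR = fmt_num(s$sor)), 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) "." else paste(paste0(names(r), "=", r), collapse = ";")
  })
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MappingQuality\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"StrandOddsRatio\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(x$gt)), collapse = "\t"))
  body <- paste(s$chrom, format(s$start + 1, trim = TRUE, scientific = FALSE),
                ".", s$ref, s$alt,
                ifelse(is.na(s$qual), ".", fmt_num(s$qual)), ".", info, "GT",
                sep = "\t")
  gtcol <- apply(x$gt, 1, paste, collapse = "\t")
  writeLines(c(hdr, paste(body, gtcol, sep = "\t")), path)
  invisible(path)
}
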