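#' Genotype matrix container
#'
#' Holds unphased diploid biallelic calls for a set of samples. Calls are
#' stored as the count of the ALT allele (0, 1, 2, or `NA` for no-call);
#' the REF/ALT nucleotides per SNP live in the `info` table so that the
#' alphabetical coding orientation used by [code_additive()] can be applied
#' independently of VCF allele orientation.
#'
#' @param calls integer (or numeric, for expectation-mode hybrids) matrix,
#'   samples x SNPs, ALT-allele dosage in \[0, 2\], `NA` = missing.
#' @param info data.frame with one row per SNP: `chrom`, `pos` (1-based bp),
#'   `ref`, `alt` (single distinct nucleotides in A/C/G/T).
#' @param samples character vector of sample identifiers (rows of `calls`).
#' @param dom optional numeric matrix of heterozygosity probabilities
#'   (expectation-mode hybrids only).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, info, samples, dom = NULL) {
  calls <- as.matrix(calls)
  stopifnot(nrow(info) == ncol(calls), length(samples) == nrow(calls))
  nt <- c("A", "C", "G", "T")
  if (!all(info$ref %in% nt) || !all(info$alt %in% nt))
    stop("ref and alt must be single nucleotides in {A,C,G,T}")
  if (any(info$ref == info$alt))
    stop("ref and alt must differ for every SNP")
  ord <- order(info$chrom, info$pos)
  if (!identical(ord, seq_len(nrow(info)))) {
    info <- info[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
    if (!is.null(dom)) dom <- dom[, ord, drop = FALSE]
  }
  if (any(unlist(tapply(info$pos, info$chrom, function(p) diff(p) <= 0))))
    stop("positions within a chromosome must be strictly increasing")
  rownames(calls) <- samples
  colnames(calls) <- paste(info$chrom, info$pos, sep = ":")
  if (!is.null(dom)) dimnames(dom) <- dimnames(calls)
  rownames(info) <- NULL
  structure(list(samples = samples, info = snp_stats_(calls, info),
                 calls = calls, dom = dom),
            class = "geno_matrix")
}

# recompute per-SNP maf and missing_rate from the calls
snp_stats_ <- function(calls, info) {
  n_ok <- colSums(!is.na(calls))
  alt_freq <- ifelse(n_ok > 0, colMeans(calls, na.rm = TRUE) / 2, NA_real_)
  info$maf <- pmin(alt_freq, 1 - alt_freq)
  info$missing_rate <- 1 - n_ok / nrow(calls)
  info
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs (%d chromosome(s), %.2f%% missing)\n",
              length(x$samples), nrow(x$info), length(unique(x$info$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param samples sample ids or indices to keep (default all).
#' @param snps SNP indices or logical mask to keep (default all).
#' @export
subset_geno <- function(x, samples = NULL, snps = NULL) {
  calls <- x$calls; info <- x$info; dom <- x$dom
  if (!is.null(snps)) {
    calls <- calls[, snps, drop = FALSE]
    info <- info[snps, , drop = FALSE]
    if (!is.null(dom)) dom <- dom[, snps, drop = FALSE]
  }
  if (!is.null(samples)) {
    calls <- calls[samples, , drop = FALSE]
    if (!is.null(dom)) dom <- dom[samples, , drop = FALSE]
  }
  geno_matrix(calls, info[, c("chrom", "pos", "ref", "alt")], rownames(calls),
              dom = dom)
}

#' Read parental genotypes from a VCF
#'
#' Reads a plain or bgzipped VCF with GT fields and returns a [geno_matrix()].
#' Only biallelic SNP records are ingested; multiallelic or indel records are
#' skipped (with a message) when `skip_invalid = TRUE`, otherwise the first
#' offending record raises an error naming it.
#'
#' @param path path to the VCF file.
#' @param skip_invalid skip (rather than error on) multiallelic / non-SNP
#'   records. Default `TRUE`.
#' @return A [geno_matrix()].
#' @export
load_vcf <- function(path, skip_invalid = TRUE) {
  if (!file.exists(path)) stop(sprintf("cannot read VCF: '%s' does not exist", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  nt <- c("A", "C", "G", "T")
  ok <- fix$REF %in% nt & fix$ALT %in% nt
  if (!all(ok)) {
    bad <- which(!ok)
    if (!skip_invalid)
      stop(sprintf("record %s:%s (REF=%s, ALT=%s) is not a biallelic SNP",
                   fix$CHROM[bad[1]], fix$POS[bad[1]], fix$REF[bad[1]], fix$ALT[bad[1]]))
    message(sprintf("load_vcf: skipped %d non-biallelic-SNP record(s)", length(bad)))
  }
  if (!any(ok)) stop_empty("no biallelic SNPs found in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  # duplicate positions (e.g. split multiallelics) violate the strict-order
  # invariant; keep the first occurrence
  key <- paste(fix$CHROM, fix$POS)
  if (anyDuplicated(key)) {
    dup <- duplicated(key)
    message(sprintf("load_vcf: dropped %d duplicate-position record(s)", sum(dup)))
    gt <- gt[!dup, , drop = FALSE]
    fix <- fix[!dup, , drop = FALSE]
  }
  code <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  calls <- matrix(code[chartr("|", "/", gt)], nrow = nrow(gt))
  calls <- t(calls)  # samples x SNPs
  info <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  geno_matrix(calls, info, colnames(gt))
}

#' Quality-filter SNPs by missingness and minor allele frequency
#'
#' Retains SNPs with `missing_rate <= max_missing` and `maf >= min_maf`
#' (a SNP exactly at the MAF threshold is kept). Per-filter removal counts
#' are reported via `message()`.
#'
#' @param g a [geno_matrix()].
#' @param max_missing maximum tolerated per-SNP missing fraction (default 0.20).
#' @param min_maf minimum minor allele frequency, computed over non-missing
#'   calls (default 0.05).
#' @return The filtered [geno_matrix()].
#' @export
qc_filter <- function(g, max_missing = 0.20, min_maf = 0.05) {
  assert_fraction(max_missing, "max_missing"); assert_fraction(min_maf, "min_maf")
  miss_fail <- g$info$missing_rate > max_missing
  maf_fail <- is.na(g$info$maf) | g$info$maf < min_maf
  keep <- !miss_fail & !maf_fail
  message(sprintf("qc_filter: removed %d SNP(s) for missingness > %g, %d for MAF < %g; %d retained",
                  sum(miss_fail), max_missing, sum(maf_fail & !miss_fail), min_maf, sum(keep)))
  if (!any(keep)) stop_empty("qc_filter removed all SNPs")
  subset_geno(g, snps = keep)
}

#' Impute missing calls by the per-SNP mode
#'
#' Each missing call is replaced by the most frequent call (0, 1 or 2 ALT
#' copies) at that SNP. Ties are broken in favour of the call with the
#' smaller additive code, i.e. the homozygote of the alphabetically lower
#' allele.
#'
#' @param g a [geno_matrix()] (normally after [qc_filter()]).
#' @return A [geno_matrix()] with no missing calls.
#' @export
impute_missing <- function(g) {
  calls <- g$calls
  miss <- is.na(calls)
  if (!any(miss)) return(g)
  if (any(all_na <- colSums(!miss) == 0))
    stop(sprintf("cannot impute: SNP(s) entirely missing: %s",
                 paste(colnames(calls)[all_na], collapse = ", ")))
  # additive code of ALT dosage v: v if ref < alt, else 2 - v
  flip <- g$info$ref > g$info$alt
  fill <- vapply(seq_len(ncol(calls)), function(j) {
    cnt <- tabulate(calls[, j] + 1L, nbins = 3L)  # counts of dosages 0,1,2
    cand <- which(cnt == max(cnt)) - 1L
    if (length(cand) > 1L) {
      addcode <- if (flip[j]) 2 - cand else cand
      cand <- cand[which.min(addcode)]
    }
    as.numeric(cand[1L])
  }, numeric(1))
  calls[miss] <- fill[col(calls)[miss]]
  g$calls <- calls
  g$info <- snp_stats_(calls, g$info)
  g
}

#' Additive (0/1/2) genotype coding
#'
#' Codes each call as the dosage of the alphabetically *higher* allele: the
#' homozygote of the alphabetically lower allele is 0, heterozygotes are 1,
#' and the other homozygote is 2. Note this orientation is alphabetical by
#' nucleotide, **not** REF/ALT dosage as VCF users may expect: for a SNP with
#' alleles T (ref) and C (alt), C/C codes 0 and T/T codes 2.
#'
#' @param g a [geno_matrix()] with no missing calls.
#' @return Numeric matrix (samples x SNPs) of dosages in \[0, 2\], with a
#'   `snp_info` attribute carrying the SNP table. Columns that are constant
#'   are flagged in the `constant` attribute.
#' @export
code_additive <- function(g) {
  if (anyNA(g$calls)) stop("code_additive: missing calls present; run impute_missing() first")
  A <- g$calls
  flip <- g$info$ref > g$info$alt
  if (any(flip)) A[, flip] <- 2 - A[, flip, drop = FALSE]
  structure(A, snp_info = g$info, constant = apply_constant_(A))
}

apply_constant_ <- function(M) {
  colSums(abs(M - rep(M[1L, ], each = nrow(M)))) == 0
}

#' Dominant (0/1) genotype coding
#'
#' Codes heterozygous calls 1 and both homozygotes 0. For expectation-mode
#' hybrid genotypes the stored heterozygosity probability is returned.
#' Fully homozygous (inbred) samples yield all-zero rows.
#'
#' @inheritParams code_additive
#' @return Numeric matrix (samples x SNPs) in \[0, 1\] with a `snp_info`
#'   attribute.
#' @export
code_dominant <- function(g) {
  if (!is.null(g$dom)) return(structure(g$dom, snp_info = g$info))
  if (anyNA(g$calls)) stop("code_dominant: missing calls present; run impute_missing() first")
  D <- (g$calls == 1) * 1
  dimnames(D) <- dimnames(g$calls)
  structure(D, snp_info = g$info)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Intended for round-tripping simulated parents; calls must be integer
#' dosages (no expectation-mode fractions).
#'
#' @param g a [geno_matrix()].
#' @param path output path (plain text).
#' @export
write_vcf <- function(g, path) {
  if (!is.null(g$dom) || any(g$calls %% 1 != 0, na.rm = TRUE))
    stop("write_vcf requires integer calls")
  gt <- c("0/0", "0/1", "1/1")[g$calls + 1L]
  gt[is.na(gt)] <- "./."
  gt <- matrix(gt, nrow = nrow(g$calls))
  body <- cbind(g$info$chrom, g$info$pos, paste(g$info$chrom, g$info$pos, sep = ":"),
                g$info$ref, g$info$alt, ".", "PASS", ".", "GT", t(gt))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write the per-SNP information table
#'
#' @param g a [geno_matrix()].
#' @param path output TSV path.
#' @export
write_snp_info <- function(g, path) {
  utils::write.table(g$info, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
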