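#' Testcross design
#'
#' A males x females testcross design: which male and female parent produced
#' each hybrid. The full factorial is allowed but not required.
#'
#' @param hybrids data.frame with columns `hybrid_id`, `male_id`, `female_id`.
#' @return An object of class `cross_design` with elements `hybrids` (the
#'   table), `males`, `females` (unique parent ids, in order of appearance).
#' @export
cross_design <- function(hybrids) {
  need <- c("hybrid_id", "male_id", "female_id")
  if (!all(need %in% names(hybrids)))
    stop("design table needs columns hybrid_id, male_id, female_id")
  hybrids <- as.data.frame(hybrids)[, need]
  if (anyDuplicated(hybrids$hybrid_id))
    stop("hybrid ids must be unique")
  structure(list(hybrids = hybrids,
                 males = unique(hybrids$male_id),
                 females = unique(hybrids$female_id)),
            class = "cross_design")
}

#' Read a testcross design table
#'
#' @param path TSV with columns `hybrid_id`, `male_id`, `female_id`.
#' @export
read_cross_design <- function(path) {
  cross_design(utils::read.delim(path, stringsAsFactors = FALSE,
                                 colClasses = "character"))
}

#' Build the full factorial males x females design
#'
#' Hybrid ids are `<male>_x_<female>`.
#'
#' @param males,females parent id vectors.
#' @export
factorial_design <- function(males, females) {
  grid <- expand.grid(male_id = males, female_id = females,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cross_design(data.frame(hybrid_id = paste(grid$male_id, grid$female_id, sep = "_x_"),
                          grid, stringsAsFactors = FALSE))
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("cross_design: %d hybrids from %d males x %d females\n",
              nrow(x$hybrids), length(x$males), length(x$females)))
  invisible(x)
}

#' Infer hybrid genotypes from parental genotypes
#'
#' In `force_hom` mode (the default, appropriate for inbred parents) any
#' residual parental heterozygote is first collapsed to that SNP's major
#' homozygote (ties to the homozygote of the alphabetically lower allele);
#' the hybrid call is then the union of the two parental alleles, so hybrid
#' dosage is the parental-dosage mean and a hybrid is heterozygous exactly
#' where its parents carry different homozygotes. In `expectation` mode the
#' hybrid additive dosage is the mean parental dosage and the dominant value
#' is the probability the offspring is heterozygous under a random gamete
#' draw from each parent; both may be fractional.
#'
#' @param parents a [geno_matrix()] with no missing calls.
#' @param design a [cross_design()].
#' @param mode `"force_hom"` or `"expectation"`.
#' @return A [geno_matrix()] with one row per hybrid (expectation mode
#'   carries the heterozygosity probabilities in `$dom`).
#' @export
infer_hybrids <- function(parents, design, mode = c("force_hom", "expectation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(parents, "geno_matrix"), inherits(design, "cross_design"))
  if (anyNA(parents$calls)) stop("infer_hybrids: parents must be imputed first")
  ids <- unique(c(design$hybrids$male_id, design$hybrids$female_id))
  unknown <- setdiff(ids, parents$samples)
  if (length(unknown))
    stop(sprintf("design references unknown parent id(s): %s",
                 paste(unknown, collapse = ", ")))
  mi <- match(design$hybrids$male_id, parents$samples)
  fi <- match(design$hybrids$female_id, parents$samples)
  P <- parents$calls
  if (mode == "force_hom") {
    het <- P == 1
    if (any(het)) {
      # per-SNP major homozygote (ALT-dosage 0 or 2); tie -> alphabetically
      # lower allele's homozygote
      n0 <- colSums(P == 0); n2 <- colSums(P == 2)
      flip <- parents$info$ref > parents$info$alt
      major <- ifelse(n2 > n0 | (n2 == n0 & flip), 2, 0)
      P[het] <- major[col(P)[het]]
    }
    H <- (P[mi, , drop = FALSE] + P[fi, , drop = FALSE]) / 2
    geno_matrix(H, parents$info[, c("chrom", "pos", "ref", "alt")],
                design$hybrids$hybrid_id)
  } else {
    pm <- P[mi, , drop = FALSE] / 2  # P(male gamete carries ALT)
    pf <- P[fi, , drop = FALSE] / 2
    H <- pm + pf                      # expected ALT dosage
    dom <- pm * (1 - pf) + (1 - pm) * pf
    geno_matrix(H, parents$info[, c("chrom", "pos", "ref", "alt")],
                design$hybrids$hybrid_id, dom = dom)
  }
}
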