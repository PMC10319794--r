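#' Read a phenotype table
#'
#' One row per sample, first column `sample_id`, one further column per
#' trait. At most one value per (sample, trait); empty cells or NA are
#' treated as missing.
#'
#' @param path TSV path.
#' @return data.frame with rownames = sample ids and one numeric column per
#'   trait.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") stop("first column must be sample_id")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in phenotype table")
  out <- tab[, -1, drop = FALSE]
  out[] <- lapply(out, as.numeric)
  rownames(out) <- tab$sample_id
  out
}

#' Extract one trait as a named vector
#'
#' @param pheno data.frame from [read_phenotypes()].
#' @param trait trait (column) name.
#' @export
trait_values <- function(pheno, trait) {
  if (!trait %in% names(pheno)) stop(sprintf("trait '%s' not found", trait))
  stats::setNames(pheno[[trait]], rownames(pheno))
}

#' General combining ability of the male parents
#'
#' The GCA of male parent i is the mean phenotype of its testcrosses minus
#' the grand mean over all testcross phenotypes, means taken over non-missing
#' values. A parent with no phenotyped testcross gets `NA` (excluded
#' downstream).
#'
#' @param t named numeric vector of testcross phenotypes (names = hybrid ids).
#' @param design a [cross_design()].
#' @return Named numeric vector, one value per male parent in the design.
#' @export
derive_gca <- function(t, design) {
  tv <- t[design$hybrids$hybrid_id]
  grand <- mean(tv, na.rm = TRUE)
  if (!is.finite(grand)) stop_empty("no non-missing testcross phenotypes")
  means <- tapply(tv, design$hybrids$male_id, mean, na.rm = TRUE)
  g <- means[design$males] - grand
  g[!is.finite(g)] <- NA_real_
  stats::setNames(as.numeric(g), design$males)
}

#' Mid-parent heterosis of each hybrid
#'
#' H = testcross phenotype minus the mean of its two parents' phenotypes.
#' Missing in any of the three terms propagates to `NA`.
#'
#' @param t named numeric vector of testcross phenotypes (hybrid ids).
#' @param v named numeric vector of inbred-parent phenotypes (parent ids).
#' @param design a [cross_design()].
#' @return Named numeric vector, one value per hybrid in the design.
#' @export
derive_heterosis <- function(t, v, design) {
  hy <- design$hybrids
  h <- t[hy$hybrid_id] - (v[hy$male_id] + v[hy$female_id]) / 2
  stats::setNames(as.numeric(h), hy$hybrid_id)
}
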