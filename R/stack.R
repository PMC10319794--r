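#' Standardize phenotype blocks and stack the joint Y/A/D system
#'
#' Builds the joint observation vector over the requested source blocks —
#' inbred phenotypes (V), testcross phenotypes (T), general combining
#' ability (G, one value per male parent), and mid-parent heterosis (H, one
#' per hybrid) — each standardized within its block, with aligned additive
#' (A) and dominant (D) design matrices. V and G rows carry the parent's
#' genotype row; T and H rows carry the hybrid's. D rows of V and G blocks
#' are identically zero (inbreds carry no heterozygotes).
#'
#' Rows with missing phenotype are dropped before standardization. Block
#' order in the stack is V, T, G, H.
#'
#' @param v,t,g,h named numeric vectors (see [derive_gca()],
#'   [derive_heterosis()]); pass `NULL` to omit a block not in `blocks`.
#' @param design a [cross_design()].
#' @param parents,hybrids imputed [geno_matrix()] objects (same SNP set).
#' @param blocks which blocks to stack; `c("V","G")` for the inbred-only
#'   analysis, `c("T","H")` for hybrid-only, all four for the combined.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return An object of class `stacked_data`: `y`, `meta` (data.frame with
#'   `row_sample`, `block`, `female`), `A`, `D`, `B` (covariates, `NULL`
#'   until [build_covariates()]), `scaling` (per-block centre/sd).
#' @export
standardize_and_stack <- function(v = NULL, t = NULL, g = NULL, h = NULL,
                                  design, parents, hybrids,
                                  blocks = c("V", "T", "G", "H"),
                                  sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  blocks <- match.arg(blocks, c("V", "T", "G", "H"), several.ok = TRUE)
  blocks <- intersect(c("V", "T", "G", "H"), blocks)  # canonical order
  A_par <- code_additive(parents); A_hyb <- code_additive(hybrids)
  D_hyb <- code_dominant(hybrids)
  fem <- stats::setNames(design$hybrids$female_id, design$hybrids$hybrid_id)

  vals <- list(V = v, T = t, G = g, H = h)
  y <- numeric(0); meta <- NULL; A <- NULL; D <- NULL; scaling <- list()
  for (b in blocks) {
    x <- vals[[b]]
    if (is.null(x)) stop(sprintf("block %s requested but its values are NULL", b))
    x <- x[!is.na(x)]
    if (length(x) < 2) stop(sprintf("block %s has fewer than 2 non-missing values", b))
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (s == 0) stop(sprintf("block %s has zero variance; cannot standardize", b))
    m <- mean(x)
    scaling[[b]] <- c(centre = m, sd = s)
    ids <- names(x)
    if (b %in% c("V", "G")) {
      idx <- match(ids, parents$samples)
      if (anyNA(idx)) stop(sprintf("block %s: no genotype for %s", b,
                                   paste(ids[is.na(idx)], collapse = ", ")))
      Ab <- A_par[idx, , drop = FALSE]
      Db <- matrix(0, length(ids), ncol(A_par))
      female <- rep(NA_character_, length(ids))
    } else {
      idx <- match(ids, hybrids$samples)
      if (anyNA(idx)) stop(sprintf("block %s: no genotype for %s", b,
                                   paste(ids[is.na(idx)], collapse = ", ")))
      Ab <- A_hyb[idx, , drop = FALSE]
      Db <- D_hyb[idx, , drop = FALSE]
      female <- unname(fem[ids])
    }
    y <- c(y, (x - m) / s)
    meta <- rbind(meta, data.frame(row_sample = ids, block = b, female = female,
                                   stringsAsFactors = FALSE))
    A <- rbind(A, Ab); D <- rbind(D, Db)
  }
  rownames(meta) <- NULL
  dimnames(A) <- list(NULL, colnames(parents$calls))
  dimnames(D) <- dimnames(A)
  noise <- noise_loadings_(meta, design, t, scaling)
  structure(list(y = unname(y), meta = meta, A = A, D = D, B = NULL,
                 snp_info = parents$info, scaling = scaling,
                 sd_type = sd_type, noise = noise),
            class = "stacked_data")
}

# Sparse map from independent measurement noises (one per phenotyped parent
# and hybrid, scaled to unit variance under the no-signal model) to the
# standardized stacked rows. G rows average their male's testcross noises;
# H rows combine the hybrid's noise with minus one half of each parent's.
# Used by the whitened marker test: the derived blocks reuse V and T noise,
# so stacked residuals are correlated by construction and the iid variance
# formula is anti-conservative.
noise_loadings_ <- function(meta, design, t, scaling) {
  hy <- design$hybrids
  male_of <- stats::setNames(hy$male_id, hy$hybrid_id)
  female_of <- stats::setNames(hy$female_id, hy$hybrid_id)
  h_ids <- meta$row_sample[meta$block == "H"]
  units <- unique(c(paste0("e:", meta$row_sample[meta$block %in% c("V", "G")]),
                    paste0("e:", male_of[h_ids]), paste0("e:", female_of[h_ids]),
                    paste0("f:", meta$row_sample[meta$block %in% c("T", "H")]),
                    if (!is.null(t)) paste0("f:", names(t)[!is.na(t)])))
  s <- function(b) if (is.null(scaling[[b]])) NA_real_ else unname(scaling[[b]]["sd"])
  # parent- and hybrid-noise sds: taken from the V and T blocks when those
  # are stacked, otherwise recovered through the no-signal identity
  # var(H) = var(T) + var(V)/2
  s_t <- s("T"); s_v <- s("V")
  if (is.na(s_t) && !is.na(s("H")) && !is.na(s_v))
    s_t <- sqrt(max(s("H")^2 - s_v^2 / 2, 0))
  if (is.na(s_v) && !is.na(s("H")) && !is.na(s_t))
    s_v <- sqrt(max(2 * (s("H")^2 - s_t^2), 0))
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, unit, w) {
    k <- match(unit, units)
    w <- rep_len(w, length(i))
    ok <- !is.na(k) & !is.na(w) & w != 0
    ii <<- c(ii, i[ok]); jj <<- c(jj, k[ok]); xx <<- c(xx, w[ok])
  }
  for (r in seq_len(nrow(meta))) {
    b <- meta$block[r]; id <- meta$row_sample[r]
    if (b == "V") add(r, paste0("e:", id), 1)
    else if (b == "T") add(r, paste0("f:", id), 1)
    else if (b == "G") {
      tc <- hy$hybrid_id[hy$male_id == id]
      if (!is.null(t)) tc <- tc[tc %in% names(t)[!is.na(t)]]
      if (length(tc) && !is.na(s_t))
        add(rep(r, length(tc)), paste0("f:", tc), (s_t / s("G")) / length(tc))
      else add(r, paste0("e:", id), 1)  # fallback: treat as an own unit
    } else {
      sh <- s("H")
      if (is.na(s_t)) add(r, paste0("f:", id), 1)  # no way to split the noise
      else {
        add(r, paste0("f:", id), s_t / sh)
        if (!is.na(s_v) && s_v > 0) {
          add(r, paste0("e:", male_of[[id]]), -s_v / (2 * sh))
          add(r, paste0("e:", female_of[[id]]), -s_v / (2 * sh))
        }
      }
    }
  }
  Matrix::sparseMatrix(i = jj, j = ii, x = xx,
                       dims = c(length(units), nrow(meta)),
                       dimnames = list(units, NULL))
}

#' @export
print.stacked_data <- function(x, ...) {
  cat(sprintf("stacked_data: %d rows (%s) x %d SNPs%s\n", length(x$y),
              paste(sprintf("%s=%d", names(table(x$meta$block)),
                            table(x$meta$block)), collapse = ", "),
              ncol(x$A), if (is.null(x$B)) "" else sprintf(", %d covariates", ncol(x$B))))
  invisible(x)
}

#' Principal-component scores of the additive genotypes
#'
#' PCA of the column-centred additive dosages of a set of individuals;
#' used as ancestry covariates in the association model.
#'
#' @param A additive dosage matrix with rownames = individual ids.
#' @param n_pc number of leading components to return.
#' @return matrix of scores (individuals x n_pc).
#' @export
pc_scores <- function(A, n_pc = 3) {
  if (n_pc > min(dim(A)) - 1)
    stop(sprintf("n_pc = %d exceeds the available components", n_pc))
  pr <- stats::prcomp(A, center = TRUE, scale. = FALSE, rank. = n_pc)
  sc <- pr$x[, seq_len(n_pc), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(n_pc))
  sc
}

#' Build the base covariate matrix B
#'
#' B contains an intercept, the leading principal-component scores of the
#' column-centred additive genotypes of the unique individuals (each
#' individual enters the PCA once even though it may occupy several stacked
#' rows), and one 0/1 dummy per female parent and source block (a dummy for
#' the T rows of that female's hybrids and another for their H rows).
#' Block-specific dummies absorb both the female's mean effect on each
#' scale and the female parent's measurement noise that the mid-parent term
#' copies into every one of her H rows; with a single shared dummy that
#' noise component would remain in the residuals and correlate rows across
#' male families. Rank-deficient columns are dropped with a warning.
#'
#' @param stacked a [standardize_and_stack()] result.
#' @param n_pc number of principal components (default 3).
#' @param scores optional precomputed PC score matrix (rownames =
#'   individual ids) covering every `row_sample`; if supplied the PCA is
#'   skipped — used in cross-validation so that scores are computed once
#'   from genotypes only.
#' @return The `stacked_data` with `$B` filled in and the scores stored in
#'   `attr(stacked$B, "pc_scores")`.
#' @export
build_covariates <- function(stacked, n_pc = 3, scores = NULL) {
  meta <- stacked$meta
  if (is.null(scores)) {
    first <- !duplicated(meta$row_sample)
    U <- stacked$A[first, , drop = FALSE]
    rownames(U) <- meta$row_sample[first]
    scores <- pc_scores(U, n_pc)
  } else {
    miss <- setdiff(unique(meta$row_sample), rownames(scores))
    if (length(miss)) stop(sprintf("precomputed scores missing for: %s",
                                   paste(utils::head(miss, 5), collapse = ", ")))
    scores <- scores[, seq_len(min(n_pc, ncol(scores))), drop = FALSE]
  }
  PC <- scores[meta$row_sample, , drop = FALSE]
  # per-block intercepts: each block is centred by construction, but the
  # marker test's noise model needs residualised markers orthogonal to
  # block-constant noise (the grand-mean terms of the derived blocks)
  blks <- unique(meta$block)
  BL <- matrix(0, nrow(meta), max(length(blks) - 1L, 0L))
  if (ncol(BL)) {
    colnames(BL) <- paste0("block_", blks[-1])
    for (k in seq_len(ncol(BL))) BL[, k] <- as.numeric(meta$block == blks[k + 1L])
  }
  # first female is the reference level: her dummy would be collinear with
  # the block intercept (the dummies of one block sum to its indicator)
  females <- sort(unique(meta$female[!is.na(meta$female)]))[-1]
  blocks_fd <- intersect(c("T", "H"), unique(meta$block))
  FD <- matrix(0, nrow(meta), length(females) * length(blocks_fd))
  if (ncol(FD))
    colnames(FD) <- paste0("female_", rep(blocks_fd, each = length(females)),
                           "_", rep(females, length(blocks_fd)))
  k <- 0
  for (b in blocks_fd) for (f in females) {
    k <- k + 1
    FD[, k] <- as.numeric(meta$block == b & !is.na(meta$female) & meta$female == f)
  }
  B <- cbind(intercept = 1, BL, PC, FD)
  rownames(B) <- NULL
  B <- drop_collinear(B, label = "covariate")
  attr(B, "pc_scores") <- scores
  stacked$B <- B
  stacked
}
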