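#' Single-effect GLM scan over all SNPs
#'
#' For each SNP, fits by ordinary least squares
#' `y = B b + M_j c_j + e`, where `M` is the additive (dosage) or dominant
#' (heterozygosity) design over the stacked rows and `B` is the base
#' covariate matrix augmented with the columns of the current pseudo-QTNs.
#' Reports the two-sided t-test p-value and estimate of the marker
#' coefficient. A tested column that is constant or collinear with the
#' covariates yields `NA` (flagged, not an error) — e.g. every dominant
#' column when only V/G rows are stacked. When a tested SNP is itself a
#' pseudo-QTN, its own columns (both effect types) are removed from the
#' covariates for its own test.
#'
#' @param stacked a [stacked_data] with covariates ([build_covariates()]).
#' @param effect `"additive"` or `"dominant"`.
#' @param pseudo data.frame with columns `snp` (column index) and `effect`,
#'   the current pseudo-QTN set; `NULL` or zero rows for none.
#' @param se_type `"whitened"` (default) tests the OLS marker coefficient
#'   against the variance implied by the stack's known noise-sharing
#'   structure (`stacked$noise`) — required for a calibrated test because
#'   the derived G and H blocks reuse the measurement noise of the V and T
#'   rows — or `"iid"` for the naive model-based t-test, which treats all
#'   stacked rows as independent.
#' @return data.frame: `snp`, `chrom`, `pos`, `effect`, `estimate`,
#'   `t_stat`, `p_value`.
#' @export
glm_scan <- function(stacked, effect = c("additive", "dominant"), pseudo = NULL,
                     se_type = c("whitened", "iid")) {
  effect <- match.arg(effect)
  se_type <- match.arg(se_type)
  if (is.null(stacked$B)) stop("run build_covariates() first")
  M <- if (effect == "additive") stacked$A else stacked$D
  y <- stacked$y
  n <- length(y)
  L <- if (se_type == "whitened") stacked$noise else NULL
  pseudo <- pseudo %||% data.frame(snp = integer(0), effect = character(0))
  Bfull <- cbind(stacked$B, pseudo_columns(stacked, pseudo))
  if (n <= ncol(Bfull) + 1)
    stop(sprintf("only %d rows for %d covariates + marker", n, ncol(Bfull)))
  fit <- scan_against_(y, M, Bfull, L)
  # self-exclusion: re-test pseudo-QTN SNPs without their own columns
  for (j in unique(pseudo$snp)) {
    keep <- pseudo$snp != j
    Bj <- cbind(stacked$B, pseudo_columns(stacked, pseudo[keep, , drop = FALSE]))
    fj <- scan_against_(y, M[, j, drop = FALSE], Bj, L)
    fit$estimate[j] <- fj$estimate; fit$t_stat[j] <- fj$t_stat
    fit$p_value[j] <- fj$p_value
  }
  data.frame(snp = seq_len(ncol(M)),
             chrom = stacked$snp_info$chrom, pos = stacked$snp_info$pos,
             effect = effect, fit, stringsAsFactors = FALSE)
}

# design columns of a pseudo-QTN set (additive dosage or heterozygosity)
pseudo_columns <- function(stacked, pseudo) {
  if (is.null(pseudo) || nrow(pseudo) == 0) return(NULL)
  cols <- lapply(seq_len(nrow(pseudo)), function(k) {
    M <- if (pseudo$effect[k] == "additive") stacked$A else stacked$D
    M[, pseudo$snp[k]]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("q_", substr(pseudo$effect, 1, 1), pseudo$snp)
  out
}

# Vectorised marginal OLS of y on [B, m_j] for every column m_j of M:
# residualise y and M against B through one QR, then per-column slopes.
# With the sparse noise-loading matrix `L` supplied, the slope keeps its
# OLS value but its variance is the design-implied
# sigma2_j * ||L x_res||^2 / (x_res' x_res)^2, which is the exact sampling
# variance when the stacked noise is L' (iid unit noises) — the iid
# formula is the special case L = I.
scan_against_ <- function(y, M, B, L = NULL) {
  qb <- qr(B)
  r <- qb$rank
  Q <- qr.Q(qb)[, seq_len(r), drop = FALSE]
  yt <- as.numeric(y - Q %*% crossprod(Q, y))
  Mt <- M - Q %*% crossprod(Q, M)
  sxx <- colSums(Mt^2)
  sxy <- as.numeric(crossprod(Mt, yt))
  syy <- sum(yt^2)
  # relative tolerance: column effectively constant/collinear with B
  scale0 <- pmax(colSums(M^2), 1)
  ok <- sxx > 1e-10 * scale0
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  df <- length(y) - r - 1L
  rss <- pmax(syy - beta * sxy, 0)
  if (is.null(L)) {
    se <- sqrt(rss / df / sxx)
  } else {
    wxx <- Matrix::colSums((L %*% Mt)^2)
    # effective residual dof under the correlated-noise model:
    # E[rss_j] = tr(Sigma0) - tr(P_B Sigma0) - x'Sigma0 x / x'x
    tr_total <- sum(L@x^2)
    tr_B <- sum((L %*% Q)^2)
    df_eff <- pmax(tr_total - tr_B - wxx / pmax(sxx, 1e-12), 2)
    sigma2 <- rss / df_eff
    se <- sqrt(sigma2 * wxx) / sxx
  }
  tstat <- ifelse(ok & se > 0, beta / se, ifelse(ok, sign(beta) * Inf, NA_real_))
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- ifelse(is.na(p), NA_real_, pmax(p, .Machine$double.xmin))
  data.frame(estimate = beta, t_stat = tstat, p_value = p)
}

#' Select pseudo-QTNs from a scan
#'
#' Candidates are the significant (below-threshold) SNP/effect columns in
#' ascending p-value order (ties broken by chromosome, position, additive
#' before dominant). A candidate is skipped if its squared Pearson
#' correlation over the stacked rows with an already-kept candidate column
#' exceeds `ld_r2_max`. The kept list, truncated at `max_candidates`, is
#' then cut to the prefix whose OLS fit `y ~ [B, prefix]` minimises BIC.
#'
#' @param scan combined scan results (rows from both effect scans).
#' @param stacked the [stacked_data] scanned.
#' @param threshold genome-wide per-test significance threshold.
#' @param ld_r2_max squared-correlation exclusion threshold (default 0.7).
#' @param max_candidates cap on candidates entering the BIC step (default 20).
#' @param include optional data.frame (`snp`, `effect`) of markers treated
#'   as candidates regardless of their current p-value — the incumbent
#'   pseudo-QTNs during iteration, so that a marker once incorporated can
#'   only leave through the BIC truncation rather than by a transient
#'   p-value fluctuation (which makes the iteration stable under
#'   finite-sample LD between detected markers).
#' @param prune_alpha backward-elimination keep level: after the BIC
#'   truncation the kept markers are refit jointly and the worst marker is
#'   dropped while its joint-model p-value exceeds this level. Defaults to
#'   `threshold`, which enforces that every pseudo-QTN is genome-wide
#'   significant *jointly with the others* — markers that entered on a
#'   marginal signal but explain little alongside the rest (chance-LD
#'   proxies of true loci) are removed.
#' @return data.frame subset of `scan` rows kept as pseudo-QTNs (possibly
#'   zero rows).
#' @export
select_pseudo_qtns <- function(scan, stacked, threshold,
                               ld_r2_max = 0.7, max_candidates = 20,
                               include = NULL, prune_alpha = threshold,
                               se_type = c("whitened", "iid")) {
  se_type <- match.arg(se_type)
  cl <- if (se_type == "whitened") stacked$noise else NULL
  keep_keys <- if (is.null(include)) character(0) else paste(include$snp, include$effect)
  sig <- scan[(!is.na(scan$p_value) & scan$p_value < threshold) |
                paste(scan$snp, scan$effect) %in% keep_keys, , drop = FALSE]
  sig <- sig[!is.na(sig$p_value), , drop = FALSE]
  if (nrow(sig) == 0) return(sig)
  ord <- order(sig$p_value, sig$chrom, sig$pos, sig$effect != "additive")
  sig <- sig[ord, , drop = FALSE]
  kept <- integer(0)
  cols <- NULL
  for (k in seq_len(nrow(sig))) {
    ck <- pseudo_columns(stacked, sig[k, , drop = FALSE])
    if (length(kept)) {
      r2 <- suppressWarnings(stats::cor(ck, cols))^2
      if (any(r2 > ld_r2_max, na.rm = TRUE)) next
    }
    kept <- c(kept, k)
    cols <- cbind(cols, ck)
    if (length(kept) >= max_candidates) break
  }
  sig <- sig[kept, , drop = FALSE]
  cols <- cols[, seq_along(kept), drop = FALSE]
  # greedy forward ordering by RSS reduction: at small founder numbers a
  # marker can tag several true loci at once through chance LD and outrank
  # them all marginally; conditioning at each step lets the markers that
  # carry independent signal surface in the path
  n <- length(stacked$y)
  path <- integer(0)
  remaining <- seq_len(nrow(sig))
  X <- stacked$B
  rss_path <- numeric(nrow(sig))
  for (step in seq_len(nrow(sig))) {
    qx <- qr(X)
    ry <- qr.resid(qx, stacked$y)
    RC <- qr.resid(qx, cols[, remaining, drop = FALSE])
    gain <- as.numeric(crossprod(RC, ry))^2 / pmax(colSums(RC^2), 1e-12)
    pick <- which.max(gain)
    path <- c(path, remaining[pick])
    X <- cbind(X, cols[, remaining[pick]])
    rss_path[step] <- sum(qr.resid(qr(X), stacked$y)^2)
    remaining <- remaining[-pick]
  }
  sig <- sig[path, , drop = FALSE]
  cols <- cols[, path, drop = FALSE]
  # BIC over prefixes of the forward path (k = 0 = covariate-only model)
  rss0 <- sum(qr.resid(qr(stacked$B), stacked$y)^2)
  p0 <- qr(stacked$B)$rank
  bic <- c(n * log(rss0 / n) + p0 * log(n),
           n * log(rss_path / n) + (p0 + seq_along(rss_path)) * log(n))
  best <- which.min(bic) - 1L
  sig <- sig[seq_len(best), , drop = FALSE]
  cols <- cols[, seq_len(best), drop = FALSE]
  # backward elimination in the joint model: markers that entered on a
  # marginal signal but explain nothing alongside the others (chance-LD
  # proxies of true loci) are dropped one at a time
  while (nrow(sig) > 0) {
    pj <- joint_marker_p_(stacked$y, stacked$B, cols, cl)
    worst <- which.max(pj)
    if (pj[worst] <= prune_alpha) break
    sig <- sig[-worst, , drop = FALSE]
    cols <- cols[, -worst, drop = FALSE]
  }
  sig
}

# two-sided t-test p-value of each marker column in the joint OLS fit
# y ~ [B, cols]; whitened variance when the noise-loading matrix `L` is given
joint_marker_p_ <- function(y, B, cols, L = NULL) {
  X <- cbind(B, cols)
  qx <- qr(X)
  df <- length(y) - qx$rank
  keep <- qx$pivot[seq_len(qx$rank)]
  Xk <- X[, keep, drop = FALSE]
  XtXi <- chol2inv(chol(crossprod(Xk)))
  b <- XtXi %*% crossprod(Xk, y)
  resid <- as.numeric(y - Xk %*% b)
  sigma2 <- sum(resid^2) / df
  if (is.null(L)) {
    se <- sqrt(diag(XtXi) * sigma2)
  } else {
    W <- as.matrix(L %*% Xk)
    se <- sqrt(sigma2 * diag(XtXi %*% crossprod(W) %*% XtXi))
  }
  pfull <- rep(NA_real_, ncol(X))
  pfull[keep] <- 2 * stats::pt(-abs(b / se), df)
  out <- pfull[ncol(B) + seq_len(ncol(cols))]
  out[is.na(out)] <- 1  # a fully collinear marker column explains nothing
  out
}

#' Run the iterative joint additive-dominant multi-locus GWAS
#'
#' The JPEG association engine: each iteration scans every SNP's additive
#' column and then its dominant column with the current pseudo-QTNs as
#' covariates, re-selects the pseudo-QTN set from the two scans, and stops
#' when the set no longer changes (or `max_iter` is reached, with a
#' warning). The genome-wide threshold is `alpha` Bonferroni-corrected for
#' both effect scans: `alpha / (2 m)` for `m` SNPs (the `m`-only
#' denominator is available via `bonferroni_denom = "m"`). The reported
#' p-values are those of the final iteration, in which each pseudo-QTN is
#' tested with its own columns removed from the covariates.
#'
#' @param stacked a [stacked_data]; covariates are built automatically if
#'   absent.
#' @param alpha familywise type-I error rate (default 0.01).
#' @param max_iter iteration cap (default 10).
#' @param ld_r2_max,max_candidates,prune_alpha see [select_pseudo_qtns()].
#' @param bonferroni_denom `"2m"` (default) or `"m"`.
#' @param n_pc principal components if covariates must be built.
#' @param se_type marker-test standard error, see [glm_scan()].
#' @return An object of class `assoc_result`: `results` (per SNP x effect:
#'   `chrom`, `pos`, `effect`, `estimate`, `t_stat`, `p_value`,
#'   `significant`, `pseudo_qtn`), `pseudo_qtns`, `threshold`,
#'   `n_iterations`, `converged`, `m`.
#' @export
run_jpeg_gwas <- function(stacked, alpha = 0.01, max_iter = 10,
                          ld_r2_max = 0.7, max_candidates = 20,
                          bonferroni_denom = c("2m", "m"), n_pc = 3,
                          prune_alpha = NULL, se_type = c("whitened", "iid")) {
  bonferroni_denom <- match.arg(bonferroni_denom)
  se_type <- match.arg(se_type)
  if (is.null(stacked$B)) stacked <- build_covariates(stacked, n_pc = n_pc)
  m <- ncol(stacked$A)
  threshold <- alpha / switch(bonferroni_denom, "2m" = 2 * m, "m" = m)
  prune_alpha <- prune_alpha %||% threshold
  pseudo <- data.frame(snp = integer(0), effect = character(0))
  seen <- ""  # visited pseudo-QTN sets (starting from empty), for cycle detection
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    scan_a <- glm_scan(stacked, "additive", pseudo, se_type)
    scan_d <- glm_scan(stacked, "dominant", pseudo, se_type)
    scan <- rbind(scan_a, scan_d)
    new_pseudo <- select_pseudo_qtns(scan, stacked, threshold,
                                     ld_r2_max, max_candidates,
                                     include = pseudo,
                                     prune_alpha = prune_alpha,
                                     se_type = se_type)
    key <- paste(sort(paste(new_pseudo$snp, new_pseudo$effect)), collapse = ";")
    if (identical(key, utils::tail(seen, 1)) || key %in% seen) {
      # fixed point, or a revisited set (a cycle): further iteration cannot
      # produce new information — accept the current scan
      converged <- TRUE
      pseudo <- new_pseudo[, c("snp", "effect")]
      if (!identical(key, utils::tail(seen, 1))) {
        scan_a <- glm_scan(stacked, "additive", pseudo, se_type)
        scan_d <- glm_scan(stacked, "dominant", pseudo, se_type)
        scan <- rbind(scan_a, scan_d)
      }
      break
    }
    seen <- c(seen, key)
    pseudo <- new_pseudo[, c("snp", "effect")]
  }
  if (!converged)
    warning(sprintf("pseudo-QTN set did not stabilise after %d iterations", max_iter))
  scan$significant <- !is.na(scan$p_value) & scan$p_value < threshold
  key <- paste(scan$snp, scan$effect)
  scan$pseudo_qtn <- key %in% paste(pseudo$snp, pseudo$effect)
  structure(list(results = scan, pseudo_qtns = pseudo, threshold = threshold,
                 n_iterations = it, converged = converged, m = m,
                 alpha = alpha, bonferroni_denom = bonferroni_denom,
                 se_type = se_type),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result: %d SNPs x 2 effects, threshold %.3e, %d significant, %d pseudo-QTNs, %d iteration(s)%s\n",
              x$m, x$threshold, sum(x$results$significant), nrow(x$pseudo_qtns),
              x$n_iterations, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Merge significant SNPs into loci
#'
#' Single-linkage chaining per chromosome: two significant SNPs belong to
#' one locus if they are at most `window_bp` apart; the locus position is
#' the midpoint of the outermost members (rounded down). Effect class per
#' [classify_locus()].
#'
#' @param assoc an [run_jpeg_gwas()] result.
#' @param window_bp merge window (default 200 kb).
#' @return data.frame: `chrom`, `position`, `start`, `end`, `n_snps`,
#'   `effect_class`, plus a list-column `snps` of member SNP indices.
#' @export
merge_loci <- function(assoc, window_bp = 200000) {
  res <- assoc$results
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(0), position = integer(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), effect_class = character(0)))
  snps <- unique(sig[, c("snp", "chrom", "pos")])
  out <- NULL
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > window_bp))
    for (gid in unique(grp)) {
      mem <- s[grp == gid, , drop = FALSE]
      loc <- data.frame(chrom = ch,
                        position = (min(mem$pos) + max(mem$pos)) %/% 2,
                        start = min(mem$pos), end = max(mem$pos),
                        n_snps = nrow(mem), stringsAsFactors = FALSE)
      loc$effect_class <- classify_locus(mem$snp, assoc)
      loc$snps <- I(list(mem$snp))
      out <- rbind(out, loc)
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify a locus as additive, dominant, or both
#'
#' A locus whose member SNPs show only significant additive effects is
#' additive; only significant dominant effects, dominant; any mix of the
#' two kinds of evidence (one SNP significant in both scans, or distinct
#' additive-only and dominant-only members), both.
#'
#' @param snp_idx member SNP column indices.
#' @param assoc an [run_jpeg_gwas()] result.
#' @export
classify_locus <- function(snp_idx, assoc) {
  res <- assoc$results
  mem <- res[res$snp %in% snp_idx & res$significant, , drop = FALSE]
  if (nrow(mem) == 0) stop("locus has no significant member SNP")
  has_a <- any(mem$effect == "additive"); has_d <- any(mem$effect == "dominant")
  if (has_a && has_d) "both" else if (has_a) "additive" else "dominant"
}

#' Write per-SNP association results as TSV
#'
#' @param assoc an [run_jpeg_gwas()] result.
#' @param path output TSV.
#' @export
write_assoc <- function(assoc, path) {
  res <- assoc$results
  res$significant <- as.integer(res$significant)
  res$pseudo_qtn <- as.integer(res$pseudo_qtn)
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write merged loci as TSV
#'
#' @param loci a [merge_loci()] result.
#' @param path output TSV.
#' @export
write_loci <- function(loci, path) {
  loci$snps <- NULL
  utils::write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
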