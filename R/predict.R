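#' gBLUP prediction for unphenotyped individuals
#'
#' Solves the mixed model `y = X b + u + e` with
#' `cov(u) = sum_k sigma2_k K_k` at the supplied variance components: fixed
#' effects by generalized least squares on the training rows, and the test
#' random effects by conditional expectation
#' `u_test = G[test, train] V^{-1} (y - X b)` with
#' `V = G[train, train] + sigma2_e I`. Equivalent to the dense
#' mixed-model-equation solve.
#'
#' @param y_train training response.
#' @param X_train,X_test fixed-effect design rows for training and test.
#' @param kinships named list of kinship matrices over the combined index
#'   set (names in `a`, `d` select `sigma2_a` / `sigma2_d`).
#' @param train_idx,test_idx row indices of the kinships for training and
#'   test individuals.
#' @param vc a [estimate_varcomp()] result (or list with `sigma2_a`,
#'   `sigma2_d`, `sigma2_e`).
#' @param jitter ridge added to the diagonal of V if it is numerically
#'   singular (default 0; an informative error suggests it).
#' @return numeric predictions for the test rows.
#' @export
gblup_predict <- function(y_train, X_train, X_test, kinships,
                          train_idx, test_idx, vc, jitter = 0) {
  sig <- c(a = vc$sigma2_a %||% 0, d = vc$sigma2_d %||% 0)
  n_tr <- length(train_idx)
  G_tt <- matrix(0, n_tr, n_tr)
  G_st <- matrix(0, length(test_idx), n_tr)
  for (k in names(kinships)) {
    if (sig[[k]] == 0) next
    G_tt <- G_tt + sig[[k]] * kinships[[k]][train_idx, train_idx]
    G_st <- G_st + sig[[k]] * kinships[[k]][test_idx, train_idx, drop = FALSE]
  }
  V <- G_tt + diag(vc$sigma2_e + jitter, n_tr)
  L <- tryCatch(chol(V), error = function(e)
    stop("training covariance V is singular; pass a small `jitter` (e.g. 1e-8)"))
  Vi_y <- backsolve(L, forwardsolve(t(L), y_train))
  Vi_X <- backsolve(L, forwardsolve(t(L), X_train))
  b <- solve(crossprod(X_train, Vi_X), crossprod(X_train, Vi_y))
  resid <- y_train - X_train %*% b
  Vi_r <- backsolve(L, forwardsolve(t(L), resid))
  as.numeric(X_test %*% b + G_st %*% Vi_r)
}

#' Bundle everything cross-validation needs
#'
#' Precomputes, from genotypes only (never from phenotypes, so reusable
#' across folds without leakage): additive/dominant codings, PC scores of
#' the unique individuals, and carrier-level additive and dominance
#' kinships over parents and hybrids.
#'
#' @param parents,hybrids imputed [geno_matrix()] objects.
#' @param design a [cross_design()].
#' @param v,t named phenotype vectors (parents; hybrids).
#' @param n_pc principal components for the covariates (default 3).
#' @return An object of class `jpeg_cv_data`.
#' @export
jpeg_cv_data <- function(parents, hybrids, design, v, t, n_pc = 3) {
  A_par <- code_additive(parents)
  A_hyb <- code_additive(hybrids)
  D_hyb <- code_dominant(hybrids)
  A_all <- rbind(A_par, A_hyb)
  D_all <- rbind(matrix(0, nrow(A_par), ncol(A_par),
                        dimnames = dimnames(A_par)), D_hyb)
  structure(list(parents = parents, hybrids = hybrids, design = design,
                 v = v, t = t, n_pc = n_pc,
                 scores = pc_scores(A_all, n_pc),
                 A_hyb = A_hyb, D_hyb = D_hyb,
                 K_a = vanraden_kinship(A_all),
                 K_d = dominant_kinship(D_all)),
            class = "jpeg_cv_data")
}

#' Fit the training half of a cross-validation fold
#'
#' Rebuilds the phenotype stack from the training hybrids only — GCA and
#' heterosis are re-derived from training testcrosses, blocks are
#' re-standardized on training values — and, for the locus-based method,
#' re-runs the GWAS on the training stack so that no test-set phenotype can
#' influence locus detection.
#'
#' @param data a [jpeg_cv_data()].
#' @param train_hybrids hybrid ids in the training half.
#' @param method `"gblup"` or `"locus_based"`.
#' @param ... passed to [run_jpeg_gwas()] for the locus-based method.
#' @return list with the training `stacked` data and, for locus_based, the
#'   `assoc` result and `detected` (snp, effect) set.
#' @export
cv_training_fit <- function(data, train_hybrids,
                            method = c("gblup", "locus_based"), ...) {
  method <- match.arg(method)
  des_tr <- cross_design(data$design$hybrids[
    data$design$hybrids$hybrid_id %in% train_hybrids, , drop = FALSE])
  t_tr <- data$t[train_hybrids]
  g_tr <- derive_gca(t_tr, des_tr)
  h_tr <- derive_heterosis(t_tr, data$v, des_tr)
  stacked <- standardize_and_stack(v = data$v, t = t_tr, g = g_tr, h = h_tr,
                                   design = des_tr, parents = data$parents,
                                   hybrids = data$hybrids)
  stacked <- build_covariates(stacked, n_pc = data$n_pc, scores = data$scores)
  out <- list(stacked = stacked, method = method)
  if (method == "locus_based") {
    assoc <- run_jpeg_gwas(stacked, ...)
    sig <- assoc$results[assoc$results$significant, c("snp", "effect")]
    out$assoc <- assoc
    out$detected <- unique(sig)
  }
  out
}

# fixed-effect rows for test hybrids, matching the training B's columns
test_design_rows_ <- function(data, fit, test_hybrids) {
  B <- fit$stacked$B
  scores <- data$scores[test_hybrids, , drop = FALSE]
  fem <- stats::setNames(data$design$hybrids$female_id, data$design$hybrids$hybrid_id)
  cols <- lapply(colnames(B), function(cn) {
    if (cn == "intercept") rep(1, length(test_hybrids))
    else if (cn == "block_T") rep(1, length(test_hybrids))
    else if (grepl("^block_", cn)) rep(0, length(test_hybrids))
    else if (grepl("^PC", cn)) scores[, cn]
    else if (grepl("^female_T_", cn))  # test rows are testcross observations
      as.numeric(fem[test_hybrids] == sub("^female_T_", "", cn))
    else if (grepl("^female_H_", cn)) rep(0, length(test_hybrids))
    else stop(sprintf("unknown covariate column '%s'", cn))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- colnames(B)
  X
}

# append detected-locus columns to train and test fixed designs, dropping
# columns collinear on the *training* rows (the test rows must not decide)
detected_designs_ <- function(data, fit, test_hybrids) {
  Xtr <- fit$stacked$B
  Xte <- test_design_rows_(data, fit, test_hybrids)
  det <- fit$detected
  if (!is.null(det) && nrow(det)) {
    tr_cols <- pseudo_columns(fit$stacked, det)
    hyb_idx <- match(test_hybrids, data$hybrids$samples)
    te_cols <- vapply(seq_len(nrow(det)), function(k) {
      M <- if (det$effect[k] == "additive") data$A_hyb else data$D_hyb
      M[hyb_idx, det$snp[k]]
    }, numeric(length(test_hybrids)))
    te_cols <- matrix(te_cols, nrow = length(test_hybrids),
                      dimnames = list(NULL, colnames(tr_cols)))
    Xtr <- cbind(Xtr, tr_cols)
    Xte <- cbind(Xte, te_cols)
    qx <- qr(Xtr)
    if (qx$rank < ncol(Xtr)) {
      keep <- qx$pivot[seq_len(qx$rank)]
      warning(sprintf("dropping %d collinear detected-locus column(s)",
                      ncol(Xtr) - qx$rank))
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
  }
  list(train = Xtr, test = Xte)
}

#' Predict the test half of a fold
#'
#' Variance components are (re-)estimated on the training rows — additive
#' kinship only for gBLUP; additive plus dominance kinships, with the
#' detected additive and dominant SNP columns as extra fixed effects, for
#' the locus-based method — then test-hybrid performance is predicted by
#' [gblup_predict()].
#'
#' @param data a [jpeg_cv_data()].
#' @param fit a [cv_training_fit()] result.
#' @param test_hybrids hybrid ids in the test half.
#' @return list with `predicted`, `observed` (raw testcross phenotypes),
#'   `r2` (squared Pearson correlation), and the fold's `vc`.
#' @export
cv_predict_fold <- function(data, fit, test_hybrids) {
  des <- detected_designs_(data, fit, test_hybrids)
  carriers <- c(fit$stacked$meta$row_sample, test_hybrids)
  tr <- seq_len(nrow(des$train)); te <- nrow(des$train) + seq_along(test_hybrids)
  kin <- if (fit$method == "gblup") {
    list(a = data$K_a[carriers, carriers])
  } else {
    list(a = data$K_a[carriers, carriers], d = data$K_d[carriers, carriers])
  }
  vc <- if (fit$method == "gblup") {
    estimate_varcomp(fit$stacked$y, des$train, K_a = kin$a[tr, tr])
  } else {
    estimate_varcomp(fit$stacked$y, des$train, K_a = kin$a[tr, tr],
                     K_d = kin$d[tr, tr])
  }
  pred <- gblup_predict(fit$stacked$y, des$train, des$test, kin, tr, te, vc,
                        jitter = 1e-8)
  obs <- unname(data$t[test_hybrids])
  ok <- !is.na(obs)
  r2 <- if (sum(ok) >= 3 && stats::sd(obs[ok]) > 0)
    stats::cor(pred[ok], obs[ok])^2 else NA_real_
  list(predicted = pred, observed = obs, r2 = r2, vc = vc)
}

#' Repeated twofold cross-validation of hybrid prediction
#'
#' Per repeat the hybrids are randomly split into two (near-)equal halves;
#' each half serves once as the test set while all inbred parents plus the
#' other half train the model. For the locus-based method the GWAS is
#' re-run on the training population of every fold. Reports the squared
#' Pearson correlation between predicted and observed testcross phenotypes
#' per fold and its mean.
#'
#' @param data a [jpeg_cv_data()].
#' @param method `"gblup"` or `"locus_based"`.
#' @param n_repeats number of random splits (default 100).
#' @param seed RNG seed (recorded in the result).
#' @param h2_total optional total heritability for the `ratio_to_h2`
#'   summary.
#' @param ... passed to [run_jpeg_gwas()] for the locus-based method.
#' @return An object of class `cv_result`: `folds` (repeat, fold, n_test,
#'   r2), `mean_r2`, `sd_r2`, `ratio_to_h2`, `method`, `seed`.
#' @export
cross_validate <- function(data, method = c("gblup", "locus_based"),
                           n_repeats = 100, seed = 1, h2_total = NULL, ...) {
  method <- match.arg(method)
  hyb <- data$design$hybrids$hybrid_id
  if (length(hyb) < 20) stop("need at least 20 hybrids for cross-validation")
  set.seed(seed)
  rows <- NULL
  for (rep_i in seq_len(n_repeats)) {
    perm <- sample(hyb)
    half <- floor(length(hyb) / 2)
    splits <- list(perm[seq_len(half)], perm[-seq_len(half)])
    for (fold_i in 1:2) {
      test_h <- splits[[fold_i]]
      train_h <- setdiff(hyb, test_h)
      fit <- cv_training_fit(data, train_h, method, ...)
      res <- cv_predict_fold(data, fit, test_h)
      if (is.na(res$r2)) {
        warning(sprintf("repeat %d fold %d skipped: no test-set variance",
                        rep_i, fold_i))
        next
      }
      rows <- rbind(rows, data.frame(rep = rep_i, fold = fold_i,
                                     n_test = length(test_h), r2 = res$r2))
    }
  }
  mean_r2 <- mean(rows$r2)
  structure(list(folds = rows, mean_r2 = mean_r2, sd_r2 = stats::sd(rows$r2),
                 ratio_to_h2 = if (is.null(h2_total)) NA_real_ else mean_r2 / h2_total,
                 method = method, n_repeats = n_repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): mean R2 = %.3f (sd %.3f) over %d folds, seed %d\n",
              x$method, x$mean_r2, x$sd_r2, nrow(x$folds), x$seed))
  invisible(x)
}
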