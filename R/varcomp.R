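#' VanRaden additive kinship
#'
#' `K = Z Z' / (2 * sum_j p_j (1 - p_j))` with `Z` the column-centred dosage
#' matrix (`A - 2p`) and `p_j` the mean dosage / 2 of SNP j over the input
#' samples. Frequencies are computed on exactly the samples the kinship is
#' built for.
#'
#' @param A additive dosage matrix (samples x SNPs, values in \[0, 2\]),
#'   e.g. from [code_additive()], with rownames = sample ids.
#' @return symmetric n x n matrix with `kind` attribute `"additive"`.
#' @export
vanraden_kinship <- function(A) {
  p <- colMeans(A) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= .Machine$double.eps)
    stop("all SNPs monomorphic in this sample set; kinship undefined")
  Z <- sweep(A, 2, 2 * p)
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(rownames(A), rownames(A))
  structure(K, kind = "additive", denominator = denom)
}

#' Dominance kinship
#'
#' The VanRaden pattern applied to centred heterozygosity codes:
#' `K_d = W W' / sum_j h_j (1 - h_j)` with `W = D - h` column-centred and
#' `h_j` the heterozygote frequency of SNP j over the input samples.
#'
#' @param D dominant (0/1 heterozygosity) matrix, e.g. [code_dominant()].
#' @return symmetric n x n matrix with `kind` attribute `"dominant"`.
#' @export
dominant_kinship <- function(D) {
  h <- colMeans(D)
  denom <- sum(h * (1 - h))
  if (denom <= .Machine$double.eps)
    stop("no heterozygosity variance in this sample set; dominance kinship undefined")
  W <- sweep(D, 2, h)
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(rownames(D), rownames(D))
  structure(K, kind = "dominant", denominator = denom)
}

#' Write a kinship matrix as TSV
#'
#' @param K kinship matrix with sample-id dimnames.
#' @param path output TSV (square, header = sample ids).
#' @export
write_kinship <- function(K, path) {
  utils::write.table(as.data.frame(K), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# -2 restricted log-likelihood (up to the usual additive constant) of
# y = Xb + u + e with cov(y) = V; computed from a Cholesky of V.
minus2_rll_ <- function(y, X, V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  Vi_y <- backsolve(L, forwardsolve(t(L), y))
  Vi_X <- backsolve(L, forwardsolve(t(L), X))
  XtViX <- crossprod(X, Vi_X)
  b <- solve(XtViX, crossprod(X, Vi_y))
  yPy <- sum(y * Vi_y) - sum(crossprod(Vi_X, y) * b)
  2 * sum(log(diag(L))) + determinant(XtViX, logarithm = TRUE)$modulus + yPy
}

#' REML variance components and heritabilities
#'
#' Fits `y = B b + u_a (+ u_d) + e` with `cov(u_a) = K_a sigma2_a`,
#' `cov(u_d) = K_d sigma2_d`, `cov(e) = I sigma2_e` by restricted maximum
#' likelihood. With a single kinship the restricted likelihood is profiled
#' on the variance ratio over the kinship's eigenbasis (fast and robust);
#' with two kinships the -2 restricted log-likelihood is minimised over the
#' log-variances by bounded quasi-Newton from a moment-based start.
#' Components are constrained nonnegative (log-parameterisation with a hard
#' floor). Heritabilities are each component over the total variance
#' including the residual, and `h2_total = h2_a + h2_d`.
#'
#' @param y numeric response.
#' @param B fixed-effect design (include an intercept); collinear columns
#'   are dropped.
#' @param K_a additive kinship (or `NULL`).
#' @param K_d dominance kinship (or `NULL`). At least one kinship required.
#' @param max_eval optimiser evaluation budget (default 400).
#' @return An object of class `varcomp`: `sigma2_a`, `sigma2_d`, `sigma2_e`,
#'   `h2_a`, `h2_d`, `h2_total`, `minus2_rll`, `converged`.
#' @export
estimate_varcomp <- function(y, B, K_a = NULL, K_d = NULL, max_eval = 400) {
  if (is.null(K_a) && is.null(K_d)) stop("supply at least one kinship")
  X <- drop_collinear(as.matrix(B), warn = FALSE)
  n <- length(y)
  stopifnot(nrow(X) == n)
  Ks <- Filter(Negate(is.null), list(a = K_a, d = K_d))
  lapply(Ks, function(K) stopifnot(nrow(K) == n, ncol(K) == n))

  if (length(Ks) == 1L) {
    fit <- reml_single_(y, X, Ks[[1]])
    names(fit$sigma2)[1] <- names(Ks)[1]
  } else {
    fit <- reml_multi_(y, X, Ks, max_eval)
  }
  s <- fit$sigma2  # named: one per kinship + "e"
  sigma2_a <- if ("a" %in% names(s)) unname(s["a"]) else 0
  sigma2_d <- if ("d" %in% names(s)) unname(s["d"]) else 0
  tot <- sigma2_a + sigma2_d + unname(s["e"])
  structure(list(sigma2_a = sigma2_a, sigma2_d = sigma2_d,
                 sigma2_e = unname(s["e"]),
                 h2_a = sigma2_a / tot, h2_d = sigma2_d / tot,
                 h2_total = (sigma2_a + sigma2_d) / tot,
                 minus2_rll = fit$minus2_rll, converged = fit$converged),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp: sigma2_a=%.4g sigma2_d=%.4g sigma2_e=%.4g | h2_a=%.3f h2_d=%.3f h2_total=%.3f%s\n",
              x$sigma2_a, x$sigma2_d, x$sigma2_e, x$h2_a, x$h2_d, x$h2_total,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# Single-kinship REML: rotate into the kinship eigenbasis so V is diagonal,
# profile sigma2_e out, and optimise the 1-D ratio delta = sigma2_g/sigma2_e.
reml_single_ <- function(y, X, K) {
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  p <- ncol(X)
  obj <- function(logd) {
    d <- exp(logd)
    w <- d * lam + 1          # V = sigma2_e * diag(w)
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    b <- solve(XtWX, crossprod(Xw, yt))
    rss <- sum(yt * (yt / w)) - sum(crossprod(Xw, yt) * b)
    s2e <- rss / (length(yt) - p)
    # full -2rll at the profiled sigma2_e
    length(yt) * log(s2e) + sum(log(w)) +
      determinant(XtWX / s2e, logarithm = TRUE)$modulus + (length(yt) - p)
  }
  op <- stats::optimize(obj, interval = c(-25, 25), tol = 1e-9)
  d <- exp(op$minimum)
  w <- d * lam + 1
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  b <- solve(XtWX, crossprod(Xw, yt))
  rss <- sum(yt * (yt / w)) - sum(crossprod(Xw, yt) * b)
  s2e <- rss / (length(yt) - p)
  sigma2 <- c(g = d * s2e, e = s2e)
  list(sigma2 = sigma2, minus2_rll = as.numeric(op$objective), converged = TRUE)
}

# Two-kinship REML: minimise -2rll over log variances.
reml_multi_ <- function(y, X, Ks, max_eval) {
  n <- length(y)
  r <- stats::lm.fit(X, y)$residuals
  v0 <- max(stats::var(r), 1e-8)
  start <- log(c(rep(v0 / (length(Ks) + 1), length(Ks)), v0 / 2))
  obj <- function(theta) {
    s <- exp(theta)
    V <- diag(s[length(s)], n)
    for (k in seq_along(Ks)) V <- V + s[k] * Ks[[k]]
    val <- minus2_rll_(y, X, V)
    if (is.null(val) || !is.finite(val)) return(1e10)
    as.numeric(val)
  }
  op <- stats::optim(start, obj, method = "L-BFGS-B",
                     lower = rep(log(v0) - 20, length(start)),
                     upper = rep(log(v0) + 12, length(start)),
                     control = list(maxit = max_eval, factr = 1e8))
  s <- exp(op$par)
  sigma2 <- stats::setNames(s, c(names(Ks), "e"))
  # a component at the floor is numerically zero
  sigma2[sigma2 <= exp(log(v0) - 19.5)] <- 0
  list(sigma2 = sigma2, minus2_rll = op$value, converged = op$convergence == 0)
}
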