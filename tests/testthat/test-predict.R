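toy_system <- function(seed = 42, n = 20, m = 200, h2 = 0.7) {
  set.seed(seed)
  # a generic positive-definite kinship (VanRaden matrices are singular by
  # centering, which leaves the MME reference undefined)
  M <- matrix(rnorm(n * m), n, m)
  K <- tcrossprod(M) / m
  dimnames(K) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  X <- cbind(1, rnorm(n))
  u <- t(chol(K)) %*% rnorm(n) * sqrt(h2)
  y <- as.numeric(X %*% c(1, 0.5) + u + rnorm(n, 0, sqrt(1 - h2)))
  list(K = K, X = X, y = y)
}

test_that("gBLUP matches a dense mixed-model-equation solve", {
  s <- toy_system()
  vc <- list(sigma2_a = 0.7, sigma2_d = 0, sigma2_e = 0.3)
  tr <- 1:15; te <- 16:20
  pred <- gblup_predict(s$y[tr], s$X[tr, ], s$X[te, ], list(a = s$K), tr, te, vc)
  lam <- vc$sigma2_e / vc$sigma2_a
  Ki <- solve(s$K)
  Z <- diag(20)[tr, ]
  LHS <- rbind(cbind(crossprod(s$X[tr, ]), crossprod(s$X[tr, ], Z)),
               cbind(crossprod(Z, s$X[tr, ]), crossprod(Z) + lam * Ki))
  RHS <- c(crossprod(s$X[tr, ], s$y[tr]), crossprod(Z, s$y[tr]))
  sol <- solve(LHS, RHS)
  mme <- as.numeric(s$X[te, ] %*% sol[1:2] + sol[2 + te])
  expect_equal(pred, mme, tolerance = 1e-8)
})

test_that("an identity kinship predicts the fixed-effect part only", {
  s <- toy_system(seed = 3)
  vc <- list(sigma2_a = 0.5, sigma2_d = 0, sigma2_e = 0.5)
  tr <- 1:15; te <- 16:20
  pred <- gblup_predict(s$y[tr], s$X[tr, ], s$X[te, ], list(a = diag(20)),
                        tr, te, vc)
  V <- vc$sigma2_a * diag(15) + vc$sigma2_e * diag(15)
  b <- solve(crossprod(s$X[tr, ], solve(V, s$X[tr, ])),
             crossprod(s$X[tr, ], solve(V, s$y[tr])))
  expect_equal(pred, as.numeric(s$X[te, ] %*% b), tolerance = 1e-8)
})

test_that("an empty detected set reduces locus-based prediction to gBLUP", {
  sim <- small_dataset(seed = 31, n_males = 15, n_females = 2, n_snps = 120)
  dat <- jpeg_cv_data(sim$parents, sim$hybrids, sim$design, sim$v, sim$t)
  hyb <- sim$design$hybrids$hybrid_id
  train <- hyb[1:20]; test <- hyb[21:30]
  fit <- quiet(cv_training_fit(dat, train, "gblup"))
  fit$method <- "locus_based"
  fit$detected <- data.frame(snp = integer(0), effect = character(0))
  out_locus <- quiet(cv_predict_fold(dat, fit, test))
  # manual gBLUP with the same two kinships over the same rows
  des <- jpegwas:::detected_designs_(dat, fit, test)
  carriers <- c(fit$stacked$meta$row_sample, test)
  kin <- list(a = dat$K_a[carriers, carriers], d = dat$K_d[carriers, carriers])
  tr <- seq_len(nrow(des$train)); te <- nrow(des$train) + seq_along(test)
  vc <- estimate_varcomp(fit$stacked$y, des$train,
                         K_a = kin$a[tr, tr], K_d = kin$d[tr, tr])
  manual <- gblup_predict(fit$stacked$y, des$train, des$test, kin, tr, te, vc,
                          jitter = 1e-8)
  expect_equal(out_locus$predicted, manual, tolerance = 1e-10)
})

test_that("duplicated detected columns are dropped without changing predictions", {
  sim <- small_dataset(seed = 32, n_males = 15, n_females = 2, n_snps = 120)
  dat <- jpeg_cv_data(sim$parents, sim$hybrids, sim$design, sim$v, sim$t)
  hyb <- sim$design$hybrids$hybrid_id
  train <- hyb[1:20]; test <- hyb[21:30]
  fit <- quiet(cv_training_fit(dat, train, "gblup"))
  fit$method <- "locus_based"
  fit$detected <- data.frame(snp = c(5L, 8L), effect = "additive")
  p1 <- quiet(cv_predict_fold(dat, fit, test))
  fit$detected <- data.frame(snp = c(5L, 8L, 5L), effect = "additive")
  p2 <- suppressWarnings(quiet(cv_predict_fold(dat, fit, test)))
  expect_equal(p1$predicted, p2$predicted, tolerance = 1e-8)
})

test_that("cross-validation is deterministic and splits halves correctly", {
  sim <- small_dataset(seed = 33, n_males = 11, n_females = 2, n_snps = 100,
                       n_qtl_dom = 0, h2_d = 0)
  # 22 hybrids: even split; drop one for an odd count below
  dat <- jpeg_cv_data(sim$parents, sim$hybrids, sim$design, sim$v, sim$t)
  cv1 <- quiet(cross_validate(dat, "gblup", n_repeats = 2, seed = 7))
  cv2 <- quiet(cross_validate(dat, "gblup", n_repeats = 2, seed = 7))
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(unique(cv1$folds$n_test), 11)
  # odd number of hybrids: halves of 10 and 11, both tested
  des_odd <- cross_design(sim$design$hybrids[-1, ])
  t_odd <- sim$t[des_odd$hybrids$hybrid_id]
  dat_odd <- jpeg_cv_data(sim$parents, sim$hybrids, des_odd, sim$v, t_odd)
  cv3 <- quiet(cross_validate(dat_odd, "gblup", n_repeats = 1, seed = 7))
  expect_equal(sort(cv3$folds$n_test), c(10, 11))
  expect_error(cross_validate(dat, "gblup", n_repeats = 1, seed = 1,
                              h2_total = NULL), NA)
})

test_that("training output is bit-identical when test-half phenotypes are removed", {
  sim <- small_dataset(seed = 34, n_males = 20, n_females = 2, n_snps = 200,
                       n_qtl_add = 1, n_qtl_dom = 0, h2_a = 0.6, h2_d = 0)
  hyb <- sim$design$hybrids$hybrid_id
  set.seed(1); test_h <- sample(hyb, 20)
  train_h <- setdiff(hyb, test_h)
  dat_full <- jpeg_cv_data(sim$parents, sim$hybrids, sim$design, sim$v, sim$t)
  t_blank <- sim$t; t_blank[test_h] <- NA
  dat_blank <- jpeg_cv_data(sim$parents, sim$hybrids, sim$design, sim$v, t_blank)
  f1 <- quiet(cv_training_fit(dat_full, train_h, "locus_based"))
  f2 <- quiet(cv_training_fit(dat_blank, train_h, "locus_based"))
  expect_identical(f1$stacked$y, f2$stacked$y)
  expect_identical(f1$detected, f2$detected)
  expect_identical(f1$stacked$B, f2$stacked$B)
})

test_that("a noise-only trait cross-validates to near-zero R2", {
  sim <- small_dataset(seed = 35, n_males = 40, n_females = 2, n_snps = 150,
                       n_qtl_add = 0, n_qtl_dom = 0, h2_a = 0, h2_d = 0)
  dat <- jpeg_cv_data(sim$parents, sim$hybrids, sim$design, sim$v, sim$t)
  cv <- quiet(cross_validate(dat, "gblup", n_repeats = 5, seed = 2))
  expect_lt(cv$mean_r2, 0.05)
})
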