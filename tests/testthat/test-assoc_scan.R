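test_that("scan coefficients and p-values match lm() on a V+T stack", {
  # with only primary blocks stacked the noise loadings are the identity,
  # so the whitened test must agree with lm() exactly
  sim <- small_dataset(seed = 21, n_snps = 40)
  st <- stack_of(sim, blocks = c("V", "T"))
  sa <- glm_scan(st, "additive")
  sa_iid <- glm_scan(st, "additive", se_type = "iid")
  for (j in c(1, 7, 23)) {
    fit <- summary(lm(st$y ~ st$B + st$A[, j] - 1))$coefficients
    k <- nrow(fit)
    expect_equal(sa_iid$estimate[j], fit[k, 1], tolerance = 1e-10)
    expect_equal(sa_iid$p_value[j], fit[k, 4], tolerance = 1e-8)
    expect_equal(sa$estimate[j], fit[k, 1], tolerance = 1e-10)
    expect_equal(sa$p_value[j], fit[k, 4], tolerance = 1e-8)
  }
})

test_that("a marker that equals the response is a perfect fit; constants are flagged NA", {
  sim <- small_dataset(seed = 22, n_snps = 30)
  st <- stack_of(sim, blocks = c("V", "T"))
  j <- 5
  st$y <- as.numeric(scale(st$A[, j]))  # response = marker, rescaled
  out <- glm_scan(st, "additive", se_type = "iid")
  expect_lt(out$p_value[j], 1e-12)
  st2 <- stack_of(sim, blocks = c("V", "T"))
  st2$A[, 3] <- 2
  out2 <- glm_scan(st2, "additive")
  expect_true(is.na(out2$p_value[3]))
  poly <- apply(st2$A, 2, sd) > 0
  expect_false(anyNA(out2$p_value[poly]))
})

test_that("inbred-only stacks yield an all-NA dominant scan", {
  sim <- small_dataset(seed = 23)
  st <- stack_of(sim, blocks = c("V", "G"))
  out <- glm_scan(st, "dominant")
  expect_true(all(is.na(out$p_value)))
  poly <- apply(st$A, 2, sd) > 0
  expect_false(anyNA(glm_scan(st, "additive")$p_value[poly]))
})

test_that("self-exclusion retests a pseudo-QTN without its own columns", {
  sim <- small_dataset(seed = 24, n_snps = 50)
  st <- stack_of(sim)
  pseudo <- data.frame(snp = c(4L, 9L), effect = c("additive", "additive"))
  out <- glm_scan(st, "additive", pseudo, se_type = "iid")
  # manual: marker 4 tested with covariates B + marker 9 (not marker 4)
  fit <- summary(lm(st$y ~ st$B + st$A[, 9] + st$A[, 4] - 1))$coefficients
  expect_equal(out$estimate[4], fit[nrow(fit), 1], tolerance = 1e-10)
  expect_equal(out$p_value[4], fit[nrow(fit), 4], tolerance = 1e-8)
})

test_that("duplicated significant columns are pruned by the LD exclusion", {
  sim <- small_dataset(seed = 25, n_snps = 60, n_qtl_add = 0, n_qtl_dom = 0,
                       h2_a = 0, h2_d = 0)
  st <- stack_of(sim)
  st$A[, 12] <- st$A[, 11]  # identical columns
  set.seed(2)
  st$y <- as.numeric(scale(st$A[, 11] + rnorm(length(st$y), 0, 0.3)))
  scan <- rbind(glm_scan(st, "additive"), glm_scan(st, "dominant"))
  expect_lt(scan$p_value[11], 1e-7)
  sel <- select_pseudo_qtns(scan, st, threshold = 1e-7)
  expect_true(11 %in% sel$snp)
  expect_false(12 %in% sel$snp)
  # nothing significant -> empty selection
  scan$p_value <- pmax(scan$p_value, 0.5, na.rm = TRUE)
  expect_equal(nrow(select_pseudo_qtns(scan, st, threshold = 1e-8)), 0L)
})

test_that("the Bonferroni threshold counts both effect scans by default", {
  sim <- small_dataset(seed = 26, n_snps = 80)
  st <- stack_of(sim)
  res <- quiet(run_jpeg_gwas(st, alpha = 0.01))
  expect_equal(res$threshold, 0.01 / (2 * 80))
  res_m <- quiet(run_jpeg_gwas(st, alpha = 0.01, bonferroni_denom = "m"))
  expect_equal(res_m$threshold, 0.01 / 80)
  expect_true(all(res$results$p_value[res$results$significant] < res$threshold))
})

test_that("merge_loci chains significant SNPs within the window per chromosome", {
  fake <- function(chrom, pos, effects) {
    n <- length(pos)
    structure(list(results = data.frame(
      snp = rep(seq_len(n), 2),
      chrom = rep(chrom, 2 * n), pos = rep(pos, 2),
      effect = rep(c("additive", "dominant"), each = n),
      estimate = 0, t_stat = 0, p_value = 1e-12,
      significant = c(effects$additive, effects$dominant)),
      threshold = 1e-9), class = "assoc_result")
  }
  a <- fake(rep("chr01", 2), c(100000, 250000),
            list(additive = c(TRUE, TRUE), dominant = c(FALSE, FALSE)))
  loci <- merge_loci(a)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$position, 175000)
  expect_equal(loci$effect_class, "additive")
  # single-linkage chaining: adjacent gaps 180 kb and 170 kb join one locus
  b <- fake(rep("chr01", 3), c(100000, 280000, 450000),
            list(additive = rep(TRUE, 3), dominant = rep(FALSE, 3)))
  locb <- merge_loci(b)
  expect_equal(nrow(locb), 1L)
  expect_equal(locb$position, 275000)
  # same positions on different chromosomes stay separate
  c2 <- fake(c("chr01", "chr02"), c(100000, 100000),
             list(additive = c(TRUE, TRUE), dominant = c(FALSE, FALSE)))
  expect_equal(nrow(merge_loci(c2)), 2L)
})

test_that("locus classification follows the additive/dominant/both rule", {
  mixed <- structure(list(results = data.frame(
    snp = c(1L, 2L, 1L, 2L),
    chrom = "chr01", pos = c(1e5, 1.5e5, 1e5, 1.5e5),
    effect = c("additive", "additive", "dominant", "dominant"),
    estimate = 0, t_stat = 0, p_value = 1e-12,
    significant = c(TRUE, FALSE, FALSE, TRUE))), class = "assoc_result")
  # one additive-only and one dominant-only member merge into a "both" locus
  loci <- merge_loci(mixed)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$effect_class, "both")
  expect_equal(classify_locus(1L, mixed), "additive")
  expect_equal(classify_locus(2L, mixed), "dominant")
  expect_error(classify_locus(99L, mixed), "no significant")
})

test_that("a planted additive signal is recovered end to end", {
  sim <- small_dataset(seed = 28, n_males = 40, n_females = 3, n_snps = 400,
                       n_qtl_add = 1, n_qtl_dom = 0, h2_a = 0.6, h2_d = 0)
  st <- stack_of(sim)
  res <- quiet(run_jpeg_gwas(st))
  qtl <- sim$truth$qtl$snp[1]
  sig_add <- res$results[res$results$effect == "additive" & res$results$significant, ]
  expect_true(qtl %in% sig_add$snp)
  expect_true(res$converged)
  loci <- merge_loci(res)
  expect_true(locus_hit(loci, sim$truth$qtl$chrom[1], sim$truth$qtl$pos[1]))
})
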