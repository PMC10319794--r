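random_pheno_design <- function(seed, n_males = 8, n_females = 3, miss = 0.1) {
  set.seed(seed)
  des <- factorial_design(sprintf("m%d", 1:n_males), sprintf("f%d", 1:n_females))
  t <- stats::setNames(rnorm(nrow(des$hybrids), 10, 3), des$hybrids$hybrid_id)
  v <- stats::setNames(rnorm(n_males + n_females, 8, 2),
                       c(sprintf("m%d", 1:n_males), sprintf("f%d", 1:n_females)))
  t[runif(length(t)) < miss] <- NA
  v[runif(length(v)) < miss] <- NA
  list(des = des, t = t, v = v)
}

test_that("derive_gca equals brute-force recomputation on random tables", {
  for (seed in 1:25) {
    d <- random_pheno_design(seed)
    g <- derive_gca(d$t, d$des)
    grand <- mean(d$t, na.rm = TRUE)
    for (m in d$des$males) {
      own <- d$t[d$des$hybrids$hybrid_id[d$des$hybrids$male_id == m]]
      expected <- if (all(is.na(own))) NA_real_ else mean(own, na.rm = TRUE) - grand
      expect_equal(unname(g[m]), expected, tolerance = 1e-12)
    }
  }
})

test_that("testcross-count-weighted GCA values sum to zero", {
  for (seed in 1:10) {
    d <- random_pheno_design(seed, miss = 0)
    g <- derive_gca(d$t, d$des)
    k <- table(d$des$hybrids$male_id)[names(g)]
    expect_equal(sum(g * as.numeric(k)), 0, tolerance = 1e-9)
  }
  # identical testcross values give GCA exactly zero
  d <- random_pheno_design(3, miss = 0)
  d$t[] <- 7
  expect_equal(unname(derive_gca(d$t, d$des)), rep(0, 8))
})

test_that("derive_heterosis equals the mid-parent formula and propagates missing", {
  for (seed in 1:25) {
    d <- random_pheno_design(seed)
    h <- derive_heterosis(d$t, d$v, d$des)
    hy <- d$des$hybrids
    expected <- unname(d$t[hy$hybrid_id] - (d$v[hy$male_id] + d$v[hy$female_id]) / 2)
    expect_equal(unname(h), expected)
  }
  d <- random_pheno_design(2, miss = 0)
  d$v["f1"] <- NA
  h <- derive_heterosis(d$t, d$v, d$des)
  f1_hybrids <- d$des$hybrids$hybrid_id[d$des$hybrids$female_id == "f1"]
  expect_true(all(is.na(h[f1_hybrids])))
  expect_true(!anyNA(h[setdiff(names(h), f1_hybrids)]))
  # a testcross equal to its mid-parent has zero heterosis
  d$v[] <- 4; d$t[] <- 4
  expect_equal(max(abs(derive_heterosis(d$t, d$v, d$des))), 0)
})

test_that("standardization is per block with the documented sd conventions", {
  x <- c(a = 2, b = 4, c = 6)
  sim <- small_dataset(seed = 3, n_snps = 40, n_males = 3, n_females = 2)
  v <- stats::setNames(x[1:3], sim$parents$samples[1:3])
  # extend to all parents so the genotype lookup succeeds
  v <- c(v, stats::setNames(c(1, 9), sim$parents$samples[4:5]))
  st_s <- standardize_and_stack(v = v[sim$parents$samples[1:3]], t = sim$t,
                                g = NULL, h = NULL, design = sim$design,
                                parents = sim$parents, hybrids = sim$hybrids,
                                blocks = c("V", "T"))
  yv <- st_s$y[st_s$meta$block == "V"]
  expect_equal(yv, c(-1, 0, 1))
  st_p <- standardize_and_stack(v = v[sim$parents$samples[1:3]], t = sim$t,
                                g = NULL, h = NULL, design = sim$design,
                                parents = sim$parents, hybrids = sim$hybrids,
                                blocks = c("V", "T"), sd_type = "population")
  expect_equal(st_p$y[st_p$meta$block == "V"], c(-2, 0, 2) / sqrt(8 / 3),
               tolerance = 1e-12)
  expect_error(standardize_and_stack(v = stats::setNames(rep(1, 3), names(v)[1:3]),
                                     t = sim$t, g = NULL, h = NULL,
                                     design = sim$design, parents = sim$parents,
                                     hybrids = sim$hybrids, blocks = c("V", "T")),
               "zero variance")
})

test_that("the stacked system has aligned blocks with zero dominant rows for V and G", {
  sim <- small_dataset(seed = 7)
  st <- stack_of(sim)
  expect_equal(length(st$y), nrow(st$A))
  expect_equal(nrow(st$A), nrow(st$D))
  expect_equal(nrow(st$B), length(st$y))
  for (b in unique(st$meta$block)) {
    yb <- st$y[st$meta$block == b]
    expect_equal(mean(yb), 0, tolerance = 1e-12)
    expect_equal(sd(yb), 1, tolerance = 1e-12)
  }
  vg <- st$meta$block %in% c("V", "G")
  expect_true(all(st$D[vg, ] == 0))
  # A and D rows of a G row equal those of the matching V row
  ig <- which(st$meta$block == "G")[1]
  iv <- which(st$meta$block == "V" & st$meta$row_sample == st$meta$row_sample[ig])
  expect_equal(st$A[ig, ], st$A[iv, ])
  # block order is V, T, G, H
  expect_equal(unique(st$meta$block), c("V", "T", "G", "H"))
})

test_that("covariates contain intercept, block terms, PCs, and per-block female dummies", {
  sim <- small_dataset(seed = 8, n_females = 2)
  st <- stack_of(sim)
  cn <- colnames(st$B)
  expect_true("intercept" %in% cn)
  expect_equal(sum(grepl("^PC", cn)), 3)
  expect_equal(sum(grepl("^female_T_", cn)), 1)  # one per block absorbed by the block intercept
  expect_equal(sum(grepl("^female_H_", cn)), 1)
  # V rows have all female dummies zero
  vrows <- st$meta$block == "V"
  expect_true(all(st$B[vrows, grepl("^female_", cn)] == 0))
  # a V row and its G row share PC scores (same genotype carrier)
  ig <- which(st$meta$block == "G")[1]
  iv <- which(st$meta$block == "V" & st$meta$row_sample == st$meta$row_sample[ig])
  expect_equal(st$B[ig, grepl("^PC", cn)], st$B[iv, grepl("^PC", cn)])
})

test_that("PCA scores are equal for genotypically identical individuals", {
  sim <- small_dataset(seed = 10, n_snps = 50)
  A <- code_additive(sim$parents)
  A2 <- rbind(A, dup = A[1, ])
  rownames(A2) <- c(rownames(A), "dup")
  sc <- pc_scores(A2, 3)
  expect_equal(sc["dup", ], sc[rownames(A)[1], ])
  expect_error(pc_scores(A[1:3, ], 5), "exceeds")
})
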