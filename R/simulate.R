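#' Simulation configuration for a diallel testcross study
#'
#' Defaults emulate the study design the pipeline targets: 113 male inbred
#' varieties crossed with 5 female testers (full factorial, 565 hybrids),
#' fully homozygous parents, SNP minor-allele frequencies uniform on
#' \[0.05, 0.5\], and a hybrid trait controlled by planted additive and
#' dominant QTLs at target heritabilities 0.4 and 0.2.
#'
#' @param n_males,n_females parent counts (defaults 113 and 5).
#' @param n_snps total SNP count (default 5000).
#' @param n_chrom chromosomes (default 12, a rice genome).
#' @param chrom_length_bp chromosome length (default 25 Mb).
#' @param maf_range range of the uniform allele-frequency spectrum
#'   (default c(0.05, 0.5)).
#' @param n_qtl_add,n_qtl_dom planted additive and dominant-only QTL counts
#'   (defaults 5 and 3).
#' @param h2_a,h2_d target additive and dominant heritabilities among
#'   hybrids (defaults 0.4 and 0.2); must sum below 1.
#' @param ld_block_size SNPs per correlated block (1 = independent SNPs).
#' @param adj_r2 target adjacent-pair r-squared within an LD block
#'   (default 0.8).
#' @param n_subpop number of subpopulations (0 = none); allele frequencies
#'   per subpopulation follow the Balding-Nichols model at `fst`.
#' @param fst subpopulation differentiation (default 0.1).
#' @param equal_var_qtls if `TRUE`, additive (and dominant) QTL effects are
#'   sized so each QTL contributes an equal share of its component's
#'   variance; otherwise effects are drawn standard normal and rescaled
#'   jointly.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_males = 113, n_females = 5, n_snps = 5000,
                       n_chrom = 12, chrom_length_bp = 25e6,
                       maf_range = c(0.05, 0.5), n_qtl_add = 5, n_qtl_dom = 3,
                       h2_a = 0.4, h2_d = 0.2, ld_block_size = 1,
                       adj_r2 = 0.8, n_subpop = 0, fst = 0.1,
                       equal_var_qtls = FALSE, seed = 1) {
  cfg <- as.list(environment())
  if (h2_a + h2_d >= 1) stop("h2_a + h2_d must be < 1")
  if (n_qtl_add + n_qtl_dom > n_snps) stop("more QTLs than SNPs")
  if (n_qtl_add == 0 && h2_a > 0) stop("h2_a > 0 requires n_qtl_add > 0")
  if (n_qtl_dom == 0 && h2_d > 0) stop("h2_d > 0 requires n_qtl_dom > 0")
  structure(cfg, class = "sim_config")
}

#' Simulate fully homozygous parental genotypes
#'
#' Per SNP an alternate-allele frequency is drawn from the configured
#' spectrum and each inbred parent is the alternate homozygote with that
#' probability. Linkage disequilibrium is emulated by block copying: within
#' a block every SNP copies the block founder's indicator with a per-sample
#' flip probability calibrated so adjacent pairs reach the target
#' r-squared. With subpopulations, frequencies are redrawn per
#' subpopulation from a Balding-Nichols Beta around the ancestral value
#' and parents are assigned to subpopulations at random. Deterministic
#' under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A [geno_matrix()] of `n_males + n_females` fully homozygous
#'   parents (males `M001...`, females `F01...`).
#' @export
simulate_parents <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_males + cfg$n_females
  ids <- c(sprintf("M%03d", seq_len(cfg$n_males)),
           sprintf("F%02d", seq_len(cfg$n_females)))
  per_chrom <- diff(round(seq(0, cfg$n_snps, length.out = cfg$n_chrom + 1)))
  chrom <- rep(sprintf("chr%02d", seq_len(cfg$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) sort(sample.int(cfg$chrom_length_bp, k))))
  alle <- t(vapply(seq_len(cfg$n_snps),
                   function(i) sample(c("A", "C", "G", "T"), 2), character(2)))
  q <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  subpop <- if (cfg$n_subpop > 0) sample.int(cfg$n_subpop, n, replace = TRUE) else rep(1L, n)
  n_pop <- max(subpop)
  qs <- matrix(q, n_pop, cfg$n_snps, byrow = TRUE)
  if (cfg$n_subpop > 0) {
    a <- (1 - cfg$fst) / cfg$fst
    for (s in seq_len(n_pop))
      qs[s, ] <- stats::rbeta(cfg$n_snps, q * a, (1 - q) * a)
  }
  blocks <- ceiling(seq_len(cfg$n_snps) / cfg$ld_block_size)
  # flip probability: corr(SNP, founder) = 1 - 2*eps, so an adjacent pair
  # (both copies of the founder) has r2 = (1 - 2*eps)^4 = adj_r2
  eps <- (1 - cfg$adj_r2^(1 / 4)) / 2
  calls <- matrix(0L, n, cfg$n_snps)
  for (b in unique(blocks)) {
    j <- which(blocks == b)
    founder <- matrix(stats::rbinom(n, 1, qs[subpop, j[1]]), n, 1)
    z <- matrix(rep(founder, length(j)), n, length(j))
    if (cfg$ld_block_size > 1 && length(j) > 1) {
      flip <- matrix(stats::rbinom(n * (length(j) - 1), 1, eps), n)
      z[, -1] <- abs(z[, -1, drop = FALSE] - flip)
    }
    calls[, j] <- 2L * z
  }
  geno_matrix(calls, data.frame(chrom = chrom, pos = pos,
                                ref = alle[, 1], alt = alle[, 2],
                                stringsAsFactors = FALSE), ids)
}

#' Simulate inbred and testcross traits from planted QTLs
#'
#' Samples QTL positions without replacement; additive effects act in both
#' generations through the additive coding, dominance effects only where
#' heterozygotes exist (hybrids). Components are rescaled to the realized
#' sample variances so that among hybrids
#' `var(A a) / var(T) = h2_a` and `var(D d) / var(T) = h2_d` hold for the
#' dataset actually generated (up to the small sampling covariance between
#' components); the residual standard deviation is `sqrt(1 - h2_a - h2_d)`
#' after rescaling the residual draw to unit realized variance. Inbred
#' phenotypes use the same additive effects and residual scale; their
#' dominance contribution is structurally zero.
#'
#' @param parents a [geno_matrix()] of inbred parents.
#' @param design a [cross_design()].
#' @param cfg a [sim_config()].
#' @return list: `v` and `t` (named phenotype vectors), `truth` (a
#'   `sim_truth` list: QTL table with per-QTL realized hybrid variance
#'   shares, realized `h2_a`/`h2_d`, `sigma_e`). QTL positions are drawn
#'   from the SNPs segregating (in the relevant coding) among the hybrids.
#' @export
simulate_traits <- function(parents, design, cfg) {
  set.seed(cfg$seed + 1L)
  hybrids <- infer_hybrids(parents, design, "force_hom")
  A_par <- code_additive(parents); A_hyb <- code_additive(hybrids)
  D_hyb <- code_dominant(hybrids)
  n_hyb <- nrow(A_hyb); n_par <- nrow(A_par)
  # QTLs must segregate in the coding they act through among the hybrids
  poly_a <- which(apply_constant_col_(A_hyb) == FALSE)
  poly_d <- which(apply_constant_col_(D_hyb) == FALSE)
  if (length(poly_a) < cfg$n_qtl_add || length(poly_d) < cfg$n_qtl_dom)
    stop("not enough polymorphic SNPs among hybrids to plant the QTLs")
  add_idx <- if (cfg$n_qtl_add > 0) sample(poly_a, cfg$n_qtl_add) else integer(0)
  dom_idx <- if (cfg$n_qtl_dom > 0)
    sample(setdiff(poly_d, add_idx), cfg$n_qtl_dom) else integer(0)
  qtl <- c(add_idx, dom_idx)

  scale_component <- function(M, idx, target_h2, equalize) {
    if (length(idx) == 0 || target_h2 == 0)
      return(list(effects = numeric(length(idx)), g = numeric(nrow(M))))
    eff <- stats::rnorm(length(idx))
    if (equalize) {
      sds <- apply(M[, idx, drop = FALSE], 2, stats::sd)
      if (any(sds == 0)) stop("degenerate QTL column (monomorphic in hybrids)")
      eff <- sign(eff) / sds
    }
    g <- as.numeric(M[, idx, drop = FALSE] %*% eff)
    vg <- stats::var(g)
    if (vg <= 0) stop("zero genetic variance from planted QTLs")
    s <- sqrt(target_h2 / vg)
    list(effects = eff * s, g = g * s)
  }
  ca <- scale_component(A_hyb, add_idx, cfg$h2_a, cfg$equal_var_qtls)
  cd <- scale_component(D_hyb, dom_idx, cfg$h2_d, cfg$equal_var_qtls)
  s2e <- 1 - cfg$h2_a - cfg$h2_d
  e_hyb <- stats::rnorm(n_hyb); e_hyb <- e_hyb / stats::sd(e_hyb) * sqrt(s2e)
  t_val <- ca$g + cd$g + e_hyb
  e_par <- stats::rnorm(n_par, 0, sqrt(s2e))
  v_val <- if (length(add_idx))
    as.numeric(A_par[, add_idx, drop = FALSE] %*% ca$effects) + e_par else e_par

  a_full <- d_full <- numeric(length(qtl))
  a_full[seq_along(add_idx)] <- ca$effects
  d_full[length(add_idx) + seq_along(dom_idx)] <- cd$effects
  var_t <- stats::var(t_val)
  share <- vapply(seq_along(qtl), function(k) {
    j <- qtl[k]
    if (a_full[k] != 0) stats::var(A_hyb[, j] * a_full[k]) / var_t
    else stats::var(D_hyb[, j] * d_full[k]) / var_t
  }, numeric(1))
  truth <- structure(list(
    qtl = data.frame(snp = qtl, chrom = parents$info$chrom[qtl],
                     pos = parents$info$pos[qtl], a = a_full, d = d_full,
                     var_share = share, stringsAsFactors = FALSE),
    h2_a = stats::var(ca$g) / var_t, h2_d = stats::var(cd$g) / var_t,
    sigma_e = sqrt(s2e)), class = "sim_truth")
  list(v = stats::setNames(v_val, parents$samples),
       t = stats::setNames(t_val, hybrids$samples),
       truth = truth)
}

#' Simulate a complete testcross dataset
#'
#' Convenience wrapper: parents, full-factorial design, inferred hybrids,
#' and one simulated trait.
#'
#' @param cfg a [sim_config()].
#' @return list: `parents`, `hybrids`, `design`, `v`, `t`, `truth`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  parents <- simulate_parents(cfg)
  design <- factorial_design(parents$samples[seq_len(cfg$n_males)],
                             parents$samples[cfg$n_males + seq_len(cfg$n_females)])
  tr <- simulate_traits(parents, design, cfg)
  hybrids <- infer_hybrids(parents, design, "force_hom")
  c(list(parents = parents, hybrids = hybrids, design = design, cfg = cfg), tr)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `genotypes.vcf`, `design.tsv`, `pheno_v.tsv`, `pheno_t.tsv`, and
#' `truth.tsv` into `dir`.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$parents, file.path(dir, "genotypes.vcf"))
  utils::write.table(sim$design$hybrids, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- function(x) data.frame(sample_id = names(x), trait = unname(x))
  utils::write.table(ph(sim$v), file.path(dir, "pheno_v.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ph(sim$t), file.path(dir, "pheno_t.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$qtl, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# TRUE for columns with no variation
apply_constant_col_ <- function(M) {
  colSums(abs(M - rep(M[1L, ], each = nrow(M)))) == 0
}
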