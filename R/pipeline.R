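#' One-trait JPEG analysis on in-memory data
#'
#' Stacks the requested blocks for one trait and dataset — `inbred` uses V
#' and G, `hybrid` uses T and H, `combined` uses all four — runs the
#' iterative additive-dominant GWAS, and merges significant SNPs into loci.
#'
#' @param parents,hybrids imputed [geno_matrix()] objects.
#' @param design a [cross_design()].
#' @param v,t named phenotype vectors for parents and hybrids.
#' @param dataset `"combined"`, `"inbred"`, or `"hybrid"`.
#' @param alpha familywise type-I error (default 0.01).
#' @param n_pc principal components (default 3).
#' @param window_bp locus merge window (default 200 kb).
#' @param ... further arguments to [run_jpeg_gwas()].
#' @return list: `stacked`, `assoc`, `loci`, `dataset`.
#' @export
jpeg_analysis <- function(parents, hybrids, design, v, t,
                          dataset = c("combined", "inbred", "hybrid"),
                          alpha = 0.01, n_pc = 3, window_bp = 200000, ...) {
  dataset <- match.arg(dataset)
  g <- derive_gca(t, design)
  h <- derive_heterosis(t, v, design)
  blocks <- switch(dataset, combined = c("V", "T", "G", "H"),
                   inbred = c("V", "G"), hybrid = c("T", "H"))
  stacked <- standardize_and_stack(v = v, t = t, g = g, h = h,
                                   design = design, parents = parents,
                                   hybrids = hybrids, blocks = blocks)
  stacked <- build_covariates(stacked, n_pc = n_pc)
  assoc <- run_jpeg_gwas(stacked, alpha = alpha, ...)
  list(stacked = stacked, assoc = assoc,
       loci = merge_loci(assoc, window_bp), dataset = dataset)
}

#' Heritability report for inbreds and hybrids
#'
#' Among inbred varieties the model carries the additive kinship only (no
#' heterozygotes, so no dominance component is estimable); among hybrids
#' both additive and dominance kinships are fitted. Kinships are built on
#' exactly the sample set being analysed.
#'
#' @inheritParams jpeg_analysis
#' @return list of two [estimate_varcomp()] results, `inbred` and `hybrid`.
#' @export
estimate_h2 <- function(parents, hybrids, v, t) {
  vv <- v[!is.na(v)]
  pi <- match(names(vv), parents$samples)
  A_par <- code_additive(parents)[pi, , drop = FALSE]
  inbred <- estimate_varcomp(unname(vv), matrix(1, length(vv)),
                             K_a = vanraden_kinship(A_par))
  tt <- t[!is.na(t)]
  hi <- match(names(tt), hybrids$samples)
  A_hyb <- code_additive(hybrids)[hi, , drop = FALSE]
  D_hyb <- code_dominant(hybrids)[hi, , drop = FALSE]
  hybrid <- estimate_varcomp(unname(tt), matrix(1, length(tt)),
                             K_a = vanraden_kinship(A_hyb),
                             K_d = dominant_kinship(D_hyb))
  list(inbred = inbred, hybrid = hybrid)
}

default_run_config <- function() {
  list(dataset = "combined", traits = NULL, alpha = 0.01,
       max_missing = 0.20, min_maf = 0.05, window_bp = 200000,
       ld_r2_max = 0.7, max_candidates = 20, n_pc = 3,
       run_h2 = TRUE, run_cv = FALSE, cv_method = "locus_based",
       cv_repeats = 10, seed = 1,
       geno = NULL, design = NULL, pheno_v = NULL, pheno_t = NULL,
       out = "jpeg_run")
}

#' Run the full file-based JPEG pipeline
#'
#' Reads parental genotypes (VCF), the cross-design table, and the two
#' phenotype tables; QC-filters and imputes the genotypes; infers hybrid
#' genotypes; then per trait runs the joint GWAS with locus merging,
#' heritability estimation, and (optionally) cross-validated prediction.
#' All outputs land in `cfg$out` together with a JSON manifest recording
#' the configuration, package version, seeds, and input checksums; each
#' output table carries the manifest's config hash in a leading comment
#' line, and a rerun with an identical manifest reproduces the outputs
#' bit-identically.
#'
#' @param cfg named list overriding the defaults (see
#'   `jpegwas:::default_run_config()`); must set `geno`, `design`,
#'   `pheno_v`, `pheno_t`, and `out`. May also be a path to a YAML file
#'   with those keys.
#' @return (invisibly) a list of per-trait results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    cfg <- yaml::read_yaml(cfg)
  }
  cfg <- utils::modifyList(default_run_config(), cfg)
  for (p in c("geno", "design", "pheno_v", "pheno_t")) {
    if (is.null(cfg[[p]])) stop(sprintf("config key '%s' is required", p))
    if (!file.exists(cfg[[p]])) stop(sprintf("input '%s' not found: %s", p, cfg[[p]]))
  }
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  logf <- function(fmt, ...) message(sprintf(paste0("[jpeg] ", fmt), ...))

  cfg_file <- tempfile()
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), cfg_file)
  hash <- substr(unname(tools::md5sum(cfg_file)), 1, 12)
  stamp <- sprintf("# config_hash: %s", hash)
  write_tsv <- function(df, name) {
    path <- file.path(cfg$out, name)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(stamp, con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    path
  }

  logf("loading genotypes from %s", cfg$geno)
  parents <- load_vcf(cfg$geno)
  parents <- qc_filter(parents, cfg$max_missing, cfg$min_maf)
  parents <- impute_missing(parents)
  design <- read_cross_design(cfg$design)
  hybrids <- infer_hybrids(parents, design)
  pv <- read_phenotypes(cfg$pheno_v)
  pt <- read_phenotypes(cfg$pheno_t)
  traits <- cfg$traits %||% names(pt)
  write_tsv(parents$info, "snp_info.tsv")

  results <- list()
  for (trait in traits) {
    logf("trait %s: %s GWAS", trait, cfg$dataset)
    v <- trait_values(pv, trait); t <- trait_values(pt, trait)
    ana <- jpeg_analysis(parents, hybrids, design, v, t,
                         dataset = cfg$dataset, alpha = cfg$alpha,
                         n_pc = cfg$n_pc, window_bp = cfg$window_bp,
                         ld_r2_max = cfg$ld_r2_max,
                         max_candidates = cfg$max_candidates)
    res <- ana$assoc$results
    res$significant <- as.integer(res$significant)
    res$pseudo_qtn <- as.integer(res$pseudo_qtn)
    write_tsv(res, sprintf("assoc_%s_%s.tsv", trait, cfg$dataset))
    loci <- ana$loci; loci$snps <- NULL
    write_tsv(loci, sprintf("loci_%s_%s.tsv", trait, cfg$dataset))
    out <- list(analysis = ana)
    if (isTRUE(cfg$run_h2)) {
      h2 <- estimate_h2(parents, hybrids, v, t)
      write_tsv(data.frame(trait = trait, population = c("inbred", "hybrid"),
                           sigma2_a = c(h2$inbred$sigma2_a, h2$hybrid$sigma2_a),
                           sigma2_d = c(h2$inbred$sigma2_d, h2$hybrid$sigma2_d),
                           sigma2_e = c(h2$inbred$sigma2_e, h2$hybrid$sigma2_e),
                           h2_a = c(h2$inbred$h2_a, h2$hybrid$h2_a),
                           h2_d = c(h2$inbred$h2_d, h2$hybrid$h2_d),
                           h2_total = c(h2$inbred$h2_total, h2$hybrid$h2_total),
                           converged = c(h2$inbred$converged, h2$hybrid$converged)),
                sprintf("h2_%s.tsv", trait))
      out$h2 <- h2
    }
    if (isTRUE(cfg$run_cv)) {
      cvd <- jpeg_cv_data(parents, hybrids, design, v, t, n_pc = cfg$n_pc)
      cv <- cross_validate(cvd, cfg$cv_method, n_repeats = cfg$cv_repeats,
                           seed = cfg$seed, alpha = cfg$alpha)
      write_tsv(cv$folds, sprintf("cv_%s_%s.tsv", trait, cfg$cv_method))
      out$cv <- cv
    }
    results[[trait]] <- out
  }
  manifest <- list(config = cfg, config_hash = hash,
                   package = "jpegwas",
                   version = as.character(utils::packageVersion("jpegwas")),
                   inputs = as.list(tools::md5sum(unlist(cfg[c("geno", "design",
                                                               "pheno_v", "pheno_t")]))))
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done; outputs in %s", cfg$out)
  invisible(results)
}
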