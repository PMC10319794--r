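# Shared fixture builders. Everything is generated in code at test time.

# a small genotype matrix built directly from dosage calls
make_geno <- function(calls, ref = NULL, alt = NULL, chrom = NULL, pos = NULL,
                      samples = NULL) {
  m <- ncol(calls)
  geno_matrix(calls,
              data.frame(chrom = chrom %||% rep("chr01", m),
                         pos = pos %||% seq(1000, by = 1000, length.out = m),
                         ref = ref %||% rep("A", m),
                         alt = alt %||% rep("G", m),
                         stringsAsFactors = FALSE),
              samples %||% sprintf("s%02d", seq_len(nrow(calls))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a minimal VCF text file and return its path
write_test_vcf <- function(records, samples,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.vcf")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# full simulated dataset at a small scale, plus its stacked combined system
small_dataset <- function(seed = 1, n_males = 20, n_females = 2, n_snps = 300,
                          n_qtl_add = 2, n_qtl_dom = 1, h2_a = 0.4, h2_d = 0.2) {
  cfg <- sim_config(n_males = n_males, n_females = n_females, n_snps = n_snps,
                    n_qtl_add = n_qtl_add, n_qtl_dom = n_qtl_dom,
                    h2_a = h2_a, h2_d = h2_d, equal_var_qtls = TRUE, seed = seed)
  simulate_dataset(cfg)
}

stack_of <- function(sim, blocks = c("V", "T", "G", "H")) {
  g <- derive_gca(sim$t, sim$design)
  h <- derive_heterosis(sim$t, sim$v, sim$design)
  st <- standardize_and_stack(v = sim$v, t = sim$t, g = g, h = h,
                              design = sim$design, parents = sim$parents,
                              hybrids = sim$hybrids, blocks = blocks)
  suppressWarnings(build_covariates(st))
}

# does any merged locus fall within `window` bp of the given position?
locus_hit <- function(loci, chrom, pos, window = 200000) {
  nrow(loci) > 0 &&
    any(loci$chrom == chrom & pos >= loci$start - window & pos <= loci$end + window)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
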