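# Small in-code fixtures shared across test files.

# random genotype fixture with optional missingness; variants on one or
# more chromosomes with sorted positions
random_gm <- function(n = 60, m = 12, n_chrom = 2, miss = 0, seed = 1,
                      spacing = 10000) {
  set.seed(seed)
  maf <- runif(m, 0.1, 0.5)
  d <- sapply(maf, function(p) rbinom(n, 2, p))
  if (miss > 0) d[runif(length(d)) < miss] <- NA
  per <- ceiling(m / n_chrom)
  variants <- data.frame(
    id = sprintf("v%03d", 1:m),
    chrom = paste0("chr", rep(1:n_chrom, each = per)[1:m]),
    pos = rep(seq(1e5, by = spacing, length.out = per), n_chrom)[1:m],
    ref = "A", alt = "G", strand = "+", stringsAsFactors = FALSE)
  geno_matrix(d, variants, sample_ids = sprintf("s%03d", 1:n))
}

small_cohort <- function(seed = 11, n = 400, h2 = 0.4, prev = 0.3,
                         n_blocks = 6, block_size = 8, r = 0.5,
                         n_causal = 6, ...) {
  cfg <- sim_config(n_samples = n, n_blocks = n_blocks,
                    block_size = block_size, within_block_r = r,
                    n_causal = n_causal, heritability_liability = h2,
                    prevalence = prev, seed = seed, ...)
  gm <- sim_genotypes(cfg)
  ph <- sim_phenotype(gm, cfg)
  list(cfg = cfg, gm = gm, samples = ph$samples, truth = ph$truth)
}
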