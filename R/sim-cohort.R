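#' Simulation configuration for a synthetic biobank cohort
#'
#' Bundles every knob of the generative model: block-structured LD
#' genotypes, a liability-threshold binary disease with planted causal
#' variants, age/sex covariates, and an EHR phenome with one genetically
#' shared comorbid code plus null codes. Identical config (including
#' `seed`) gives bit-identical output from every simulator operation.
#'
#' Defaults encode the study conditions the downstream analyses assume:
#' 8000 samples, 80 LD blocks of 25 variants (2000 variants), liability
#' heritability 0.5, prevalence 0.1, ages Normal(57, 8) truncated to
#' [40, 70] (a UK-Biobank-like age structure), sexes Bernoulli(0.5).
#'
#' @param n_samples number of samples.
#' @param n_blocks,block_size LD blocks and variants per block; each block
#'   lives on its own synthetic chromosome so LD windows never span blocks.
#' @param maf_range pair of allele frequencies in (0, 0.5] to draw
#'   per-variant ALT frequencies from (uniform).
#' @param within_block_r target Pearson correlation of adjacent-variant
#'   dosages within a block, in [0, 1).
#' @param n_causal number of causal variants (spread across blocks).
#' @param heritability_liability fraction of liability variance explained
#'   by genotype, in [0, 1).
#' @param prevalence disease prevalence in (0, 1).
#' @param covar_frac fraction of liability variance from the age and sex
#'   terms (split equally), so tests can switch covariate confounding off.
#' @param comorbidity_shared_fraction fraction of causal variants whose
#'   effects are reused by the comorbid code's liability, in [0, 1].
#' @param comorbid_prevalence prevalence of the comorbid code.
#' @param n_null_codes number of EHR codes assigned independently of
#'   genotype.
#' @param anchor_code_rate fraction of samples carrying the healthy-visit
#'   anchor code (Z00.00), in (0, 1].
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param missing_rate fraction of dosages set missing at random.
#' @param seed integer seed; every simulator operation is a pure function
#'   of (inputs, seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 8000,
                       n_blocks = 80,
                       block_size = 25,
                       maf_range = c(0.05, 0.5),
                       within_block_r = 0.5,
                       n_causal = 50,
                       heritability_liability = 0.5,
                       prevalence = 0.1,
                       covar_frac = 0.02,
                       comorbidity_shared_fraction = 0.8,
                       comorbid_prevalence = 0.05,
                       n_null_codes = 50,
                       anchor_code_rate = 0.6,
                       age_mean = 57, age_sd = 8, age_range = c(40, 70),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size), maf_range = maf_range,
    within_block_r = within_block_r, n_causal = as.integer(n_causal),
    heritability_liability = heritability_liability, prevalence = prevalence,
    covar_frac = covar_frac,
    comorbidity_shared_fraction = comorbidity_shared_fraction,
    comorbid_prevalence = comorbid_prevalence,
    n_null_codes = as.integer(n_null_codes),
    anchor_code_rate = anchor_code_rate,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  with(cfg, {
    if (n_samples < 1 || n_blocks < 1 || block_size < 1) {
      stop("n_samples, n_blocks and block_size must be positive")
    }
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
      stop("maf_range must lie in (0, 0.5]")
    }
    if (within_block_r < 0 || within_block_r >= 1) stop("within_block_r must be in [0, 1)")
    if (n_causal > n_blocks * block_size) stop("n_causal exceeds variant count")
    if (heritability_liability < 0 || heritability_liability >= 1) {
      stop("heritability_liability must be in [0, 1)")
    }
    if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
    if (comorbidity_shared_fraction < 0 || comorbidity_shared_fraction > 1) {
      stop("comorbidity_shared_fraction must be in [0, 1]")
    }
    if (anchor_code_rate <= 0 || anchor_code_rate > 1) {
      stop("anchor_code_rate must be in (0, 1]")
    }
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  })
  structure(cfg, class = "sim_config")
}

# Bivariate standard normal upper tail P(Z1 > a, Z2 > b) at correlation rho,
# by 1-D quadrature over the conditional distribution.
bvn_upper <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(-a) * pnorm(-b))
  if (rho > 1 - 1e-7) return(pnorm(-max(a, b)))
  f <- function(z) dnorm(z) * pnorm((rho * z - b) / sqrt(1 - rho^2))
  stats::integrate(f, a, Inf, rel.tol = 1e-9)$value
}

# Pearson correlation of two dosages obtained by qbinom(pnorm(z), 2, p)
# transforms of latent normals with correlation rho.
copula_dosage_cor <- function(rho, p1, p2) {
  cuts <- function(p) qnorm(c((1 - p)^2, (1 - p)^2 + 2 * p * (1 - p)))
  c1 <- cuts(p1); c2 <- cuts(p2)
  e12 <- 0
  for (i in 1:2) for (j in 1:2) e12 <- e12 + bvn_upper(c1[i], c2[j], rho)
  (e12 - 4 * p1 * p2) / sqrt(4 * p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent correlation that yields a target adjacent dosage correlation at
# MAF p (equal on both sides). The copula attenuates correlation, so the
# latent value is inflated; inverted by root finding, cached on a MAF grid.
calibrate_latent_r <- function(target_r, p) {
  if (target_r <= 0) return(0)
  f <- function(rho) copula_dosage_cor(rho, p, p) - target_r
  stats::uniroot(f, c(target_r, 1 - 1e-7), tol = 1e-7)$root
}

#' Simulate block-LD genotypes
#'
#' Genotypes are generated through a Gaussian copula: per block, a latent
#' AR(1) normal chain is transformed variant-wise through the Binomial(2, p)
#' quantile function. The latent adjacent correlation is calibrated
#' (numerically, per MAF) so the *dosage* correlation of adjacent variants
#' approximates `within_block_r`. Blocks are mutually independent and each
#' block is placed on its own synthetic chromosome (variants 5 kb apart),
#' so clumping/pruning windows never span blocks.
#'
#' @param config a [sim_config()].
#' @return a [geno_matrix()]; its variant table has columns
#'   `id, chrom, pos, ref, alt, strand, block`.
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  B <- config$n_blocks
  m <- config$block_size
  r <- config$within_block_r

  # MAF is drawn per block: variants sharing an LD block share a
  # frequency, which keeps the target dosage correlation attainable for
  # every adjacent pair (strongly disparate frequencies cap the
  # achievable correlation below the target)
  maf <- rep(runif(B, config$maf_range[1], config$maf_range[2]), each = m)
  # calibration grid: latent r as a function of MAF, interpolated
  if (r > 0) {
    grid_p <- seq(max(0.02, config$maf_range[1]), 0.5, length.out = 12)
    grid_a <- vapply(grid_p, function(p) calibrate_latent_r(r, p), numeric(1))
    latent_of <- stats::approxfun(grid_p, grid_a, rule = 2)
  }

  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T", "T", "C", "G", "A",
                    "A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), B * m, replace = TRUE)

  dosage <- matrix(NA_integer_, n, B * m)
  for (b in seq_len(B)) {
    cols <- (b - 1L) * m + seq_len(m)
    z <- matrix(rnorm(n * m), n, m)
    if (r > 0 && m > 1) {
      for (k in 2:m) {
        a <- latent_of((maf[cols[k - 1]] + maf[cols[k]]) / 2)
        z[, k] <- a * z[, k - 1] + sqrt(1 - a^2) * z[, k]
      }
    }
    for (k in seq_len(m)) {
      dosage[, cols[k]] <- qbinom(pnorm(z[, k]), 2L, maf[cols[k]])
    }
  }
  if (config$missing_rate > 0) {
    dosage[runif(length(dosage)) < config$missing_rate] <- NA_integer_
  }

  variants <- data.frame(
    id = sprintf("snp%05d", seq_len(B * m)),
    chrom = paste0("chr", rep(seq_len(B), each = m)),
    pos = rep(1e6 + (seq_len(m) - 1L) * 5000L, B),
    ref = pairs[pick, 1], alt = pairs[pick, 2],
    strand = "+",
    block = rep(seq_len(B), each = m),
    stringsAsFactors = FALSE
  )
  gm <- geno_matrix(dosage, variants,
                    sample_ids = sprintf("S%05d", seq_len(n)))
  gm
}

# truncated-normal ages by rejection (vectorized resampling)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate a liability-threshold phenotype with covariates
#'
#' Liability is the sum of a genetic term (standardized dosages of the
#' planted causal variants times their effects, scaled to variance
#' `heritability_liability`), small age and sex terms (total variance
#' `covar_frac`), and Gaussian noise filling the remainder, so total
#' liability variance is 1. A sample is a case iff liability exceeds the
#' standard-normal `1 - prevalence` quantile.
#'
#' @param gm a [geno_matrix()] from [sim_genotypes()].
#' @param config the [sim_config()] used to generate `gm`.
#' @return list with `samples` (data.frame: `id, reported_sex, genetic_sex,
#'   age, status`) and `truth` (list: `causal_variant_ids, causal_effects,
#'   case_ids, genetic_liability, liability`).
#' @export
sim_phenotype <- function(gm, config) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(config, "sim_config"))
  h2 <- config$heritability_liability
  if (h2 >= 1) stop("heritability must be < 1")
  set.seed(config$seed + 1L)
  n <- nrow(gm$dosage)
  M <- ncol(gm$dosage)

  # spread causal variants across blocks: round-robin over shuffled blocks
  blocks <- gm$variants$block
  if (is.null(blocks)) blocks <- rep(1L, M)
  by_block <- split(seq_len(M), blocks)
  by_block <- lapply(by_block[sample(length(by_block))], sample)
  picked <- integer(0)
  while (length(picked) < config$n_causal) {
    for (b in seq_along(by_block)) {
      if (length(by_block[[b]])) {
        picked <- c(picked, by_block[[b]][1])
        by_block[[b]] <- by_block[[b]][-1]
        if (length(picked) == config$n_causal) break
      }
    }
  }
  causal <- sort(picked)
  eff <- rnorm(length(causal))

  g <- 0
  if (h2 > 0 && length(causal)) {
    X <- gm$dosage[, causal, drop = FALSE]
    X <- scale(ifelse(is.na(X), matrix(colMeans(X, na.rm = TRUE),
                                       n, length(causal), byrow = TRUE), X))
    X[is.nan(X)] <- 0
    g <- drop(X %*% eff)
    sg <- stats::sd(g)
    if (sg > 0) g <- g * sqrt(h2) / sg else h2 <- 0
  } else {
    g <- rep(0, n)
    eff <- rep(0, length(causal))
  }

  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  sex <- rbinom(n, 1, 0.5) # 1 = male
  cf <- config$covar_frac
  cov_term <- sqrt(cf / 2) * scale(age)[, 1] +
    sqrt(cf / 2) * (sex - 0.5) / 0.5
  noise_var <- max(1 - h2 - cf, 1e-8)
  liab <- g + cov_term + rnorm(n, 0, sqrt(noise_var))
  thr <- qnorm(1 - config$prevalence)
  status <- ifelse(liab > thr, "case", "control")

  ids <- rownames(gm$dosage)
  samples <- data.frame(
    id = ids,
    reported_sex = ifelse(sex == 1, "M", "F"),
    genetic_sex = ifelse(sex == 1, "M", "F"),
    age = age,
    status = status,
    stringsAsFactors = FALSE
  )
  rownames(samples) <- NULL
  truth <- list(
    causal_variant_ids = gm$variants$id[causal],
    causal_effects = eff,
    case_ids = ids[status == "case"],
    genetic_liability = stats::setNames(g, ids),
    liability = stats::setNames(liab, ids)
  )
  list(samples = samples, truth = truth)
}
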