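#' Simulate training-cohort GWAS summary statistics
#'
#' Emulates an external large-scale case-control meta-GWAS over the same
#' variants: the per-variant "true" marginal effect is the least-squares
#' slope of the genetic liability on the variant's dosage in the simulated
#' cohort (so LD partners of causal variants carry proxy effects), and the
#' reported beta adds Gaussian estimation noise with standard error
#' `1 / (sd(dosage) * sqrt(n_train))`. P-values are two-sided Wald. To
#' exercise allele harmonization, a configurable fraction of records is
#' emitted with effect/other alleles swapped (beta negated, so the record
#' stays self-consistent) and a fraction on the complementary strand.
#'
#' @param truth truth record from [sim_phenotype()].
#' @param gm the [geno_matrix()] the truth was generated from.
#' @param n_train effective training sample size (use `Inf` for the
#'   noise-free limit, where `se = 0` and `p` is 0 or 1).
#' @param seed integer seed.
#' @param swap_frac fraction of records with effect/other alleles swapped.
#' @param flip_frac fraction of records reported on the reverse strand.
#' @return data.frame with columns
#'   `id, chrom, pos, effect_allele, other_allele, beta, se, p` plus a
#'   logical `swapped`/`flipped` ground-truth pair for tests.
#' @export
sim_training_sumstats <- function(truth, gm, n_train = 50000, seed = 1L,
                                  swap_frac = 0, flip_frac = 0) {
  stopifnot(inherits(gm, "geno_matrix"), n_train > 0)
  set.seed(as.integer(seed))
  d <- gm$dosage
  n <- nrow(d)
  g <- truth$genetic_liability[rownames(d)]
  mu <- colMeans(d, na.rm = TRUE)
  dc <- ifelse(is.na(d), matrix(mu, n, ncol(d), byrow = TRUE), d)
  vg <- apply(dc, 2, stats::var)
  vg[vg == 0] <- NA
  beta_true <- as.vector(crossprod(dc, g - mean(g))) / ((n - 1) * vg)
  beta_true[is.na(beta_true)] <- 0
  se <- if (is.finite(n_train)) 1 / (sqrt(pmax(vg, 1e-12)) * sqrt(n_train)) else rep(0, ncol(d))
  se[is.na(se)] <- 1
  beta <- beta_true + rnorm(ncol(d)) * se
  p <- if (is.finite(n_train)) {
    2 * pnorm(-abs(beta / se))
  } else {
    ifelse(beta == 0, 1, 0)
  }

  v <- gm$variants
  out <- data.frame(
    id = v$id, chrom = v$chrom, pos = v$pos,
    effect_allele = v$alt, other_allele = v$ref,
    beta = beta, se = se, p = p,
    swapped = runif(nrow(v)) < swap_frac,
    flipped = runif(nrow(v)) < flip_frac,
    stringsAsFactors = FALSE
  )
  if (any(out$swapped)) {
    i <- out$swapped
    tmp <- out$effect_allele[i]
    out$effect_allele[i] <- out$other_allele[i]
    out$other_allele[i] <- tmp
    out$beta[i] <- -out$beta[i]
  }
  if (any(out$flipped)) {
    i <- out$flipped
    out$effect_allele[i] <- revcomp(out$effect_allele[i])
    out$other_allele[i] <- revcomp(out$other_allele[i])
  }
  out
}

#' Simulate an EHR diagnosis table
#'
#' Builds a phenome with known ground truth: the index code (`K51.90`) is
#' assigned to every case; one comorbid code (`E10.9`) arises from its own
#' liability threshold whose genetic component reuses a
#' `comorbidity_shared_fraction` subset of the causal effects (planting
#' cross-trait genetic sharing); `n_null_codes` codes are assigned
#' independently of genotype with per-code prevalences drawn uniformly
#' from 2-10%; and the anchor code `Z00.00` is assigned to a random
#' `anchor_code_rate` fraction of samples, independent of case status.
#'
#' @param samples sample table from [sim_phenotype()].
#' @param truth truth record from [sim_phenotype()].
#' @param gm the cohort [geno_matrix()].
#' @param config the [sim_config()].
#' @param seed integer seed.
#' @return list with `ehr` (data.frame `sample_id, icd10`), and `codes`
#'   (list: `index_code, comorbid_code, null_codes, anchor_code,
#'   comorbid_case_ids`).
#' @export
sim_ehr <- function(samples, truth, gm, config, seed = config$seed + 2L) {
  stopifnot(nrow(samples) > 0, inherits(config, "sim_config"))
  if (config$anchor_code_rate <= 0) stop("anchor_code_rate must be positive")
  set.seed(as.integer(seed))
  ids <- samples$id
  n <- length(ids)
  index_code <- "K51.90"
  comorbid_code <- "E10.9"
  anchor_code <- "Z00.00"

  rows <- list(data.frame(sample_id = truth$case_ids, icd10 = index_code,
                          stringsAsFactors = FALSE))

  # comorbid liability: shared subset of causal effects + own noise
  share <- config$comorbidity_shared_fraction
  h2 <- config$heritability_liability
  comorbid_cases <- character(0)
  k <- floor(share * length(truth$causal_variant_ids))
  if (k > 0 && h2 > 0) {
    sel <- truth$causal_variant_ids[seq_len(k)]
    X <- gm$dosage[ids, sel, drop = FALSE]
    mu <- colMeans(X, na.rm = TRUE)
    X <- scale(ifelse(is.na(X), matrix(mu, n, k, byrow = TRUE), X))
    X[is.nan(X)] <- 0
    g2 <- drop(X %*% truth$causal_effects[seq_len(k)])
    sg <- stats::sd(g2)
    g2 <- if (sg > 0) g2 * sqrt(h2) / sg else rep(0, n)
    liab2 <- g2 + rnorm(n, 0, sqrt(1 - h2))
  } else {
    liab2 <- rnorm(n)
  }
  comorbid_cases <- ids[liab2 > qnorm(1 - config$comorbid_prevalence)]
  if (length(comorbid_cases)) {
    rows <- c(rows, list(data.frame(sample_id = comorbid_cases,
                                    icd10 = comorbid_code,
                                    stringsAsFactors = FALSE)))
  }

  null_codes <- character(0)
  if (config$n_null_codes > 0) {
    null_codes <- sprintf("R%02d.%d",
                          seq_len(config$n_null_codes) %/% 10,
                          seq_len(config$n_null_codes) %% 10)
    null_codes <- make.unique(null_codes, sep = "x")
    for (code in null_codes) {
      prev <- runif(1, 0.02, 0.10)
      carriers <- ids[runif(n) < prev]
      if (length(carriers)) {
        rows <- c(rows, list(data.frame(sample_id = carriers, icd10 = code,
                                        stringsAsFactors = FALSE)))
      }
    }
  }

  anchor <- ids[runif(n) < config$anchor_code_rate]
  rows <- c(rows, list(data.frame(sample_id = anchor, icd10 = anchor_code,
                                  stringsAsFactors = FALSE)))
  ehr <- do.call(rbind, rows)
  rownames(ehr) <- NULL
  list(ehr = ehr,
       codes = list(index_code = index_code, comorbid_code = comorbid_code,
                    null_codes = null_codes, anchor_code = anchor_code,
                    comorbid_case_ids = comorbid_cases))
}

#' Plant QC defects into a clean cohort
#'
#' Returns corrupted copies of the genotypes and sample table plus a
#' ledger naming exactly what was corrupted, so QC tests can check that
#' precisely the planted items are removed. Defect classes (each applied
#' to a disjoint set of samples / variants):
#' \itemize{
#' \item `sex_mismatch`: reported sex flipped;
#' \item `low_call`: a fraction `low_call_missingness` of the sample's
#'   genotypes set missing;
#' \item `inbred`: genotypes replaced by fully homozygous draws
#'   (2 x Bernoulli(freq)), giving an inbreeding coefficient near 1;
#' \item `duplicate`: an appended copy of an existing sample (id suffix
#'   `_dup`) with `dup_extra_missing` extra missingness, so the copy is
#'   the higher-missingness member of the pair;
#' \item `monomorphic`: variant set to all-reference;
#' \item `hwe_violation`: variant regenerated as a half/half mixture of
#'   two subpopulation frequencies (0.02 and 0.6), a strong heterozygote
#'   deficit in everyone including controls;
#' \item `missdiff`: a fraction `missdiff_case_missing` of case dosages
#'   at the variant set missing (controls untouched).
#' }
#'
#' @param gm clean [geno_matrix()].
#' @param samples clean sample table (needs `id`, `reported_sex`,
#'   `genetic_sex`, `status`).
#' @param seed integer seed.
#' @param rates named list of per-class rates (fractions of samples for
#'   sample classes, counts could be 0): `sex_mismatch, low_call, inbred,
#'   duplicate, monomorphic, hwe_violation, missdiff`.
#' @param low_call_missingness,dup_extra_missing,missdiff_case_missing
#'   severity knobs of the respective defects.
#' @return list `genotypes` (corrupted `geno_matrix`), `samples`
#'   (corrupted table, possibly with appended duplicates), `ledger`
#'   (data.frame `kind, item, partner`).
#' @export
sim_qc_defects <- function(gm, samples, seed = 1L,
                           rates = list(sex_mismatch = 0.01, low_call = 0.01,
                                        inbred = 0.005, duplicate = 0.005,
                                        monomorphic = 0.005,
                                        hwe_violation = 0.005,
                                        missdiff = 0.005),
                           low_call_missingness = 0.10,
                           dup_extra_missing = 0.05,
                           missdiff_case_missing = 0.20) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) stop("rates must be in [0, 1]")
  set.seed(as.integer(seed))
  d <- gm$dosage
  v <- gm$variants
  n <- nrow(d); m <- ncol(d)
  ledger <- list()
  note <- function(kind, item, partner = NA_character_) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      kind = kind, item = item, partner = partner, stringsAsFactors = FALSE)
  }
  r <- function(name) if (is.null(rates[[name]])) 0 else rates[[name]]

  n_sex <- round(r("sex_mismatch") * n)
  n_low <- round(r("low_call") * n)
  n_inb <- round(r("inbred") * n)
  n_dup <- round(r("duplicate") * n)
  pool <- sample(rownames(d))
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
  }
  sex_ids <- take(n_sex); low_ids <- take(n_low)
  inb_ids <- take(n_inb); dup_ids <- take(n_dup)

  if (length(sex_ids)) {
    i <- match(sex_ids, samples$id)
    samples$reported_sex[i] <- ifelse(samples$reported_sex[i] == "M", "F", "M")
    for (id in sex_ids) note("sex_mismatch", id)
  }
  for (id in low_ids) {
    j <- sample.int(m, round(low_call_missingness * m))
    d[id, j] <- NA_integer_
    note("low_call", id)
  }
  freqs <- colSums(gm$dosage, na.rm = TRUE) / (2 * colSums(!is.na(gm$dosage)))
  for (id in inb_ids) {
    d[id, ] <- 2L * rbinom(m, 1L, freqs)
    note("inbred", id)
  }
  dup_rows <- list()
  for (id in dup_ids) {
    did <- paste0(id, "_dup")
    row <- d[id, ]
    row[sample.int(m, round(dup_extra_missing * m))] <- NA_integer_
    dup_rows[[did]] <- row
    src <- samples[match(id, samples$id), ]
    src$id <- did
    samples <- rbind(samples, src)
    note("duplicate", did, partner = id)
  }
  if (length(dup_rows)) {
    d <- rbind(d, do.call(rbind, dup_rows))
  }

  n_mono <- round(r("monomorphic") * m)
  n_hwe <- round(r("hwe_violation") * m)
  n_md <- round(r("missdiff") * m)
  vpool <- sample(v$id)
  vtake <- function(k) {
    if (k == 0) return(character(0))
    out <- vpool[seq_len(k)]; vpool <<- vpool[-seq_len(k)]; out
  }
  mono_ids <- vtake(n_mono); hwe_ids <- vtake(n_hwe); md_ids <- vtake(n_md)

  for (id in mono_ids) {
    d[, id] <- 0L
    note("monomorphic", id)
  }
  nn <- nrow(d)
  for (id in hwe_ids) {
    # half/half mixture of two widely separated subpopulation
    # frequencies: a strong Wahlund heterozygote deficit in everyone
    grp <- rep(c(0.02, 0.6), length.out = nn)[sample.int(nn)]
    d[, id] <- rbinom(nn, 2L, grp)
    note("hwe_violation", id)
  }
  case_rows <- rownames(d) %in% samples$id[samples$status == "case"]
  for (id in md_ids) {
    i <- which(case_rows & runif(nn) < missdiff_case_missing)
    d[i, id] <- NA_integer_
    note("missdiff", id)
  }

  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(kind = character(0), item = character(0),
               partner = character(0), stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  list(genotypes = geno_matrix(d, v), samples = samples, ledger = ledger)
}
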