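#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the sample size and allele count, the
#' probability of each attainable heterozygote count follows the classic
#' exact genotype-count distribution; the p-value is the sum of the
#' probabilities of all configurations no more probable than the observed
#' one (standard cumulative exact p, not mid-p). Symmetric in allele
#' labels.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts (total >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (length(n_AA) != 1) {
    return(mapply(hwe_exact_p, n_AA, n_Aa, n_aa))
  }
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped sample required")
  nA <- 2 * n_AA + n_Aa # minor-or-either allele count; test is label-symmetric
  nA <- min(nA, 2 * n - nA)
  hets <- seq(nA %% 2, nA, by = 2)
  # log-probability of each heterozygote count given (n, nA):
  # P(h) = C(n; (nA-h)/2, h, n-(nA+h)/2) 2^h / C(2n, nA)
  lp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(2 * n - nA + 1))
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(min(n_Aa, nA), hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Method-of-moments inbreeding coefficient
#'
#' `F = (O - E) / (n_used - E)` where `O` is the observed number of
#' homozygous calls in the sample, `E = sum(1 - 2 p q)` the expectation
#' under Hardy-Weinberg at the supplied cohort allele frequencies, and
#' `n_used` the number of non-missing, polymorphic variants entering both
#' sums.
#'
#' @param dosages numeric vector of the sample's dosages (0/1/2/`NA`).
#' @param allele_freqs ALT allele frequencies of the same variants,
#'   estimated on the analyzed cohort.
#' @return `F` (dimensionless); `NA` with a warning in the degenerate case
#'   `n_used == E` (flagged, not filtered).
#' @export
inbreeding_f <- function(dosages, allele_freqs) {
  stopifnot(length(dosages) == length(allele_freqs))
  use <- !is.na(dosages) & !is.na(allele_freqs) &
    allele_freqs > 0 & allele_freqs < 1
  d <- dosages[use]
  p <- allele_freqs[use]
  n_used <- length(d)
  if (n_used == 0) {
    warning("no usable variants for inbreeding coefficient")
    return(NA_real_)
  }
  obs_hom <- sum(d != 1)
  exp_hom <- sum(1 - 2 * p * (1 - p))
  denom <- n_used - exp_hom
  if (abs(denom) < 1e-12) {
    warning("degenerate inbreeding denominator; coefficient undefined")
    return(NA_real_)
  }
  (obs_hom - exp_hom) / denom
}

# Per-variant expected IBS-state probabilities under IBD states
# (Purcell-style method of moments). When the per-variant genotyped
# sample count is supplied, the small-sample bias corrections for
# frequencies estimated from the analyzed cohort itself are applied
# (ratios of falling factorials of the allele counts); without them the
# estimator is noticeably inflated at a few hundred samples.
ibs_expectations <- function(p, n_obs = NULL) {
  q <- 1 - p
  if (is.null(n_obs)) {
    return(list(
      e0_ibd0 = 2 * p^2 * q^2,
      e1_ibd0 = 4 * p^3 * q + 4 * p * q^3,
      e2_ibd0 = p^4 + q^4 + 4 * p^2 * q^2,
      e1_ibd1 = 2 * p^2 * q + 2 * p * q^2,
      e2_ibd1 = p^3 + q^3 + p^2 * q + p * q^2
    ))
  }
  T <- 2 * n_obs
  x <- p * T # ALT allele count
  y <- q * T
  f <- function(cnt, k) pmax((cnt - k) / cnt, 0) # falling-factorial ratio
  g <- function(k) T / (T - k)
  c3 <- g(1) * g(2) * g(3) # IBD0 terms condition on 4 distinct alleles
  c2 <- g(1) * g(2) # IBD1 terms condition on 3 distinct alleles
  list(
    e0_ibd0 = 2 * p^2 * q^2 * f(x, 1) * f(y, 1) * c3,
    e1_ibd0 = 4 * p^3 * q * f(x, 1) * f(x, 2) * c3 +
      4 * p * q^3 * f(y, 1) * f(y, 2) * c3,
    e2_ibd0 = p^4 * f(x, 1) * f(x, 2) * f(x, 3) * c3 +
      q^4 * f(y, 1) * f(y, 2) * f(y, 3) * c3 +
      4 * p^2 * q^2 * f(x, 1) * f(y, 1) * c3,
    e1_ibd1 = 2 * p^2 * q * f(x, 1) * c2 + 2 * p * q^2 * f(y, 1) * c2,
    e2_ibd1 = p^3 * f(x, 1) * f(x, 2) * c2 + q^3 * f(y, 1) * f(y, 2) * c2 +
      p^2 * q * f(x, 1) * c2 + p * q^2 * f(y, 1) * c2
  )
}

#' Pairwise IBD sharing (PI_HAT) by method of moments
#'
#' Estimates P(IBD = 0, 1, 2) from the observed identity-by-state counts
#' of the pair against their Hardy-Weinberg expectations at the supplied
#' allele frequencies, then `PI_HAT = P(IBD=2) + P(IBD=1)/2`, clamped to
#' [0, 1]. Intended for quasi-independent (LD-pruned) markers.
#'
#' @param dosages_a,dosages_b dosage vectors of the two samples.
#' @param allele_freqs cohort ALT allele frequencies of the same variants.
#' @param min_overlap minimum non-missing overlap; below it the pair is
#'   unevaluable and `NA` is returned with a warning.
#' @param n_obs optional per-variant count of genotyped samples behind
#'   `allele_freqs`; when supplied, small-sample bias corrections for
#'   cohort-estimated frequencies are applied.
#' @return PI_HAT in [0, 1], or `NA` for an unevaluable pair.
#' @export
ibd_pihat <- function(dosages_a, dosages_b, allele_freqs, min_overlap = 200,
                      n_obs = NULL) {
  stopifnot(length(dosages_a) == length(dosages_b),
            length(dosages_a) == length(allele_freqs))
  use <- !is.na(dosages_a) & !is.na(dosages_b) &
    allele_freqs > 0 & allele_freqs < 1
  if (sum(use) < min_overlap) {
    warning("unevaluable pair: fewer than ", min_overlap,
            " overlapping informative variants")
    return(NA_real_)
  }
  a <- dosages_a[use]; b <- dosages_b[use]; p <- allele_freqs[use]
  ibs <- 2 - abs(a - b)
  ex <- ibs_expectations(p, if (is.null(n_obs)) NULL else n_obs[use])
  n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
  P0 <- n0 / sum(ex$e0_ibd0)
  P1 <- (n1 - P0 * sum(ex$e1_ibd0)) / sum(ex$e1_ibd1)
  P2 <- (n2 - P0 * sum(ex$e2_ibd0) - P1 * sum(ex$e2_ibd1)) / length(p)
  P <- pmax(c(P0, P1, P2), 0)
  P <- P / sum(P)
  min(1, max(0, P[3] + 0.5 * P[2]))
}

# All-pairs PI_HAT via indicator cross-products; returns a data.frame of
# pairs exceeding `threshold`. Used inside sample_qc on pruned variants.
pihat_pairs <- function(dosage, allele_freqs, threshold = 0.25,
                        n_obs = NULL) {
  ok <- allele_freqs > 0 & allele_freqs < 1 & !is.na(allele_freqs)
  dosage <- dosage[, ok, drop = FALSE]
  p <- allele_freqs[ok]
  if (!is.null(n_obs)) n_obs <- n_obs[ok]
  n <- nrow(dosage)
  if (n < 2 || ncol(dosage) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      pihat = numeric(0), stringsAsFactors = FALSE))
  }
  A0 <- (!is.na(dosage) & dosage == 0) * 1
  A1 <- (!is.na(dosage) & dosage == 1) * 1
  A2 <- (!is.na(dosage) & dosage == 2) * 1
  Mm <- (!is.na(dosage)) * 1
  N2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  N0 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  NN <- tcrossprod(Mm)
  N1 <- NN - N2 - N0
  ex <- ibs_expectations(p, n_obs)
  s0 <- sum(ex$e0_ibd0); s10 <- sum(ex$e1_ibd0); s20 <- sum(ex$e2_ibd0)
  s11 <- sum(ex$e1_ibd1); s21 <- sum(ex$e2_ibd1)
  m <- length(p)
  frac <- NN / m # overlap fraction scales the expectations
  P0 <- N0 / (s0 * frac)
  P1 <- (N1 - P0 * s10 * frac) / (s11 * frac)
  P2 <- (N2 - P0 * s20 * frac - P1 * s21 * frac) / NN
  P0 <- pmax(P0, 0); P1 <- pmax(P1, 0); P2 <- pmax(P2, 0)
  tot <- P0 + P1 + P2
  pihat <- pmin(pmax((P2 + 0.5 * P1) / tot, 0), 1)
  idx <- which(upper.tri(pihat) & pihat > threshold, arr.ind = TRUE)
  data.frame(a = rownames(dosage)[idx[, 1]],
             b = rownames(dosage)[idx[, 2]],
             pihat = pihat[idx], stringsAsFactors = FALSE)
}

qc_report_row <- function(step, removed, remaining) {
  data.frame(step = step, n_removed = length(removed),
             n_remaining = remaining, stringsAsFactors = FALSE)
}

#' Age- and sex-matched control selection
#'
#' Greedy nearest-age matching without replacement: cases are processed in
#' input order; for each case, `ratio` controls of identical sex with the
#' smallest absolute age difference are taken from the pool, ties broken
#' by pool order after a seeded shuffle.
#'
#' @param cases,pool sample tables (`id, reported_sex, age`); pool must be
#'   disjoint from cases.
#' @param ratio controls per case.
#' @param seed integer seed for the tie-breaking shuffle.
#' @return character vector of selected control ids.
#' @export
match_controls <- function(cases, pool, ratio = 1, seed = 1L) {
  if (any(pool$id %in% cases$id)) stop("pool must be disjoint from cases")
  for (s in unique(cases$reported_sex)) {
    need <- ratio * sum(cases$reported_sex == s)
    have <- sum(pool$reported_sex == s)
    if (have < need) {
      stop(sprintf("insufficient pool for sex stratum %s: need %d, have %d",
                   s, need, have))
    }
  }
  set.seed(as.integer(seed))
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  avail <- rep(TRUE, nrow(pool))
  out <- character(0)
  for (i in seq_len(nrow(cases))) {
    for (r in seq_len(ratio)) {
      elig <- which(avail & pool$reported_sex == cases$reported_sex[i])
      j <- elig[which.min(abs(pool$age[elig] - cases$age[i]))]
      avail[j] <- FALSE
      out <- c(out, pool$id[j])
    }
  }
  out
}

#' Sample-level QC cascade
#'
#' Applies, in order: (1) removal of samples whose reported and genetic
#' sex disagree; (2) per-sample call-rate filter; (3) removal of
#' inbreeding-coefficient outliers, where `F` and its mean/SD bounds are
#' computed on the samples surviving the call-rate step; (4) for each
#' duplicate/related pair with `PI_HAT > pihat_max` (method of moments on
#' variants LD-pruned at r^2 = 0.2), removal of the member with the higher
#' missingness rate. Dosage values of retained samples are never altered.
#'
#' @param gm a [geno_matrix()].
#' @param samples sample table with `id, reported_sex, genetic_sex`.
#' @param call_rate_min minimum per-sample call rate (default 0.94).
#' @param inbreed_sd F outlier bound in SDs of the mean (default 6).
#' @param pihat_max relatedness threshold (default 0.25).
#' @param prune_r2 LD-pruning threshold for the relatedness marker set.
#' @return list: `retained_ids`, `report` (per-step data.frame), `removed`
#'   (named list of removed ids per step), `pairs` (flagged related pairs).
#' @export
sample_qc <- function(gm, samples, call_rate_min = 0.94, inbreed_sd = 6,
                      pihat_max = 0.25, prune_r2 = 0.2) {
  stopifnot(inherits(gm, "geno_matrix"))
  ids <- rownames(gm$dosage)
  samples <- samples[match(ids, samples$id), , drop = FALSE]
  report <- list()
  removed <- list()

  gs <- samples$genetic_sex
  mism <- ids[!is.na(gs) & gs != "unknown" & gs != samples$reported_sex]
  keep <- setdiff(ids, mism)
  removed$sex_mismatch <- mism
  report[[1]] <- qc_report_row("sex_mismatch", mism, length(keep))

  cr <- sample_call_rate(gm)[keep]
  low <- names(cr)[cr < call_rate_min]
  keep <- setdiff(keep, low)
  removed$call_rate <- low
  report[[2]] <- qc_report_row("call_rate", low, length(keep))

  sub <- gm$dosage[keep, , drop = FALSE]
  freqs <- colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  fv <- vapply(keep, function(id) {
    inbreeding_f(sub[id, poly], freqs[poly])
  }, numeric(1))
  mu <- mean(fv, na.rm = TRUE); sdv <- stats::sd(fv, na.rm = TRUE)
  outl <- if (is.na(sdv) || sdv == 0) character(0) else
    keep[!is.na(fv) & abs(fv - mu) > inbreed_sd * sdv]
  keep <- setdiff(keep, outl)
  removed$inbreeding <- outl
  report[[3]] <- qc_report_row("inbreeding", outl, length(keep))

  sub <- gm$dosage[keep, , drop = FALSE]
  freqs <- colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
  pruned <- ld_prune(gm_subset(gm, samples = keep), r2_max = prune_r2)
  nobs <- colSums(!is.na(sub))
  pairs <- pihat_pairs(sub[, pruned, drop = FALSE],
                       freqs[pruned], threshold = pihat_max,
                       n_obs = nobs[pruned])
  rel_rm <- character(0)
  if (nrow(pairs)) {
    pairs <- pairs[order(-pairs$pihat), , drop = FALSE]
    miss <- 1 - sample_call_rate(gm)[keep]
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$a[i]; b <- pairs$b[i]
      if (a %in% rel_rm || b %in% rel_rm) next
      worse <- if (miss[a] >= miss[b]) a else b
      rel_rm <- c(rel_rm, worse)
    }
  }
  keep <- setdiff(keep, rel_rm)
  removed$relatedness <- rel_rm
  report[[4]] <- qc_report_row("relatedness", rel_rm, length(keep))

  if (!length(keep)) stop("sample QC removed every sample")
  list(retained_ids = keep, report = do.call(rbind, report),
       removed = removed, pairs = pairs)
}

NONAUTOSOME <- c("X", "Y", "MT", "M", "CHRX", "CHRY", "CHRMT", "CHRM",
                 "23", "24", "25", "26")

#' Variant-level QC cascade
#'
#' Applies, in order: exclusion of non-autosomal variants (X/Y/MT
#' labels); per-variant call-rate filter; removal of monomorphic
#' variants; removal of variants with case/control missing-rate
#' difference above `missdiff_max`; removal of variants violating
#' Hardy-Weinberg equilibrium in controls at `hwe_p_min` (exact test);
#' and strand flipping, which rewrites ref/alt of reverse-strand variants
#' to their reverse complements (dosages untouched). Palindromic (A/T,
#' C/G) variants marked reverse-strand cannot be flipped meaningfully and
#' are flagged for the scoring policy to handle.
#'
#' @param gm a [geno_matrix()] (typically already sample-QC'd).
#' @param samples sample table with `id, status` (`"case"`/`"control"`).
#' @param autosomes_only drop X/Y/MT variants (default TRUE).
#' @param call_rate_min minimum variant call rate (default 0.95).
#' @param missdiff_max maximum case-control missing-rate difference.
#' @param hwe_p_min exact-HWE p-value floor in controls (default 1e-6).
#' @return list: `retained_ids`, `variants` (updated table, strand
#'   flipped), `report`, `removed` (per-step id lists),
#'   `palindromic_flagged`.
#' @export
variant_qc <- function(gm, samples, autosomes_only = TRUE,
                       call_rate_min = 0.95, missdiff_max = 0.05,
                       hwe_p_min = 1e-6) {
  stopifnot(inherits(gm, "geno_matrix"))
  samples <- samples[match(rownames(gm$dosage), samples$id), , drop = FALSE]
  if (!all(samples$status %in% c("case", "control"))) {
    stop("variant QC requires case/control status for every sample")
  }
  v <- gm$variants
  ids <- v$id
  report <- list()
  removed <- list()
  keep <- ids

  if (autosomes_only) {
    nonauto <- ids[toupper(v$chrom) %in% NONAUTOSOME]
    keep <- setdiff(keep, nonauto)
  } else {
    nonauto <- character(0)
  }
  removed$nonautosomal <- nonauto
  report[[1]] <- qc_report_row("nonautosomal", nonauto, length(keep))

  cr <- variant_call_rate(gm)[keep]
  low <- names(cr)[cr < call_rate_min]
  keep <- setdiff(keep, low)
  removed$call_rate <- low
  report[[2]] <- qc_report_row("call_rate", low, length(keep))

  f <- gm_freq(gm)[keep]
  mono <- keep[is.nan(f) | f == 0 | f == 1]
  keep <- setdiff(keep, mono)
  removed$monomorphic <- mono
  report[[3]] <- qc_report_row("monomorphic", mono, length(keep))

  case_ids <- samples$id[samples$status == "case"]
  ctrl_ids <- samples$id[samples$status == "control"]
  if (!length(case_ids) || !length(ctrl_ids)) {
    stop("variant QC needs both cases and controls")
  }
  miss_case <- colMeans(is.na(gm$dosage[case_ids, keep, drop = FALSE]))
  miss_ctrl <- colMeans(is.na(gm$dosage[ctrl_ids, keep, drop = FALSE]))
  md <- keep[abs(miss_case - miss_ctrl) > missdiff_max]
  keep <- setdiff(keep, md)
  removed$missdiff <- md
  report[[4]] <- qc_report_row("missdiff", md, length(keep))

  dctrl <- gm$dosage[ctrl_ids, keep, drop = FALSE]
  n_aa <- colSums(dctrl == 0, na.rm = TRUE)
  n_het <- colSums(dctrl == 1, na.rm = TRUE)
  n_AA <- colSums(dctrl == 2, na.rm = TRUE)
  hp <- mapply(function(a, h, b) {
    if (a + h + b == 0) NA_real_ else hwe_exact_p(a, h, b)
  }, n_AA, n_het, n_aa)
  hw <- keep[!is.na(hp) & hp < hwe_p_min]
  keep <- setdiff(keep, hw)
  removed$hwe <- hw
  report[[5]] <- qc_report_row("hwe_controls", hw, length(keep))

  vkeep <- v[match(keep, v$id), , drop = FALSE]
  flip <- vkeep$strand == "-"
  pal_flag <- vkeep$id[flip & is_palindromic(vkeep$ref, vkeep$alt)]
  if (any(flip)) {
    vkeep$ref[flip] <- revcomp(vkeep$ref[flip])
    vkeep$alt[flip] <- revcomp(vkeep$alt[flip])
    vkeep$strand[flip] <- "+"
  }
  report[[6]] <- qc_report_row("strand_flip", character(0), length(keep))
  rownames(vkeep) <- NULL

  list(retained_ids = keep, variants = vkeep,
       report = do.call(rbind, report), removed = removed,
       palindromic_flagged = pal_flag)
}
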