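make_variants <- function(ref, alt, chrom = "chr1",
                          pos = seq(1e5, by = 1e4,
                                    length.out = length(ref))) {
  data.frame(id = paste0("v", seq_along(ref)), chrom = chrom, pos = pos,
             ref = ref, alt = alt, strand = "+", stringsAsFactors = FALSE)
}

test_that("harmonization resolves swaps, strand flips and palindromes", {
  v <- make_variants(ref = c("A", "A", "A", "A", "A"),
                     alt = c("G", "G", "G", "G", "T"))
  ss <- data.frame(
    id = paste0("x", 1:5), chrom = "chr1", pos = v$pos,
    effect_allele = c("G", "A", "C", "T", "A"),
    other_allele = c("A", "G", "T", "C", "T"),
    beta = c(0.5, 0.5, 0.5, 0.5, 0.5), p = rep(0.01, 5),
    stringsAsFactors = FALSE)
  # 1: direct; 2: swapped (negate); 3: strand-flipped direct (C/T -> G/A);
  # 4: strand-flipped swapped (negate); 5: palindromic (excluded)
  h <- harmonize_sumstats(ss, v)
  expect_equal(h$sumstats$variant_id, paste0("v", 1:4))
  expect_equal(h$sumstats$beta, c(0.5, -0.5, 0.5, -0.5))
  expect_true(all(h$sumstats$effect_allele == "G"))
  expect_equal(h$ledger$n[h$ledger$reason == "palindromic"], 1)

  # unmatched position and mismatched alleles are ledgered
  ss2 <- data.frame(id = "y", chrom = "chr1", pos = 999,
                    effect_allele = "A", other_allele = "G",
                    beta = 1, p = 0.5, stringsAsFactors = FALSE)
  h2 <- harmonize_sumstats(ss2, v)
  expect_equal(nrow(h2$sumstats), 0)
  expect_equal(h2$ledger$n[h2$ledger$reason == "absent"], 1)
})

test_that("simulator-generated swaps and flips are fully recovered", {
  cc <- small_cohort(seed = 40, n = 500, h2 = 0.4, r = 0,
                     n_blocks = 20, block_size = 10)
  ss_clean <- sim_training_sumstats(cc$truth, cc$gm, n_train = 5e4,
                                    seed = 5)
  ss_mixed <- sim_training_sumstats(cc$truth, cc$gm, n_train = 5e4,
                                    seed = 5, swap_frac = 0.3,
                                    flip_frac = 0.2)
  h <- harmonize_sumstats(ss_mixed, cc$gm$variants)
  hc <- harmonize_sumstats(ss_clean, cc$gm$variants)
  # every non-palindromic variant comes back with the correct sign
  common <- intersect(h$sumstats$variant_id, hc$sumstats$variant_id)
  expect_equal(h$sumstats$beta[match(common, h$sumstats$variant_id)],
               hc$sumstats$beta[match(common, hc$sumstats$variant_id)],
               tolerance = 1e-12)
  # swapped-allele fraction 1.0: betas recovered, matching the clean run
  ss_all <- sim_training_sumstats(cc$truth, cc$gm, n_train = 5e4,
                                  seed = 5, swap_frac = 1)
  h_all <- harmonize_sumstats(ss_all, cc$gm$variants)
  common2 <- intersect(h_all$sumstats$variant_id, hc$sumstats$variant_id)
  expect_equal(
    h_all$sumstats$beta[match(common2, h_all$sumstats$variant_id)],
    hc$sumstats$beta[match(common2, hc$sumstats$variant_id)],
    tolerance = 1e-12)
})

test_that("LD pruning keeps independents, drops duplicates, matches oracle", {
  gm <- random_gm(n = 200, m = 10, n_chrom = 1, seed = 50)
  expect_identical(ld_prune(gm, r2_max = 0.99), gm$variants$id)
  # duplicated variant pair: exactly one survives
  d <- gm$dosage
  d[, 2] <- d[, 1]
  gm2 <- geno_matrix(d, gm$variants)
  kept <- ld_prune(gm2, r2_max = 0.5)
  expect_equal(sum(c("v001", "v002") %in% kept), 1)
  # randomized fixtures against the brute-force oracle
  for (s in 1:5) {
    gmr <- random_gm(n = 150, m = 15, n_chrom = 2, miss = 0.02,
                     seed = 200 + s, spacing = 30000)
    mine <- ld_prune(gmr, window_kb = 100, step = 5, r2_max = 0.15)
    orc <- oracle_prune(gmr$variants, gmr$dosage,
                        window_kb = 100, step = 5, r2_max = 0.15)
    expect_identical(mine, orc)
  }
})

test_that("C+T selection respects thresholds and grid monotonicity", {
  cc <- small_cohort(seed = 60, n = 800, h2 = 0.5, r = 0.6,
                     n_blocks = 10, block_size = 8, n_causal = 5)
  ss <- sim_training_sumstats(cc$truth, cc$gm, n_train = 5e4, seed = 6)
  h <- harmonize_sumstats(ss, cc$gm$variants)$sumstats
  # degenerate thresholds: everything is its own index
  m_all <- ct_select(h, cc$gm, r2_thresh = 1 - 1e-9, p_thresh = 1)
  expect_setequal(m_all$variant_ids, h$variant_id)
  # stringent p on null-ish sumstats: near-empty model
  cc0 <- small_cohort(seed = 61, n = 500, h2 = 0, r = 0,
                      n_blocks = 10, block_size = 8, n_causal = 0)
  ss0 <- sim_training_sumstats(cc0$truth, cc0$gm, n_train = 5e4, seed = 7)
  h0 <- harmonize_sumstats(ss0, cc0$gm$variants)$sumstats
  suppressMessages(
    m0 <- ct_select(h0, cc0$gm, r2_thresh = 0.5, p_thresh = 5e-8))
  expect_lte(length(m0$variant_ids), 1)
  # monotone in p_thresh at fixed r2, and in r2 at fixed p
  sizes <- sapply(c(1e-4, 1e-2, 0.5, 1), function(pt) {
    length(ct_select(h, cc$gm, r2_thresh = 0.4, p_thresh = pt)$variant_ids)
  })
  expect_true(all(diff(sizes) >= 0))
  sizes_r <- sapply(c(0.05, 0.4, 0.9), function(r2) {
    length(ct_select(h, cc$gm, r2_thresh = r2, p_thresh = 1)$variant_ids)
  })
  expect_true(all(diff(sizes_r) >= 0))
})

test_that("SNP-set restriction equals brute-force interval membership", {
  gm <- random_gm(n = 30, m = 12, n_chrom = 2, seed = 70, spacing = 20000)
  v <- gm$variants
  w <- rnorm(12)
  model <- prs_model(v$id, w, mode = "weighted")
  # identity and empty restrictions
  all_r <- data.frame(chrom = unique(v$chrom), start = 1, end = 1e9)
  expect_identical(
    restrict_snpset(model, regions = all_r, variants = v)$variant_ids,
    model$variant_ids)
  none_r <- data.frame(chrom = "chr9", start = 1, end = 2)
  expect_message(
    empty <- restrict_snpset(model, regions = none_r, variants = v),
    "empty")
  expect_length(empty$variant_ids, 0)
  # random intervals against the oracle
  set.seed(71)
  for (i in 1:5) {
    regions <- data.frame(
      chrom = sample(unique(v$chrom), 3, replace = TRUE),
      start = sample(seq(1e5, 3e5, by = 1e4), 3))
    regions$end <- regions$start + sample(c(0, 2e4, 5e4), 3, replace = TRUE)
    r <- restrict_snpset(model, regions = regions, variants = v)
    expect_setequal(r$variant_ids, oracle_restrict(v, regions))
    # weight alignment preserved
    expect_equal(r$weights, w[match(r$variant_ids, v$id)])
  }
  # id-list restriction
  r2 <- restrict_snpset(model, ids = c("v003", "v007"))
  expect_identical(r2$variant_ids, c("v003", "v007"))
})

test_that("PRS scoring matches its closed forms to 1e-12", {
  v1 <- make_variants("A", "G")
  gm1 <- geno_matrix(matrix(2L, 1, 1), v1, sample_ids = "s1")
  m1 <- prs_model("v1", log(2))
  expect_equal(compute_prs(m1, gm1)$prs, log(2), tolerance = 1e-12)

  v3 <- make_variants(rep("A", 3), rep("G", 3))
  gm3 <- geno_matrix(matrix(c(0L, 1L, 2L), 1, 3), v3, sample_ids = "s1")
  mw <- prs_model(paste0("v", 1:3), rep(1, 3))
  mu <- prs_model(paste0("v", 1:3), mode = "unweighted")
  expect_equal(compute_prs(mw, gm3)$prs, 0.5, tolerance = 1e-12)
  expect_equal(compute_prs(mw, gm3)$prs, compute_prs(mu, gm3)$prs,
               tolerance = 1e-12)
  # all weights = c is c times the unweighted score (complete data)
  mc <- prs_model(paste0("v", 1:3), rep(2.5, 3))
  expect_equal(compute_prs(mc, gm3)$prs, 2.5 * compute_prs(mu, gm3)$prs,
               tolerance = 1e-12)
})

test_that("PRS scoring handles missingness exactly like the naive loop", {
  gm <- random_gm(n = 40, m = 10, seed = 80, miss = 0.15)
  w <- rnorm(10)
  model <- prs_model(gm$variants$id, w)
  got <- compute_prs(model, gm)
  orc <- oracle_prs(gm$variants$id, w, gm$dosage)
  expect_equal(got$prs, unname(orc), tolerance = 1e-12)
  # M_j = 0 gives a flagged missing score
  d <- gm$dosage; d[1, ] <- NA
  gm0 <- geno_matrix(d, gm$variants)
  expect_true(is.na(compute_prs(model, gm0)$prs[1]))
  # sample with some missing: M_j counts only observed model variants
  expect_equal(got$m_nonmissing, unname(rowSums(!is.na(gm$dosage))))
})

test_that("scores are invariant to reordering, absent variants and swaps", {
  gm <- random_gm(n = 30, m = 8, seed = 90, miss = 0.1)
  w <- rnorm(8)
  model <- prs_model(gm$variants$id, w)
  base <- compute_prs(model, gm)
  # variant reorder
  perm <- sample(8)
  m2 <- prs_model(gm$variants$id[perm], w[perm])
  expect_equal(compute_prs(m2, gm)$prs, base$prs, tolerance = 1e-12)
  # sample reorder
  gm2 <- gm_subset(gm, samples = rev(rownames(gm$dosage)))
  expect_equal(compute_prs(model, gm2)$prs, rev(base$prs),
               tolerance = 1e-12)
  # appending an everywhere-missing variant changes nothing
  d <- cbind(gm$dosage, extra = NA_integer_)
  v <- rbind(gm$variants,
             data.frame(id = "extra", chrom = "chr1", pos = 9e6,
                        ref = "A", alt = "G", strand = "+"))
  gme <- geno_matrix(d, v)
  me <- prs_model(c(gm$variants$id, "extra"), c(w, 5))
  got <- compute_prs(me, gme)
  expect_equal(got$prs, base$prs, tolerance = 1e-12)
  expect_equal(got$m_nonmissing, base$m_nonmissing)
  # model variants absent from genotypes are dropped with a warning
  mab <- prs_model(c(gm$variants$id, "ghost"), c(w, 1))
  expect_warning(gw <- compute_prs(mab, gm), "absent")
  expect_equal(gw$prs, base$prs, tolerance = 1e-12)

  # allele-swap invariance: flipping ref/alt with dosage 2-g and negated
  # weight leaves scores equal up to the constant sum(w)/(2 M_j) shift
  # absorbed by the harmonization convention; concretely, scoring the
  # swapped representation after harmonization equals the original
  v1 <- make_variants("A", "G")
  g <- matrix(c(0L, 1L, 2L), 3, 1)
  gm1 <- geno_matrix(g, v1, sample_ids = paste0("s", 1:3))
  ss <- data.frame(id = "x", chrom = "chr1", pos = v1$pos,
                   effect_allele = "A", other_allele = "G",
                   beta = -0.7, p = 0.1, stringsAsFactors = FALSE)
  h <- harmonize_sumstats(ss, v1)$sumstats
  m_h <- prs_model(h$variant_id, h$beta)
  direct <- prs_model("v1", 0.7) # the unswapped representation
  expect_equal(compute_prs(m_h, gm1)$prs, compute_prs(direct, gm1)$prs,
               tolerance = 1e-12)
})
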