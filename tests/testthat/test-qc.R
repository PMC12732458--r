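test_that("exact HWE p matches full enumeration and is label-symmetric", {
  # closed-form / boundary cases
  expect_equal(hwe_exact_p(100, 0, 0), 1) # monomorphic: single configuration
  expect_equal(hwe_exact_p(0, 50, 0), oracle_hwe_enum(0, 50, 0))
  # label swap symmetry
  expect_equal(hwe_exact_p(12, 30, 8), hwe_exact_p(8, 30, 12))
  # random sweep against the enumeration oracle
  set.seed(42)
  for (i in 1:40) {
    n <- sample(1:60, 1)
    cnt <- as.vector(stats::rmultinom(1, n, runif(3)))
    expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe_enum(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12,
                 label = paste("table", paste(cnt, collapse = "/")))
  }
  expect_error(hwe_exact_p(0, 0, 0), "at least one")
  expect_error(hwe_exact_p(-1, 2, 3), "non-negative")
})

test_that("inbreeding coefficient has its closed forms and null behavior", {
  # fully homozygous at p = 0.5: F = 1
  expect_equal(inbreeding_f(rep(c(0, 2), 50), rep(0.5, 100)), 1)
  # fully heterozygous at p = 0.5 across 100 variants: (0 - 50)/(100 - 50)
  expect_equal(inbreeding_f(rep(1, 100), rep(0.5, 100)), -1)
  # HWE sample: F near 0
  set.seed(1)
  p <- runif(10000, 0.1, 0.5)
  g <- rbinom(10000, 2, p)
  expect_lt(abs(inbreeding_f(g, p)), 0.03)
  # missing genotypes excluded from both sums
  g2 <- c(1, NA, 1, NA)
  expect_equal(inbreeding_f(g2, rep(0.5, 4)), (0 - 1) / (2 - 1))
})

test_that("PI_HAT separates duplicates, relatives and unrelateds", {
  set.seed(2)
  m <- 5000
  p <- runif(m, 0.1, 0.5)
  h <- function() rbinom(m, 1, p) # one haplotype
  a <- h() + h()
  b <- h() + h()
  expect_lt(ibd_pihat(a, b, p), 0.1) # independent
  expect_gt(ibd_pihat(a, a, p), 0.9) # duplicate
  # parent-offspring: child shares exactly one haplotype with the parent
  shared <- h()
  parent <- shared + h()
  child <- shared + h()
  po <- ibd_pihat(parent, child, p)
  expect_gt(po, 0.4)
  expect_lt(po, 0.6)
  # agrees with the independent oracle
  expect_equal(po, oracle_pihat(parent, child, p), tolerance = 1e-12)
  expect_warning(ibd_pihat(a[1:50], b[1:50], p[1:50]), "unevaluable")
})

test_that("control matching is greedy nearest-age within sex", {
  cases <- data.frame(id = c("c1", "c2"), reported_sex = c("F", "F"),
                      age = c(40, 60), stringsAsFactors = FALSE)
  pool <- data.frame(id = paste0("p", 1:4), reported_sex = "F",
                     age = c(41, 59, 70, 75), stringsAsFactors = FALSE)
  sel <- match_controls(cases, pool, ratio = 1, seed = 1)
  expect_setequal(pool$age[match(sel, pool$id)], c(41, 59))

  # perfect copies give zero age gap
  pool2 <- cases; pool2$id <- c("q1", "q2")
  sel2 <- match_controls(cases, pool2, ratio = 1, seed = 3)
  expect_setequal(pool2$age[match(sel2, pool2$id)], cases$age)

  # hard sex constraint
  cases_m <- data.frame(id = "m1", reported_sex = "M", age = 50,
                        stringsAsFactors = FALSE)
  pool3 <- data.frame(id = c("f1", "m2"), reported_sex = c("F", "M"),
                      age = c(50, 65), stringsAsFactors = FALSE)
  expect_identical(match_controls(cases_m, pool3, 1, 1), "m2")
  expect_error(match_controls(cases_m, pool3, ratio = 2, seed = 1),
               "stratum M")

  # matched groups show no significant demographic differences
  cc <- small_cohort(seed = 20, n = 2000, prev = 0.15)
  cases4 <- cc$samples[cc$samples$status == "case", ]
  pool4 <- cc$samples[cc$samples$status == "control", ]
  sel4 <- match_controls(cases4, pool4, ratio = 1, seed = 5)
  ctrl4 <- pool4[match(sel4, pool4$id), ]
  expect_gt(t.test(cases4$age, ctrl4$age)$p.value, 0.05)
  expect_identical(table(cases4$reported_sex), table(ctrl4$reported_sex))
})

test_that("sample QC removes exactly the planted defects, in order", {
  # the relatedness moment estimator needs a genome-wide marker count for
  # its null noise to stay clear of the 0.25 threshold
  cc <- small_cohort(seed = 30, n = 300, n_blocks = 120, block_size = 20,
                     r = 0.3, prev = 0.3)
  def <- sim_qc_defects(cc$gm, cc$samples, seed = 4,
                        rates = list(sex_mismatch = 0.02, low_call = 0.02,
                                     inbred = 0.01, duplicate = 0.01))
  led <- def$ledger
  qc <- sample_qc(def$genotypes, def$samples)
  expect_setequal(qc$removed$sex_mismatch,
                  led$item[led$kind == "sex_mismatch"])
  expect_setequal(qc$removed$call_rate, led$item[led$kind == "low_call"])
  expect_setequal(qc$removed$inbreeding, led$item[led$kind == "inbred"])
  # the higher-missingness member (the planted copy) goes
  expect_setequal(qc$removed$relatedness, led$item[led$kind == "duplicate"])
  # cascade monotonicity
  expect_true(all(diff(qc$report$n_remaining) <= 0))
  # clean cohort: zero removals; and idempotence on QC'd output
  clean <- sample_qc(cc$gm, cc$samples)
  expect_length(unlist(clean$removed), 0)
  gm2 <- gm_subset(def$genotypes, samples = qc$retained_ids)
  s2 <- def$samples[def$samples$id %in% qc$retained_ids, ]
  again <- sample_qc(gm2, s2)
  expect_length(unlist(again$removed), 0)
})

test_that("variant QC filters in the stated order and flips strands", {
  n <- 400
  set.seed(6)
  status <- rep(c("case", "control"), c(100, 300))
  p <- runif(8, 0.2, 0.5)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  # v5 monomorphic; v6 differentially missing (20% of cases only);
  # v7 HWE-violating in controls; v8 on chromosome X
  d[, 5] <- 0
  d[sample(1:100, 20), 6] <- NA
  d[, 7] <- rbinom(n, 1, 0.5) * 2 # no heterozygotes at all
  variants <- data.frame(
    id = paste0("v", 1:8),
    chrom = c(rep("chr1", 7), "X"),
    pos = seq(1e5, by = 5e4, length.out = 8),
    ref = c(rep("A", 7), "A"), alt = c(rep("G", 6), "C", "G"),
    strand = c(rep("+", 3), "-", rep("+", 4)),
    stringsAsFactors = FALSE)
  gm <- geno_matrix(d, variants, sample_ids = sprintf("s%03d", 1:n))
  samples <- data.frame(id = rownames(gm$dosage), status = status,
                        stringsAsFactors = FALSE)
  qc <- variant_qc(gm, samples)
  expect_identical(qc$removed$nonautosomal, "v8")
  expect_identical(qc$removed$monomorphic, "v5")
  expect_identical(qc$removed$missdiff, "v6")
  expect_identical(qc$removed$hwe, "v7")
  # oracle confirms the HWE violator is beyond the threshold in controls
  dc <- d[status == "control", 7]
  expect_lt(oracle_hwe_enum(sum(dc == 2), sum(dc == 1), sum(dc == 0)), 1e-6)
  # strand flip rewrote ref/alt of the reverse-strand variant
  v4 <- qc$variants[qc$variants$id == "v4", ]
  expect_identical(c(v4$ref, v4$alt, v4$strand), c("T", "C", "+"))
  # monotone remaining counts, dosages untouched for retained variants
  expect_true(all(diff(qc$report$n_remaining) <= 0))
  # idempotence
  gm2 <- gm_subset(gm, variants = qc$retained_ids)
  gm2$variants <- qc$variants
  qc2 <- variant_qc(gm2, samples)
  expect_length(unlist(qc2$removed), 0)
})

test_that("variant QC flags palindromic reverse-strand variants", {
  d <- matrix(rbinom(200, 2, 0.4), 100, 2)
  v <- data.frame(id = c("a", "b"), chrom = "chr1", pos = c(100, 200),
                  ref = c("A", "A"), alt = c("T", "G"),
                  strand = c("-", "-"), stringsAsFactors = FALSE)
  gm <- geno_matrix(d, v, sample_ids = paste0("s", 1:100))
  samples <- data.frame(id = rownames(gm$dosage),
                        status = rep(c("case", "control"), 50),
                        stringsAsFactors = FALSE)
  qc <- variant_qc(gm, samples)
  expect_identical(qc$palindromic_flagged, "a")
})
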