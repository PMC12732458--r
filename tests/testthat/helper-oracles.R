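# Independent brute-force reference implementations. These are written
# as naive loops from the definitions and deliberately share no code
# with the package internals they check.

# Exact HWE p by full enumeration over heterozygote counts compatible
# with the observed allele count, each configuration's probability from
# the multinomial/hypergeometric identity evaluated with exact choose().
oracle_hwe_enum <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- sapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- n - a - h
    exp(lchoose(n, a) + lchoose(n - a, h) + h * log(2) - lchoose(2 * n, nA))
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Greedy clumping by direct restatement of the rule.
oracle_clump <- function(stats, variants, dosage, p1, p2, window_kb, r2_min) {
  df <- merge(stats, variants, by.x = "variant_id", by.y = "id")
  df <- df[order(df$p, df$chrom, df$pos), ]
  assigned <- character(0)
  clumps <- list()
  repeat {
    cand <- df[!(df$variant_id %in% assigned) & !is.na(df$p) & df$p <= p1, ]
    if (!nrow(cand)) break
    ix <- cand[1, ]
    assigned <- c(assigned, ix$variant_id)
    members <- character(0)
    for (j in seq_len(nrow(df))) {
      vj <- df[j, ]
      if (vj$variant_id %in% assigned) next
      if (vj$chrom != ix$chrom) next
      if (abs(vj$pos - ix$pos) > window_kb * 1000) next
      if (is.na(vj$p) || vj$p > p2) next
      a <- dosage[, ix$variant_id]; b <- dosage[, vj$variant_id]
      ok <- !is.na(a) & !is.na(b)
      r2 <- if (sum(ok) < 2 || sd(a[ok]) == 0 || sd(b[ok]) == 0) 0 else
        cor(a[ok], b[ok])^2
      if (r2 >= r2_min) members <- c(members, vj$variant_id)
    }
    assigned <- c(assigned, members)
    clumps[[ix$variant_id]] <- members
  }
  clumps
}

# Sliding-window greedy pruning by direct restatement.
oracle_prune <- function(variants, dosage, window_kb, step, r2_max) {
  keep <- setNames(rep(TRUE, nrow(variants)), variants$id)
  maf <- apply(dosage, 2, function(g) {
    f <- mean(g, na.rm = TRUE) / 2
    min(f, 1 - f)
  })
  for (ch in unique(variants$chrom)) {
    vv <- variants[variants$chrom == ch, ]
    start <- 1
    while (start <= nrow(vv)) {
      w <- vv[vv$pos >= vv$pos[start] &
                vv$pos <= vv$pos[start] + window_kb * 1000, ]
      repeat {
        act <- w$id[keep[w$id]]
        if (length(act) < 2) break
        best <- NULL; best_r2 <- r2_max
        for (i in 1:(length(act) - 1)) for (j in (i + 1):length(act)) {
          a <- dosage[, act[i]]; b <- dosage[, act[j]]
          ok <- !is.na(a) & !is.na(b)
          r2 <- if (sum(ok) < 2 || sd(a[ok]) == 0 || sd(b[ok]) == 0) 0 else
            cor(a[ok], b[ok])^2
          if (r2 > best_r2) { best_r2 <- r2; best <- c(act[i], act[j]) }
        }
        if (is.null(best)) break
        m1 <- maf[best[1]]; m2 <- maf[best[2]]
        drop <- if (m1 < m2) best[1] else if (m2 < m1) best[2] else {
          p1 <- vv$pos[vv$id == best[1]]; p2 <- vv$pos[vv$id == best[2]]
          if (p1 > p2) best[1] else best[2]
        }
        keep[drop] <- FALSE
      }
      start <- start + step
    }
  }
  names(keep)[keep]
}

# Per-sample double-loop PRS from the score formula.
oracle_prs <- function(variant_ids, weights, dosage) {
  sapply(rownames(dosage), function(s) {
    num <- 0; m <- 0
    for (i in seq_along(variant_ids)) {
      g <- dosage[s, variant_ids[i]]
      if (!is.na(g)) {
        num <- num + weights[i] * g
        m <- m + 1
      }
    }
    if (m == 0) NA_real_ else num / (2 * m)
  })
}

# Interval membership by direct scan.
oracle_restrict <- function(variants, regions) {
  hits <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(regions))) {
      if (variants$chrom[i] == regions$chrom[j] &&
          variants$pos[i] >= regions$start[j] &&
          variants$pos[i] <= regions$end[j]) hits[i] <- TRUE
    }
  }
  variants$id[hits]
}

# Exhaustive AUC pair counting with half-credit ties.
oracle_auc <- function(y, s) {
  cases <- s[y == 1]; ctrls <- s[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# Method-of-moments PI_HAT for one pair, written from the IBS/IBD
# expectation identities.
oracle_pihat <- function(a, b, p) {
  ok <- !is.na(a) & !is.na(b) & p > 0 & p < 1
  a <- a[ok]; b <- b[ok]; p <- p[ok]; q <- 1 - p
  ibs <- 2 - abs(a - b)
  P0 <- sum(ibs == 0) / sum(2 * p^2 * q^2)
  P1 <- (sum(ibs == 1) - P0 * sum(4 * p^3 * q + 4 * p * q^3)) /
    sum(2 * p^2 * q + 2 * p * q^2)
  P2 <- (sum(ibs == 2) - P0 * sum(p^4 + q^4 + 4 * p^2 * q^2) -
           P1 * sum(p^3 + q^3 + p^2 * q + p * q^2)) / length(p)
  P <- pmax(c(P0, P1, P2), 0); P <- P / sum(P)
  min(1, max(0, P[3] + P[2] / 2))
}
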