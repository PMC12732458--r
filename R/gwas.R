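#' Principal components of the genotype matrix
#'
#' Missing dosages are mean-imputed per variant, variants standardized to
#' mean 0 / unit variance (zero-variance variants dropped), and the
#' left singular vectors taken as scores, so score cross-products are the
#' identity. Each component's sign is fixed by making its
#' largest-magnitude variant loading positive.
#'
#' @param gm a [geno_matrix()].
#' @param k number of components; must not exceed the matrix rank.
#' @return data.frame: `sample_id`, `PC1..PCk` (orthonormal columns).
#' @export
compute_pcs <- function(gm, k = 10) {
  stopifnot(inherits(gm, "geno_matrix"))
  d <- gm$dosage
  n <- nrow(d)
  mu <- colMeans(d, na.rm = TRUE)
  x <- ifelse(is.na(d), matrix(mu, n, ncol(d), byrow = TRUE), d)
  sdv <- apply(x, 2, stats::sd)
  x <- scale(x[, sdv > 0, drop = FALSE])
  if (k > min(dim(x)) - 1) stop("k exceeds min(dim) - 1")
  sv <- svd(x, nu = k, nv = k)
  if (sum(sv$d > 1e-8) < k) stop("k exceeds the rank of the genotype matrix")
  scores <- sv$u
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  out <- data.frame(sample_id = rownames(d), scores,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("PC", seq_len(k))
  out
}

# One logistic fit y ~ X (X includes intercept). Returns beta/se for the
# last column plus convergence/separation flags.
logit_wald <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  p <- ncol(X)
  cf <- fit$coefficients
  ok <- fit$converged && !any(is.na(cf))
  if (ok) {
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (is.null(cov)) ok <- FALSE
  }
  if (!ok) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, flagged = TRUE))
  }
  beta <- cf[p]
  se <- sqrt(cov[p, p])
  # Wald statistics are meaningless under (quasi-)separation; the bound
  # is on the per-SD scale of the predictor so it is unit-invariant
  sdx <- stats::sd(X[, p])
  if (!is.finite(se) || se * sdx > 15 || abs(beta) * sdx > 15) {
    return(list(beta = beta, se = se, p = NA_real_, flagged = TRUE))
  }
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)), flagged = FALSE)
}

#' Per-variant covariate-adjusted logistic association
#'
#' For every variant with cohort MAF at least `maf_min`, fits
#' `status ~ covariates + dosage` by iteratively reweighted least squares
#' and reports the Wald statistics of the additive dosage term. Samples
#' with a missing dosage are dropped for that variant (complete-case;
#' `n_used` records the count). Non-converged or separated fits are
#' flagged with `p = NA`, never a fabricated value.
#'
#' @param gm a [geno_matrix()].
#' @param status binary status: `"case"`/`"control"` or 0/1, aligned with
#'   the genotype rows.
#' @param covariates data.frame (or NULL) of numeric covariates, e.g. age,
#'   sex, PCs; rows aligned with genotype rows.
#' @param maf_min variants below this cohort MAF are excluded.
#' @return data.frame: `variant_id, chrom, pos, a1, a2, maf, beta, se,
#'   odds_ratio, l95, u95, p, n_used, flagged` (a1 = effect allele = ALT).
#' @export
logistic_assoc <- function(gm, status, covariates = NULL, maf_min = 0.01) {
  stopifnot(inherits(gm, "geno_matrix"))
  y <- if (is.character(status) || is.factor(status)) {
    as.integer(as.character(status) == "case")
  } else as.integer(status)
  if (!all(y %in% c(0L, 1L))) stop("status must be binary")
  n <- nrow(gm$dosage)
  if (length(y) != n) stop("status length mismatch")
  C <- if (is.null(covariates)) NULL else {
    cm <- as.matrix(covariates[, setdiff(names(covariates), "sample_id"),
                               drop = FALSE])
    if (anyNA(cm)) stop("covariates must be complete")
    cm
  }
  maf <- gm_maf(gm)
  keep <- which(!is.nan(maf) & maf >= maf_min)
  v <- gm$variants
  ncv <- if (is.null(C)) 0L else ncol(C)
  Xfull <- cbind(`(Intercept)` = rep(1, n), C, dosage = 0)
  res <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    j <- keep[ii]
    g <- gm$dosage[, j]
    use <- !is.na(g)
    X <- Xfull[use, , drop = FALSE]
    X[, ncv + 2L] <- g[use]
    w <- logit_wald(X, y[use])
    res[[ii]] <- c(w$beta, w$se, w$p, sum(use), w$flagged)
  }
  res <- do.call(rbind, res)
  out <- data.frame(
    variant_id = v$id[keep], chrom = v$chrom[keep], pos = v$pos[keep],
    a1 = v$alt[keep], a2 = v$ref[keep], maf = maf[keep],
    beta = res[, 1], se = res[, 2],
    odds_ratio = exp(res[, 1]),
    l95 = exp(res[, 1] - 1.96 * res[, 2]),
    u95 = exp(res[, 1] + 1.96 * res[, 2]),
    p = res[, 3], n_used = as.integer(res[, 4]),
    flagged = as.logical(res[, 5]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; values near 1
#' indicate well-controlled confounding.
#'
#' @param p_values numeric vector of p-values in (0, 1]; at least 100.
#' @return lambda (dimensionless).
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100) stop("at least 100 p-values required")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  stats::median(qchisq(p_values, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1)
}

#' Pairwise LD as squared dosage correlation
#'
#' @param dosage_a,dosage_b dosage vectors over the same samples.
#' @return squared Pearson correlation over pairwise-complete samples;
#'   `NA` if fewer than 2 complete pairs or either variant is monomorphic
#'   on the overlap (clumping treats `NA` as 0).
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  use <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(use) < 2) return(NA_real_)
  a <- dosage_a[use]; b <- dosage_b[use]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Greedy LD-based clumping
#'
#' Repeatedly takes the unassigned variant with the smallest p-value not
#' exceeding `p1` as an index, and assigns to its clump every unassigned
#' variant on the same chromosome within `window_kb` with `p <= p2` and
#' dosage `r^2 >= r2_min` with the index; iterates until no eligible
#' index remains. Ties in p are broken by (chrom, pos). Every emitted
#' variant appears in exactly one clump.
#'
#' @param stats data.frame with `variant_id` and `p` (NA p never indexes
#'   nor joins).
#' @param gm [geno_matrix()] supplying positions and dosages for r^2.
#' @param p1 index significance threshold.
#' @param p2 member significance threshold.
#' @param window_kb clump half-window in kilobases.
#' @param r2_min minimum LD with the index for membership.
#' @return data.frame, one row per clump: `index_id, chrom, pos, p,
#'   n_members`, plus a list column `members`.
#' @export
clump <- function(stats, gm, p1 = 1e-5, p2 = 1e-3, window_kb = 150,
                  r2_min = 0.5) {
  stopifnot(inherits(gm, "geno_matrix"))
  v <- gm$variants
  idx <- match(stats$variant_id, v$id)
  if (anyNA(idx)) stop("stats contain variant ids absent from genotypes")
  df <- data.frame(variant_id = stats$variant_id, p = stats$p,
                   chrom = v$chrom[idx], pos = v$pos[idx],
                   col = idx, stringsAsFactors = FALSE)
  df <- df[order(df$p, df$chrom, df$pos), , drop = FALSE]
  unassigned <- rep(TRUE, nrow(df))
  window <- window_kb * 1000
  out <- list()
  repeat {
    cand <- which(unassigned & !is.na(df$p) & df$p <= p1)
    if (!length(cand)) break
    i <- cand[1]
    unassigned[i] <- FALSE
    near <- which(unassigned & df$chrom == df$chrom[i] &
                    abs(df$pos - df$pos[i]) <= window &
                    !is.na(df$p) & df$p <= p2)
    members <- character(0)
    if (length(near)) {
      gi <- gm$dosage[, df$col[i]]
      r2 <- vapply(near, function(j) {
        r <- ld_r2(gi, gm$dosage[, df$col[j]])
        if (is.na(r)) 0 else r
      }, numeric(1))
      hit <- near[r2 >= r2_min]
      members <- df$variant_id[hit]
      unassigned[hit] <- FALSE
    }
    out[[length(out) + 1L]] <- data.frame(
      index_id = df$variant_id[i], chrom = df$chrom[i], pos = df$pos[i],
      p = df$p[i], n_members = length(members), stringsAsFactors = FALSE)
    out[[length(out)]]$members <- list(members)
  }
  if (!length(out)) {
    return(data.frame(index_id = character(0), chrom = character(0),
                      pos = integer(0), p = numeric(0),
                      n_members = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
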