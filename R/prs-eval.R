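#' Area under the ROC curve
#'
#' Mann-Whitney identity: the probability that a random case outranks a
#' random control, ties counted 1/2.
#'
#' @param labels binary labels (`"case"`/`"control"`, logical, or 0/1).
#' @param scores numeric scores, higher = more case-like.
#' @return AUC in [0, 1].
#' @export
prs_auc <- function(labels, scores) {
  y <- if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "case")
  } else as.integer(labels)
  ok <- !is.na(scores) & !is.na(y)
  y <- y[ok]; scores <- scores[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes required")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified k-fold assignment: cases and controls split separately
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Repeated stratified cross-validated AUC
#'
#' Per repeat, a stratified k-fold split; on each training fold two
#' logistic models are fitted (covariates only, and PRS + covariates)
#' and scored by AUC on the held-out fold. Reports the mean and SD over
#' all `k x repeats` fold-AUCs for both models. Identical seed gives
#' identical folds and results; the covariates-only model is unaffected
#' by the PRS column.
#'
#' @param data data.frame with a binary `status` column, a `prs` column,
#'   and covariate columns (everything else except `sample_id`).
#' @param k folds (default 5).
#' @param repeats repetitions of the k-fold split (default 100).
#' @param seed integer seed.
#' @return list: `covariates_only` and `with_prs`, each
#'   `list(mean, sd, fold_aucs)`.
#' @export
cv_auc <- function(data, k = 5, repeats = 100, seed = 1L) {
  y <- if (is.character(data$status) || is.factor(data$status)) {
    as.integer(as.character(data$status) == "case")
  } else as.integer(data$status)
  if (length(unique(y)) != 2) stop("both classes required")
  covars <- setdiff(names(data), c("status", "prs", "sample_id"))
  Xc <- cbind(1, as.matrix(data[, covars, drop = FALSE]))
  Xp <- cbind(Xc, prs = data$prs)
  set.seed(as.integer(seed))
  auc_c <- auc_p <- numeric(0)
  for (rep_i in seq_len(repeats)) {
    fold <- stratified_folds(y, k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      fc <- suppressWarnings(stats::glm.fit(Xc[tr, , drop = FALSE], y[tr],
                                            family = stats::binomial()))
      fp <- suppressWarnings(stats::glm.fit(Xp[tr, , drop = FALSE], y[tr],
                                            family = stats::binomial()))
      # collinear columns get NA coefficients; they contribute nothing
      bc <- ifelse(is.na(fc$coefficients), 0, fc$coefficients)
      bp <- ifelse(is.na(fp$coefficients), 0, fp$coefficients)
      auc_c <- c(auc_c, prs_auc(y[te], drop(Xc[te, , drop = FALSE] %*% bc)))
      auc_p <- c(auc_p, prs_auc(y[te], drop(Xp[te, , drop = FALSE] %*% bp)))
    }
  }
  list(
    covariates_only = list(mean = mean(auc_c), sd = stats::sd(auc_c),
                           fold_aucs = auc_c),
    with_prs = list(mean = mean(auc_p), sd = stats::sd(auc_p),
                    fold_aucs = auc_p)
  )
}

#' Quintile odds ratios for a polygenic score
#'
#' Samples are cut at the 20/40/60/80 score percentiles (rank-based;
#' tied scores all land in the lower quintile), and a covariate-adjusted
#' logistic model of status on quintile indicators (lowest quintile as
#' reference) plus covariates is fitted. Wald ORs and 95% CIs are
#' reported for Q2-Q5; separated fits are flagged rather than given a
#' fabricated p.
#'
#' @param scores numeric score vector.
#' @param status binary status aligned with `scores`.
#' @param covariates optional numeric covariate data.frame.
#' @param min_per_quintile minimum quintile size (default 5).
#' @return data.frame: `quintile, odds_ratio, l95, u95, p, flagged`, and
#'   attribute `counts` (per-quintile case/control table).
#' @export
quintile_or <- function(scores, status, covariates = NULL,
                        min_per_quintile = 5) {
  y <- if (is.character(status) || is.factor(status)) {
    as.integer(as.character(status) == "case")
  } else as.integer(status)
  n <- length(scores)
  q <- ceiling(5 * rank(scores, ties.method = "min") / n)
  q <- pmin(pmax(q, 1L), 5L)
  sizes <- tabulate(q, 5)
  if (any(sizes < min_per_quintile)) {
    stop("degenerate score distribution: quintile ",
         which(sizes < min_per_quintile)[1], " has ",
         min(sizes), " samples")
  }
  Qd <- outer(q, 2:5, `==`) * 1
  colnames(Qd) <- paste0("Q", 2:5)
  C <- if (is.null(covariates)) NULL else as.matrix(
    covariates[, setdiff(names(covariates), "sample_id"), drop = FALSE])
  X <- cbind(`(Intercept)` = 1, Qd, C)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  cf <- fit$coefficients
  R <- fit$qr$qr[seq_len(ncol(X)), seq_len(ncol(X)), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  out <- lapply(1:4, function(i) {
    b <- cf[1 + i]
    se <- if (is.null(cov)) NA_real_ else sqrt(cov[1 + i, 1 + i])
    flag <- !fit$converged || is.na(b) || !is.finite(se) || se > 50 ||
      abs(b) > 25
    data.frame(quintile = paste0("Q", i + 1),
               odds_ratio = exp(b),
               l95 = exp(b - 1.96 * se), u95 = exp(b + 1.96 * se),
               p = if (flag) NA_real_ else 2 * pnorm(-abs(b / se)),
               flagged = flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "counts") <- table(quintile = q, case = y)
  res
}
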