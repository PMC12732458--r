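#' Build a phenome from an EHR diagnosis table
#'
#' For every code with at least `min_cases` distinct case samples, cases
#' are the samples with at least one assignment of the code, eligible
#' controls are the samples lacking the code that carry at least one
#' assignment of the anchor code (a healthy-encounter code, default
#' `Z00.00`), and the control set is a seeded uniform sample (without
#' replacement) of size `min(control_ratio * n_cases, n_eligible)` to
#' prevent effect-size bias from extreme imbalance. The anchor code
#' itself is not emitted as a phenotype (its control set would be empty
#' by construction).
#'
#' @param ehr data.frame: `sample_id, icd10` (or any code column named
#'   `icd10`); duplicate assignments permitted.
#' @param samples sample table (`id`); EHR rows must reference known ids.
#' @param min_cases minimum distinct cases per phenotype (default 50).
#' @param control_ratio controls per case (default 5).
#' @param anchor_code control-eligibility code (default `"Z00.00"`).
#' @param seed integer seed for control sampling.
#' @return named list, one element per phenotype:
#'   `list(phenotype_id, case_ids, control_ids)`.
#' @export
build_phenome <- function(ehr, samples, min_cases = 50, control_ratio = 5,
                          anchor_code = "Z00.00", seed = 1L) {
  if (!all(ehr$sample_id %in% samples$id)) {
    stop("EHR references unknown sample ids")
  }
  anchor_carriers <- unique(ehr$sample_id[ehr$icd10 == anchor_code])
  if (!length(anchor_carriers)) {
    stop("anchor code ", anchor_code, " absent from EHR: controls undefinable")
  }
  set.seed(as.integer(seed))
  codes <- setdiff(unique(ehr$icd10), anchor_code)
  out <- list()
  for (code in sort(codes)) {
    cases <- unique(ehr$sample_id[ehr$icd10 == code])
    if (length(cases) < min_cases) next
    eligible <- setdiff(anchor_carriers, cases)
    n_ctrl <- min(control_ratio * length(cases), length(eligible))
    controls <- if (n_ctrl < length(eligible)) {
      sample(eligible, n_ctrl)
    } else eligible
    out[[code]] <- list(phenotype_id = code, case_ids = cases,
                        control_ids = controls)
  }
  out
}

#' Map an ICD-10 EHR to phecodes
#'
#' Each EHR row is translated to its phecode; codes without a direct map
#' entry fall back to successively truncated prefixes (dropping one
#' trailing character at a time, trailing dots skipped) before being
#' dropped with a logged count. A sample is a phecode case if any of its
#' ICD-10 codes maps to the phecode, so rows are de-duplicated after
#' translation.
#'
#' @param ehr data.frame: `sample_id, icd10`.
#' @param map data.frame: `icd10, phecode, label`; rows with empty icd10
#'   or phecode are rejected at load with their row numbers.
#' @return data.frame `sample_id, icd10` (phecode values in the `icd10`
#'   column so downstream operations are code-system agnostic), with
#'   attributes `n_dropped` (unmapped assignments) and `labels` (named
#'   vector phecode -> label).
#' @export
map_phecodes <- function(ehr, map) {
  bad <- which(is.na(map$icd10) | map$icd10 == "" |
                 is.na(map$phecode) | map$phecode == "")
  if (length(bad)) {
    stop("malformed phecode map rows: ", paste(bad, collapse = ", "))
  }
  lookup <- stats::setNames(as.character(map$phecode), map$icd10)
  resolve <- function(code) {
    while (nchar(code) > 0) {
      hit <- lookup[code]
      if (!is.na(hit)) return(unname(hit))
      code <- sub("\\.?$", "", substr(code, 1, nchar(code) - 1))
    }
    NA_character_
  }
  uniq <- unique(ehr$icd10)
  resolved <- vapply(uniq, resolve, character(1))
  phe <- resolved[match(ehr$icd10, uniq)]
  dropped <- sum(is.na(phe))
  if (dropped) message(dropped, " EHR assignments had no phecode; dropped")
  out <- unique(data.frame(sample_id = ehr$sample_id[!is.na(phe)],
                           icd10 = phe[!is.na(phe)],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  labels <- map$label
  if (!is.null(labels)) {
    attr(out, "labels") <- stats::setNames(labels, as.character(map$phecode))[
      !duplicated(as.character(map$phecode))]
  }
  out
}

#' Bonferroni phenome-wide significance threshold
#'
#' @param n_phenotypes number of phenotypes interrogated (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return threshold `alpha / n_phenotypes` at full precision; the
#'   3-significant-figure presentation is `signif(x, 3)`.
#' @export
bonferroni_threshold <- function(n_phenotypes, alpha = 0.05) {
  if (n_phenotypes < 1) stop("n_phenotypes must be >= 1")
  alpha / n_phenotypes
}

#' Phenome-wide association scan
#'
#' For each phenotype, fits a logistic regression of case/control status
#' (per the phenome definitions) on the predictor (a variant dosage or a
#' polygenic score) plus covariates:
#' `logit P(phenotype) = b0 + b1 predictor + covariates`. Wald
#' statistics are reported; separated or non-converged fits are flagged
#' with `p = NA`. Results are sorted by p, and the Bonferroni flag uses
#' `alpha / n_phenotypes_tested` (override via `n_override` to reproduce
#' an externally fixed divisor).
#'
#' @param predictor named numeric vector (by sample id): dosages 0/1/2
#'   for variant mode, scores for PRS mode.
#' @param phenome phenotype definitions from [build_phenome()].
#' @param covariates data.frame with `sample_id` plus numeric covariate
#'   columns (age, sex, PCs).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param n_override optional fixed Bonferroni divisor.
#' @return data.frame sorted by p: `phenotype, n_cases, n_controls,
#'   beta, odds_ratio, p, flagged, passes_bonferroni`, with attribute
#'   `bonferroni` (the threshold used).
#' @export
phewas <- function(predictor, phenome, covariates, alpha = 0.05,
                   n_override = NULL) {
  stopifnot(!is.null(names(predictor)))
  cov_ids <- covariates$sample_id
  Cm <- as.matrix(covariates[, setdiff(names(covariates), "sample_id"),
                             drop = FALSE])
  rows <- list()
  skipped <- character(0)
  for (ph in names(phenome)) {
    def <- phenome[[ph]]
    ids <- c(def$case_ids, def$control_ids)
    y <- rep(c(1L, 0L), c(length(def$case_ids), length(def$control_ids)))
    x <- predictor[ids]
    ok <- !is.na(x)
    if (!any(ok & y == 1L)) {
      skipped <- c(skipped, ph)
      next
    }
    if (stats::sd(x[ok]) == 0) {
      rows[[ph]] <- data.frame(
        phenotype = ph, n_cases = length(def$case_ids),
        n_controls = length(def$control_ids), beta = NA_real_,
        odds_ratio = NA_real_, p = NA_real_, flagged = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    X <- cbind(1, Cm[match(ids, cov_ids), , drop = FALSE], x)[ok, , drop = FALSE]
    w <- logit_wald(X, y[ok])
    rows[[ph]] <- data.frame(
      phenotype = ph, n_cases = length(def$case_ids),
      n_controls = length(def$control_ids), beta = w$beta,
      odds_ratio = exp(w$beta), p = w$p, flagged = w$flagged,
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message(length(skipped), " phenotypes skipped (predictor missing for all cases)")
  }
  res <- do.call(rbind, rows)
  thr <- bonferroni_threshold(
    if (is.null(n_override)) nrow(res) else n_override, alpha)
  res$passes_bonferroni <- !is.na(res$p) & res$p < thr
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "bonferroni") <- thr
  res
}
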