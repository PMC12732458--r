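#' Harmonize external summary statistics against cohort variants
#'
#' Records are matched to cohort variants by (chrom, pos) and the allele
#' pair reconciled:
#' \itemize{
#' \item effect allele equals cohort ALT (other = REF): kept as-is;
#' \item effect allele equals cohort REF (other = ALT): alleles swapped
#'   and beta negated, so the effect allele is always the cohort ALT;
#' \item allele pair matches only after reverse-complement: strand
#'   flipped, then the two rules above applied;
#' \item anything else: excluded (`allele_mismatch`).
#' }
#' Strand-ambiguous palindromic (A/T, C/G) pairs are excluded by default
#' since a strand flip is undetectable from the alleles. Records at
#' positions absent from the cohort, duplicated records with
#' inconsistent alleles, and (optionally) variants below a cohort MAF
#' floor are excluded. Every exclusion reason is counted in the ledger.
#'
#' @param sumstats data.frame: `id, chrom, pos, effect_allele,
#'   other_allele, beta, p` (`se` carried through if present).
#' @param variants cohort variant table (`id, chrom, pos, ref, alt`).
#' @param cohort_maf optional named MAF vector (by cohort variant id) for
#'   the `maf_min` filter.
#' @param maf_min cohort MAF floor (applied only when `cohort_maf` given).
#' @param palindromic `"exclude"` (default) or `"keep"`.
#' @return list: `sumstats` (harmonized, with `variant_id` = cohort id,
#'   `effect_allele` = cohort ALT) and `ledger` (data.frame
#'   `reason, n`).
#' @export
harmonize_sumstats <- function(sumstats, variants, cohort_maf = NULL,
                               maf_min = 0.01,
                               palindromic = c("exclude", "keep")) {
  palindromic <- match.arg(palindromic)
  led <- c(absent = 0L, duplicate_inconsistent = 0L, allele_mismatch = 0L,
           palindromic = 0L, low_maf = 0L)
  key <- paste(variants$chrom, variants$pos)
  skey <- paste(sumstats$chrom, sumstats$pos)
  # duplicated sumstat positions with inconsistent alleles are dropped
  dup <- skey[duplicated(skey)]
  if (length(dup)) {
    bad <- unique(unlist(lapply(unique(dup), function(k) {
      rows <- which(skey == k)
      pairs <- paste(pmin(sumstats$effect_allele[rows],
                          sumstats$other_allele[rows]),
                     pmax(sumstats$effect_allele[rows],
                          sumstats$other_allele[rows]))
      if (length(unique(pairs)) > 1) rows else rows[-1]
    })))
    led["duplicate_inconsistent"] <- length(bad)
    sumstats <- sumstats[-bad, , drop = FALSE]
    skey <- skey[-bad]
  }
  hit <- match(skey, key)
  led["absent"] <- sum(is.na(hit))
  keep <- !is.na(hit)
  ss <- sumstats[keep, , drop = FALSE]
  vv <- variants[hit[keep], , drop = FALSE]

  ea <- toupper(ss$effect_allele); oa <- toupper(ss$other_allele)
  ref <- toupper(vv$ref); alt <- toupper(vv$alt)
  pal <- is_palindromic(ea, oa)
  if (palindromic == "exclude" && any(pal)) {
    led["palindromic"] <- sum(pal)
    ss <- ss[!pal, , drop = FALSE]; vv <- vv[!pal, , drop = FALSE]
    ea <- ea[!pal]; oa <- oa[!pal]; ref <- ref[!pal]; alt <- alt[!pal]
  }

  direct <- ea == alt & oa == ref
  swapped <- ea == ref & oa == alt
  flip_d <- revcomp(ea) == alt & revcomp(oa) == ref
  flip_s <- revcomp(ea) == ref & revcomp(oa) == alt
  # palindromic pairs kept under policy "keep" satisfy both direct and
  # flipped predicates; direct interpretation wins
  flip_d <- flip_d & !direct & !swapped
  flip_s <- flip_s & !direct & !swapped
  mism <- !(direct | swapped | flip_d | flip_s)
  led["allele_mismatch"] <- sum(mism)

  beta <- ss$beta
  beta[swapped | flip_s] <- -beta[swapped | flip_s]
  out <- data.frame(
    variant_id = vv$id, chrom = vv$chrom, pos = vv$pos,
    effect_allele = alt, other_allele = ref,
    beta = beta, p = ss$p, stringsAsFactors = FALSE)
  if (!is.null(ss$se)) out$se <- ss$se
  out <- out[!mism, , drop = FALSE]

  if (!is.null(cohort_maf)) {
    mafv <- cohort_maf[out$variant_id]
    low <- is.na(mafv) | mafv < maf_min
    led["low_maf"] <- sum(low)
    out <- out[!low, , drop = FALSE]
  }
  rownames(out) <- NULL
  list(sumstats = out,
       ledger = data.frame(reason = names(led), n = as.integer(led),
                           stringsAsFactors = FALSE))
}

#' Sliding-window greedy LD pruning
#'
#' Within each window of `window_kb` kilobases (anchored at successive
#' variants, advancing by `step` variants), while any retained pair has
#' dosage `r^2` above `r2_max`, the member of the currently worst pair
#' with the lower MAF is removed (tie: the later position). Chromosomes
#' are processed independently; positions must be sorted within
#' chromosome.
#'
#' @param gm a [geno_matrix()].
#' @param window_kb window span in kilobases (default 250).
#' @param step variants to advance between windows (default 50).
#' @param r2_max pruning threshold.
#' @return character vector of retained variant ids, in input order.
#' @export
ld_prune <- function(gm, window_kb = 250, step = 50, r2_max = 0.2) {
  stopifnot(inherits(gm, "geno_matrix"))
  v <- gm$variants
  keep <- rep(TRUE, nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    if (is.unsorted(v$pos[idx])) stop("positions must be sorted within chromosome")
    start <- 1L
    repeat {
      if (start > length(idx)) break
      anchor <- idx[start]
      win <- idx[v$pos[idx] >= v$pos[anchor] &
                   v$pos[idx] <= v$pos[anchor] + window_kb * 1000]
      if (length(win) >= 2) {
        r2m <- suppressWarnings(
          stats::cor(gm$dosage[, win, drop = FALSE],
                     use = "pairwise.complete.obs")^2)
        r2m[is.na(r2m)] <- 0
        diag(r2m) <- 0
        maf_win <- gm_maf(gm)[win]
        alive <- keep[win]
        repeat {
          sub <- r2m
          sub[!alive, ] <- 0; sub[, !alive] <- 0
          worst_r2 <- max(sub)
          if (worst_r2 <= r2_max) break
          w <- which(sub == worst_r2, arr.ind = TRUE)[1, ]
          pair <- sort(w)
          drop_k <- if (maf_win[pair[1]] < maf_win[pair[2]]) pair[1]
          else if (maf_win[pair[2]] < maf_win[pair[1]]) pair[2]
          else pair[which.max(v$pos[win[pair]])]
          alive[drop_k] <- FALSE
        }
        keep[win] <- alive
      }
      start <- start + step
    }
  }
  v$id[keep]
}

#' Polygenic score model
#'
#' @param variant_ids character vector of unique model variant ids.
#' @param weights per-variant effect sizes aligned with `variant_ids`
#'   (all 1 for unweighted mode).
#' @param mode `"weighted"` or `"unweighted"`.
#' @param provenance free-form selection descriptor (thresholds, SNP-set
#'   name) carried into evaluation reports.
#' @return a `prs_model` object.
#' @export
prs_model <- function(variant_ids, weights = NULL,
                      mode = c("weighted", "unweighted"),
                      provenance = list()) {
  mode <- match.arg(mode)
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(variant_ids)) stop("model variant ids must be unique")
  if (mode == "unweighted") weights <- rep(1, length(variant_ids))
  if (length(weights) != length(variant_ids)) {
    stop("one weight per variant required")
  }
  if (any(!is.finite(weights))) stop("weights must be finite")
  structure(list(variant_ids = variant_ids, weights = as.numeric(weights),
                 mode = mode, provenance = provenance),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> %d variants, %s%s\n", length(x$variant_ids),
              x$mode,
              if (length(x$provenance)) {
                paste0(" [", paste(names(x$provenance), unlist(x$provenance),
                                   sep = "=", collapse = ", "), "]")
              } else ""))
  invisible(x)
}

#' Clumping + thresholding variant selection
#'
#' Clumps the harmonized summary statistics with index and member
#' p-value thresholds of 1 (every variant index-eligible, none silently
#' dropped), window `window_kb`, LD threshold `r2_thresh`; retains the
#' index variants; then applies the p-value cutoff `p_thresh`. Weights
#' are the harmonized betas.
#'
#' @param harmonized harmonized sumstats data.frame from
#'   [harmonize_sumstats()].
#' @param gm cohort [geno_matrix()] (LD source).
#' @param r2_thresh clumping r^2 threshold.
#' @param p_thresh p-value cutoff applied after clumping.
#' @param window_kb clump window (default 250).
#' @return a [prs_model()] (possibly empty, with a message).
#' @export
ct_select <- function(harmonized, gm, r2_thresh, p_thresh, window_kb = 250) {
  st <- data.frame(variant_id = harmonized$variant_id, p = harmonized$p,
                   stringsAsFactors = FALSE)
  cl <- clump(st, gm_subset(gm, variants = harmonized$variant_id),
              p1 = 1, p2 = 1, window_kb = window_kb, r2_min = r2_thresh)
  sel <- harmonized[harmonized$variant_id %in% cl$index_id &
                      harmonized$p <= p_thresh, , drop = FALSE]
  if (!nrow(sel)) message("C+T selection is empty at p <= ", p_thresh)
  prs_model(sel$variant_id, sel$beta, mode = "weighted",
            provenance = list(snpset = "genome-wide", r2 = r2_thresh,
                              p = p_thresh, window_kb = window_kb))
}

#' Restrict a model or harmonized sumstats to a SNP set
#'
#' Keeps variants whose position falls inside any of the supplied
#' 1-based inclusive intervals, or whose id is in the supplied list;
#' weight alignment is preserved.
#'
#' @param x a [prs_model()] or harmonized sumstats data.frame.
#' @param regions data.frame (`chrom, start, end`), 1-based inclusive
#'   (see [read_bed_intervals()]); or NULL.
#' @param ids character id list; or NULL. Exactly one of `regions`/`ids`.
#' @param variants variant table supplying positions when `x` is a
#'   `prs_model` and `regions` is used.
#' @return object of the same type as `x`, restricted (possibly empty,
#'   with a message).
#' @export
restrict_snpset <- function(x, regions = NULL, ids = NULL, variants = NULL) {
  if (is.null(regions) == is.null(ids)) {
    stop("supply exactly one of `regions` or `ids`")
  }
  pos_in <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      any(regions$chrom == chrom[i] &
            regions$start <= pos[i] & pos[i] <= regions$end)
    }, logical(1))
  }
  if (inherits(x, "prs_model")) {
    if (!is.null(ids)) {
      keep <- x$variant_ids %in% ids
    } else {
      if (is.null(variants)) stop("interval restriction of a model needs `variants`")
      m <- match(x$variant_ids, variants$id)
      keep <- pos_in(variants$chrom[m], variants$pos[m])
    }
    if (!any(keep)) message("restriction left an empty model")
    return(prs_model(x$variant_ids[keep], x$weights[keep], mode = x$mode,
                     provenance = c(x$provenance, list(restricted = TRUE))))
  }
  keep <- if (!is.null(ids)) x$variant_id %in% ids else pos_in(x$chrom, x$pos)
  if (!any(keep)) message("restriction left an empty selection")
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute per-sample polygenic scores
#'
#' Weighted: `PRS_j = sum_i S_i G_ij / (P M_j)`; unweighted:
#' `PRS_j = sum_i G_ij / (P M_j)`; sums over model variants non-missing
#' in sample j, ploidy `P = 2`, `M_j` the count of non-missing model
#' variants for sample j (average-over-observed normalization). `G_ij`
#' counts effect (ALT, post-harmonization) alleles. Model variants
#' absent from the genotypes are dropped with a warning and do not enter
#' `N` or `M_j`. Samples with `M_j = 0` get a missing score.
#'
#' @param model a [prs_model()].
#' @param gm a [geno_matrix()].
#' @return data.frame: `sample_id, prs, m_nonmissing`.
#' @export
compute_prs <- function(model, gm) {
  stopifnot(inherits(model, "prs_model"), inherits(gm, "geno_matrix"))
  present <- model$variant_ids %in% gm$variants$id
  if (!all(present)) {
    warning(sum(!present), " model variants absent from genotypes; dropped")
  }
  ids <- model$variant_ids[present]
  w <- model$weights[present]
  n <- nrow(gm$dosage)
  if (!length(ids)) {
    return(data.frame(sample_id = rownames(gm$dosage), prs = NA_real_,
                      m_nonmissing = 0L, stringsAsFactors = FALSE))
  }
  G <- gm$dosage[, ids, drop = FALSE]
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0L
  num <- as.vector(G0 %*% w)
  m <- as.integer(rowSums(obs))
  prs <- ifelse(m > 0, num / (2 * m), NA_real_)
  data.frame(sample_id = rownames(gm$dosage), prs = prs, m_nonmissing = m,
             stringsAsFactors = FALSE)
}
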