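#' Canonical qualifying-consequence vocabulary
#'
#' The default high-impact consequence set for qualifying-variant
#' selection, normalized to underscore-separated lower-case terms and
#' deduplicated (13 terms). Configurable wherever it is consumed.
#'
#' @return character vector of consequence terms.
#' @export
qualifying_consequences <- function() {
  c("missense_variant", "start_lost", "stop_lost", "stop_gained",
    "splice_acceptor_variant", "splice_donor_variant",
    "inframe_insertion", "inframe_deletion", "protein_altering_variant",
    "start_retained_variant", "stop_retained_variant",
    "regulatory_region_variant", "frameshift_variant")
}

#' Default consequence-severity ranking
#'
#' Most severe first; used to resolve multi-consequence annotations
#' ("most severe category selected"). Terms absent from the ranking sort
#' last.
#'
#' @return character vector, most severe first.
#' @export
consequence_severity <- function() {
  c("frameshift_variant", "stop_gained", "splice_acceptor_variant",
    "splice_donor_variant", "start_lost", "stop_lost",
    "inframe_insertion", "inframe_deletion", "protein_altering_variant",
    "missense_variant", "start_retained_variant", "stop_retained_variant",
    "regulatory_region_variant", "synonymous_variant", "intron_variant",
    "intergenic_variant")
}

normalize_consequence <- function(x) {
  gsub("[ ]+", "_", tolower(trimws(x)))
}

most_severe <- function(terms, ranking = consequence_severity()) {
  r <- match(terms, ranking)
  r[is.na(r)] <- length(ranking) + 1L
  terms[which.min(r)]
}

#' Select qualifying rare variants and group them by gene
#'
#' A variant qualifies iff its (most severe) consequence is in the
#' qualifying list, its reference-population MAF is below `maf_max`, it
#' is not in a low-complexity region, and it carries a gene symbol.
#' Multi-consequence annotations (separated by `&` or `,`) are resolved
#' to the most severe term first. Unannotated tested variants are
#' excluded with a logged count, not an error.
#'
#' @param annotations data.frame: `variant_id, gene, consequence,
#'   ref_pop_maf, in_lcr` (logical).
#' @param variant_ids character vector of variants under test (e.g. the
#'   QC-retained set); annotations for other variants are ignored.
#' @param maf_max reference-population MAF cutoff (default 0.01, strict
#'   `<`).
#' @param consequences qualifying vocabulary (default
#'   [qualifying_consequences()]).
#' @param ranking severity ranking for multi-consequence resolution.
#' @return named list gene -> character vector of qualifying variant ids,
#'   with attributes `n_unannotated` and `n_no_gene`.
#' @export
select_qualifying <- function(annotations, variant_ids,
                              maf_max = 0.01,
                              consequences = qualifying_consequences(),
                              ranking = consequence_severity()) {
  ann <- annotations[annotations$variant_id %in% variant_ids, , drop = FALSE]
  n_unann <- length(setdiff(variant_ids, ann$variant_id))
  if (n_unann > 0) {
    message(n_unann, " tested variants lack annotation; excluded")
  }
  if (!nrow(ann)) {
    out <- list()
    attr(out, "n_unannotated") <- n_unann
    attr(out, "n_no_gene") <- 0L
    return(out)
  }
  cons <- vapply(strsplit(normalize_consequence(ann$consequence), "[&,]"),
                 most_severe, character(1), ranking = ranking)
  no_gene <- is.na(ann$gene) | ann$gene == ""
  qual <- cons %in% normalize_consequence(consequences) &
    ann$ref_pop_maf < maf_max &
    !ann$in_lcr & !no_gene
  sel <- ann[qual, , drop = FALSE]
  out <- split(sel$variant_id, sel$gene)
  attr(out, "n_unannotated") <- n_unann
  attr(out, "n_no_gene") <- sum(no_gene & cons %in% consequences)
  out
}

#' Flag variants falling in low-complexity regions
#'
#' @param variants variant table (`id, chrom, pos`).
#' @param lcr data.frame of 1-based inclusive intervals
#'   (`chrom, start, end`), e.g. from [read_bed_intervals()].
#' @return logical vector, one per variant.
#' @export
in_lcr <- function(variants, lcr) {
  vapply(seq_len(nrow(variants)), function(i) {
    any(lcr$chrom == variants$chrom[i] &
          lcr$start <= variants$pos[i] & variants$pos[i] <= lcr$end)
  }, logical(1))
}

#' Gene-level carrier-burden collapsing test
#'
#' Per gene, a sample is a carrier iff it carries at least one ALT allele
#' at any qualifying variant (missing dosages ignored). The gene-level
#' test is a covariate-adjusted logistic regression of status on the
#' carrier indicator; when that fit is non-converged or separated the
#' test falls back to a two-sided Fisher exact test on the carrier 2x2
#' table, with the fallback recorded in `method`. Genes with zero
#' carriers overall are skipped with a message.
#'
#' @param qualifying named list gene -> variant ids, from
#'   [select_qualifying()].
#' @param gm a [geno_matrix()].
#' @param status binary status aligned with genotype rows
#'   (`"case"`/`"control"` or 0/1).
#' @param covariates optional numeric covariate data.frame.
#' @return data.frame: `gene, n_qualifying_variants, n_carriers_case,
#'   n_carriers_control, p, method`.
#' @export
gene_collapse_test <- function(qualifying, gm, status, covariates = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  y <- if (is.character(status) || is.factor(status)) {
    as.integer(as.character(status) == "case")
  } else as.integer(status)
  C <- if (is.null(covariates)) NULL else as.matrix(
    covariates[, setdiff(names(covariates), "sample_id"), drop = FALSE])
  out <- list()
  for (gene in names(qualifying)) {
    vids <- intersect(qualifying[[gene]], gm$variants$id)
    if (!length(vids)) next
    sub <- gm$dosage[, vids, drop = FALSE]
    carrier <- as.integer(rowSums(sub > 0, na.rm = TRUE) > 0)
    if (sum(carrier) == 0) {
      message("gene ", gene, ": no carriers; skipped")
      next
    }
    n_cc <- sum(carrier == 1 & y == 1)
    n_cn <- sum(carrier == 1 & y == 0)
    X <- cbind(`(Intercept)` = 1, C, carrier = carrier)
    w <- logit_wald(X, y)
    if (w$flagged || is.na(w$p)) {
      tab <- matrix(c(n_cc, sum(y == 1) - n_cc,
                      n_cn, sum(y == 0) - n_cn), nrow = 2, byrow = TRUE)
      p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
      method <- "fisher"
    } else {
      p <- w$p
      method <- "logistic"
    }
    out[[gene]] <- data.frame(
      gene = gene, n_qualifying_variants = length(vids),
      n_carriers_case = n_cc, n_carriers_control = n_cn,
      p = p, method = method, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), n_qualifying_variants = integer(0),
                      n_carriers_case = integer(0),
                      n_carriers_control = integer(0), p = numeric(0),
                      method = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
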