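#' Genotype matrix container
#'
#' A `geno_matrix` holds additive allele dosages (number of ALT alleles,
#' 0/1/2, `NA` = missing) for `n_samples x n_variants`, together with a
#' variant table carrying coordinates and alleles. It is the substrate of
#' every pipeline stage: QC filters subset it, association tests iterate
#' over its columns, and polygenic scores are weighted row sums of it.
#'
#' @param dosage integer or numeric matrix, samples in rows, variants in
#'   columns; entries must be 0, 1, 2 or `NA`. Row and column names are
#'   taken as sample / variant ids if `sample_ids` / `variants` are absent.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt` and optionally `strand` (`"+"`/`"-"`, default `"+"`),
#'   one row per dosage column, in column order.
#' @param sample_ids character vector of unique sample ids, one per row.
#' @return an object of class `geno_matrix`: a list with elements `dosage`
#'   (the matrix, dimnames set) and `variants` (the variant table).
#' @export
geno_matrix <- function(dosage, variants, sample_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) stop("sample ids are required (rownames or `sample_ids`)")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(dosage)) stop("one sample id per dosage row required")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    stop("variant table needs columns: ", paste(req, collapse = ", "))
  }
  if (is.null(variants$strand)) variants$strand <- "+"
  variants$id <- as.character(variants$id)
  if (nrow(variants) != ncol(dosage)) stop("one variant row per dosage column required")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (any(variants$pos < 1)) stop("positions are 1-based: pos >= 1 required")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sample_ids, variants$id)
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' Membership-only operation: retained dosage values are never altered.
#'
#' @param gm a [geno_matrix()].
#' @param samples,variants character ids (or logical/integer index vectors)
#'   to retain; `NULL` keeps all. Character ids are retained in the order
#'   given.
#' @return a `geno_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  d <- gm$dosage
  v <- gm$variants
  if (!is.null(samples)) {
    if (is.character(samples) && !all(samples %in% rownames(d))) {
      stop("unknown sample ids in subset")
    }
    d <- d[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    if (is.character(variants)) {
      if (!all(variants %in% v$id)) stop("unknown variant ids in subset")
      keep <- match(variants, v$id)
    } else {
      keep <- variants
    }
    d <- d[, keep, drop = FALSE]
    v <- v[keep, , drop = FALSE]
    rownames(v) <- NULL
  }
  geno_matrix(d, v)
}

#' Per-variant ALT allele frequency
#'
#' @param gm a [geno_matrix()].
#' @param samples optional sample ids to restrict to.
#' @return named numeric vector of ALT allele frequencies (missing dosages
#'   excluded from numerator and denominator); `NaN` where no calls.
#' @export
gm_freq <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
}

#' Per-variant minor allele frequency
#' @inheritParams gm_freq
#' @return named numeric vector, `pmin(f, 1 - f)` of ALT frequency.
#' @export
gm_maf <- function(gm, samples = NULL) {
  f <- gm_freq(gm, samples)
  pmin(f, 1 - f)
}

#' Per-sample and per-variant call rates
#' @param gm a [geno_matrix()].
#' @return named numeric vector of non-missing fractions.
#' @export
sample_call_rate <- function(gm) rowMeans(!is.na(gm$dosage))

#' @rdname sample_call_rate
#' @export
variant_call_rate <- function(gm) colMeans(!is.na(gm$dosage))

#' Reverse-complement allele strings
#'
#' Used for strand flipping: `A<->T`, `C<->G`, applied base-wise and the
#' string reversed (so indel alleles flip too).
#'
#' @param x character vector of allele strings over A/C/G/T.
#' @return character vector.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' Is an allele pair strand-ambiguous (palindromic)?
#'
#' A/T and C/G pairs read the same on both strands, so strand flips cannot
#' be detected from the alleles alone.
#'
#' @param a1,a2 character vectors of alleles.
#' @return logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  toupper(a2) == revcomp(a1)
}
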