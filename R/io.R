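#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' SNP-major bed layout (magic bytes `6c 1b 01`), two bits per genotype:
#' `00` = homozygous A1 (dosage 2 of the bim A1 allele = ALT), `10` =
#' heterozygous, `11` = homozygous A2, `01` = missing. The bim carries
#' chrom, id, 0 cM, pos, A1 = ALT, A2 = REF.
#'
#' @param gm a [geno_matrix()].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @param samples optional sample table (`id, reported_sex, status`) for
#'   fam sex (1 = M, 2 = F) and phenotype (2 = case, 1 = control) codes.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix, samples = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  v <- gm$variants
  d <- gm$dosage
  ids <- rownames(d)
  sex <- phe <- rep(0L, length(ids))
  if (!is.null(samples)) {
    i <- match(ids, samples$id)
    if (!is.null(samples$reported_sex)) {
      sex <- ifelse(samples$reported_sex[i] == "M", 1L, 2L)
    }
    if (!is.null(samples$status)) {
      phe <- ifelse(samples$status[i] == "case", 2L, 1L)
    }
  }
  utils::write.table(
    data.frame(ids, ids, 0L, 0L, sex, phe),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = " ", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(v$chrom, v$id, 0L, v$pos, v$alt, v$ref),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  n <- length(ids)
  # per-genotype 2-bit codes, dosage of A1(ALT): 2 -> 00, 1 -> 10, 0 -> 11,
  # NA -> 01
  code <- matrix(3L, n, ncol(d))
  code[d == 2L] <- 0L
  code[d == 1L] <- 2L
  code[is.na(d)] <- 1L
  npad <- (4 - n %% 4) %% 4
  if (npad) code <- rbind(code, matrix(0L, npad, ncol(d)))
  dim(code) <- c(4, nrow(code) / 4, ncol(d))
  bytes <- code[1, , ] + 4L * code[2, , ] + 16L * code[3, , ] +
    64L * code[4, , ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam into a genotype matrix
#'
#' @param prefix path prefix of the fileset.
#' @return a [geno_matrix()] (dosage counts the bim A1 allele, stored as
#'   ALT).
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK bed file")
  }
  body <- as.integer(raw[-(1:3)])
  bpv <- ceiling(n / 4)
  codes <- matrix(0L, 4 * bpv, m)
  block <- matrix(body, bpv, m)
  codes[seq(1, 4 * bpv, by = 4), ] <- block %% 4L
  codes[seq(2, 4 * bpv, by = 4), ] <- (block %/% 4L) %% 4L
  codes[seq(3, 4 * bpv, by = 4), ] <- (block %/% 16L) %% 4L
  codes[seq(4, 4 * bpv, by = 4), ] <- (block %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  variants <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                         ref = bim$a2, alt = bim$a1, strand = "+",
                         stringsAsFactors = FALSE)
  geno_matrix(dos, variants, sample_ids = fam$V2)
}

#' Write a genotype matrix as VCFv4.2
#'
#' Unphased GT records (`0/0`, `0/1`, `1/1`, `./.`) against the variant
#' table's REF/ALT.
#'
#' @param gm a [geno_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  v <- gm$variants
  gt <- c("0/0", "0/1", "1/1")
  d <- gm$dosage
  body <- apply(d, 2, function(col) {
    out <- gt[col + 1L]
    out[is.na(col)] <- "./."
    out
  })
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(d)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".",
              "PASS", ".", "GT", body[, i]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Uses the vcfR parser; dosages count ALT alleles from the GT field.
#'
#' @param path VCF path.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf requires the vcfR package")
  }
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vc, element = "GT")
  alt_count <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a) {
             sum(as.integer(a) > 0)
           }, integer(1)))
  }
  dos <- matrix(alt_count(as.vector(gt)), nrow = nrow(gt)) # variants x samples
  fix <- vcfR::getFIX(vc)
  variants <- data.frame(
    id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    strand = "+", stringsAsFactors = FALSE)
  geno_matrix(t(dos), variants, sample_ids = colnames(gt))
}

#' Read BED genomic intervals as 1-based inclusive
#'
#' BED is 0-based half-open; the returned `start` is `start0 + 1` and
#' `end` is unchanged, giving the pipeline's 1-based closed convention.
#'
#' @param path BED path (first three columns used).
#' @return data.frame: `chrom, start, end`.
#' @export
read_bed_intervals <- function(path) {
  b <- utils::read.table(path, stringsAsFactors = FALSE)
  data.frame(chrom = b[[1]], start = b[[2]] + 1L, end = b[[3]],
             stringsAsFactors = FALSE)
}

#' Read GWAS summary statistics
#'
#' Tab-separated with a header; required columns `id, chrom, pos,
#' effect_allele, other_allele, p` and either `beta` or `OR` (an OR
#' column is converted to `beta = log(OR)` with a message).
#'
#' @param path TSV path.
#' @return data.frame in the harmonizer's input layout.
#' @export
read_sumstats <- function(path) {
  ss <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(ss$beta)) {
    orc <- ss$OR
    if (is.null(orc)) orc <- ss$or
    if (is.null(orc)) stop("sumstats need a `beta` or `OR` column")
    message("converting OR column to beta = log(OR)")
    ss$beta <- log(orc)
  }
  req <- c("id", "chrom", "pos", "effect_allele", "other_allele", "beta", "p")
  if (!all(req %in% names(ss))) {
    stop("sumstats need columns: ", paste(req, collapse = ", "))
  }
  ss
}

#' Write GWAS summary statistics / association output as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a QC report as JSON
#'
#' @param qc result list from [sample_qc()] or [variant_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(
    list(report = qc$report, removed = qc$removed,
         retained = qc$retained_ids),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
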