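#' Read genotypes from VCF or a dosage TSV
#'
#' VCF input (4.x, via \pkg{vcfR}) keeps biallelic SNP records only; sites
#' with more than one ALT allele are skipped (`multiallelic = "skip"`, the
#' count is reported in a message) or rejected. Genotype calls are converted
#' to alternate-allele dosages: `0/0 -> 0`, `0/1`/`1/0 -> 1`, `1/1 -> 2`,
#' `./.` and half-calls `-> NA`. Phased separators (`|`) are accepted.
#'
#' The TSV dialect is: header row of variant ids, first column the accession
#' label, remaining cells in \{0, 1, 2, NA\}. Variant coordinates are parsed
#' from ids of the form `chrom_pos` when possible, otherwise synthesised as
#' consecutive positions on one chromosome.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`.
#' @param multiallelic for VCF: `"skip"` (drop such records) or `"error"`.
#' @return a [geno_matrix].
#' @export
load_genotypes <- function(path, format = c("vcf", "tsv"),
                           multiallelic = c("skip", "error")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop_bad_arg("file not found: ", path)
  if (format == "vcf") load_genotypes_vcf(path, multiallelic)
  else load_genotypes_tsv(path)
}

load_genotypes_vcf <- function(path, multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) < 1L
  # keep single-nucleotide biallelic records only
  snp <- nchar(fix$REF) == 1L & nchar(gsub(",", "", fix$ALT)) >= 1L
  drop <- multi
  if (any(drop)) {
    if (multiallelic == "error")
      stop_bad_arg(sum(drop), " multiallelic/non-SNP record(s) in ", path)
    message("load_genotypes: skipped ", sum(drop),
            " multiallelic/non-SNP record(s)")
  }
  keep <- !drop & snp
  if (!any(keep)) stop_bad_arg("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0")] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% c("1/1")] <- 2
    out
  }
  dos <- apply(gt, 2, code)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  geno_matrix(t(dos),
              data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.numeric(fix$POS),
                         ref = fix$REF, alt = fix$ALT),
              accessions = colnames(gt))
}

load_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  if (ncol(dt) < 2) stop_bad_arg("dosage TSV needs >= 2 columns: ", path)
  acc <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  ids <- colnames(m)
  parsed <- regmatches(ids, regexec("^(.+)_([0-9]+)$", ids))
  ok <- lengths(parsed) == 3
  if (all(ok)) {
    chrom <- vapply(parsed, `[`, "", 2)
    pos <- as.numeric(vapply(parsed, `[`, "", 3))
  } else {
    chrom <- rep("chr1", length(ids))
    pos <- seq_along(ids)
  }
  rownames(m) <- acc
  geno_matrix(m, data.frame(id = ids, chrom = chrom, pos = pos), acc)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Inverse of `load_genotypes(format = "tsv")`: header row of variant ids,
#' first column `accession`, cells 0/1/2/NA.
#'
#' @param G a [geno_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(G, path) {
  dt <- data.table::data.table(accession = G$accessions)
  dt <- cbind(dt, data.table::as.data.table(G$dosages))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
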