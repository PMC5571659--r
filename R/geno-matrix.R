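#' Genotype matrix container
#'
#' Holds biallelic SNP dosages for a panel of accessions. Dosages count copies
#' of the alternate allele: 0 (homozygous reference), 1 (heterozygous), 2
#' (homozygous alternate), `NA` (missing). Rows are accessions, columns are
#' variants; variants are stored sorted by chromosome and strictly increasing
#' position, and variant ids are unique.
#'
#' @param dosages numeric matrix, accessions x variants, values in
#'   \{0, 1, 2, NA\}. Row names are taken as accession labels if present.
#' @param variants data.frame with columns `id`, `chrom`, `pos` and optionally
#'   `ref`, `alt`; one row per column of `dosages`.
#' @param accessions character vector of accession labels; defaults to the
#'   row names of `dosages`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (matrix), `variants` (data.frame), `accessions` (character).
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0, 1, 2, 2, 0, 0), nrow = 3,
#'          dimnames = list(c("a1", "a2", "a3"), NULL)),
#'   data.frame(id = c("v1", "v2"), chrom = "chr1", pos = c(100, 250))
#' )
#' n_variants(g)
#' @export
geno_matrix <- function(dosages, variants, accessions = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(accessions))
    accessions <- paste0("acc", seq_len(nrow(dosages)))
  accessions <- as.character(accessions)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!all(c("id", "chrom", "pos") %in% names(variants)))
    stop_bad_arg("`variants` needs columns id, chrom, pos")
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "T"
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.numeric(variants$pos)
  if (nrow(variants) != ncol(dosages))
    stop_bad_arg("variant table and dosage matrix dimensions disagree")
  if (length(accessions) != nrow(dosages))
    stop_bad_arg("accession labels and dosage matrix dimensions disagree")
  if (anyDuplicated(accessions))
    stop_bad_arg("duplicate accession labels: ",
                 paste(unique(accessions[duplicated(accessions)]), collapse = ", "))
  if (anyDuplicated(variants$id))
    stop_bad_arg("duplicate variant ids")
  if (any(variants$pos < 1)) stop_bad_arg("positions must be >= 1")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop_bad_arg("dosages must be 0, 1, 2 or NA")
  # enforce sort order within chromosome, chromosomes in order of appearance
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop_bad_arg("positions must be strictly increasing within ", ch)
  }
  rownames(variants) <- NULL
  dimnames(dosages) <- list(accessions, variants$id)
  structure(list(dosages = dosages, variants = variants,
                 accessions = accessions),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$accessions), "accessions x",
      nrow(x$variants), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing: %.3f%%  het: %.3f%%\n", 100 * miss,
              100 * mean(x$dosages == 1, na.rm = TRUE)))
  invisible(x)
}

#' Panel dimensions and summaries
#'
#' @param G a [geno_matrix].
#' @return `n_accessions()`/`n_variants()` return counts; `variant_maf()` the
#'   per-variant minor allele frequency computed on non-missing dosages;
#'   `variant_missing_rate()` the per-variant fraction of missing calls.
#' @export
n_accessions <- function(G) length(G$accessions)

#' @rdname n_accessions
#' @export
n_variants <- function(G) nrow(G$variants)

#' @rdname n_accessions
#' @export
variant_maf <- function(G) {
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @rdname n_accessions
#' @export
variant_missing_rate <- function(G) colMeans(is.na(G$dosages))

#' Subset a genotype matrix
#'
#' @param G a [geno_matrix].
#' @param accessions,variants index vectors (logical, integer or character)
#'   into accessions / variant ids; `NULL` keeps all.
#' @return a [geno_matrix] restricted to the selection, order preserved.
#' @export
subset_geno <- function(G, accessions = NULL, variants = NULL) {
  ai <- seq_along(G$accessions)
  vi <- seq_len(nrow(G$variants))
  if (!is.null(accessions)) {
    ai <- if (is.character(accessions)) match(accessions, G$accessions)
          else ai[accessions]
    if (anyNA(ai)) stop_bad_arg("unknown accession in subset")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, G$variants$id)
          else vi[variants]
    if (anyNA(vi)) stop_bad_arg("unknown variant in subset")
  }
  # keep positional sort: variant subsets must preserve panel order
  vi <- sort(vi)
  geno_matrix(G$dosages[ai, vi, drop = FALSE],
              G$variants[vi, , drop = FALSE],
              G$accessions[ai])
}
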