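#' Filter variants on minor allele frequency and missing rate
#'
#' Keeps variants with MAF >= `maf_min` and missing rate < `miss_max`.
#' MAF is `min(p, 1 - p)` with `p` the mean non-missing dosage divided by 2.
#' The accession set is unchanged; the operation is idempotent.
#'
#' @param G a [geno_matrix].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max strict upper bound on the per-variant missing call
#'   fraction (default 0.1).
#' @return a filtered [geno_matrix] (possibly with zero variants).
#' @export
filter_variants <- function(G, maf_min = 0.05, miss_max = 0.1) {
  stopifnot(inherits(G, "geno_matrix"))
  maf <- variant_maf(G)
  miss <- variant_missing_rate(G)
  keep <- !is.na(maf) & maf >= maf_min & miss < miss_max
  subset_geno(G, variants = which(keep))
}

#' Impute missing dosages by k nearest neighbours
#'
#' The distance between two accessions is the mean over co-observed variants
#' of `|g_i - g_j| / 2`. Each missing cell is replaced by the mean dosage of
#' the `k` nearest accessions (by that distance) that carry an observed call
#' at the variant, rounded to the nearest integer dosage; ties in distance
#' are broken by accession order. Observed cells are never altered.
#'
#' On near-homozygous (selfing) panels prefer `k = 1` or another odd/small
#' `k`: averaging several neighbours rounds bimodal 0/2 dosages toward
#' spurious heterozygote calls.
#'
#' @param G a [geno_matrix].
#' @param k neighbour count (default 5); at least `k + 1` accessions needed.
#' @return a [geno_matrix] with no missing cells.
#' @export
impute_knn <- function(G, k = 5) {
  stopifnot(inherits(G, "geno_matrix"), is_count(k))
  n <- n_accessions(G)
  if (n < k + 1) stop_bad_arg("need at least k + 1 = ", k + 1, " accessions")
  M <- G$dosages
  if (!anyNA(M)) return(G)
  all_missing <- colSums(!is.na(M)) == 0
  if (any(all_missing))
    stop_bad_arg("variant(s) missing in all accessions: ",
                 paste(G$variants$id[all_missing], collapse = ", "))
  D <- accession_distance(M)
  out <- M
  miss_var <- which(colSums(is.na(M)) > 0)
  for (v in miss_var) {
    gv <- M[, v]
    obs <- which(!is.na(gv))
    for (i in which(is.na(gv))) {
      cand <- obs
      # stable order: distance, then accession index
      nb <- cand[order(D[i, cand], cand)][seq_len(min(k, length(cand)))]
      out[i, v] <- round(mean(gv[nb]))
    }
  }
  geno_matrix(out, G$variants, G$accessions)
}

# pairwise mean |g_i - g_j| / 2 over co-observed variants, via one-hot
# indicator cross-products so that NA patterns cost nothing extra
accession_distance <- function(M) {
  O <- !is.na(M)
  A0 <- (M == 0) & O; A1 <- (M == 1) & O; A2 <- (M == 2) & O
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  storage.mode(O) <- "double"
  n01 <- tcrossprod(A0, A1); n12 <- tcrossprod(A1, A2)
  n02 <- tcrossprod(A0, A2)
  num <- (n01 + t(n01) + n12 + t(n12)) + 2 * (n02 + t(n02))
  co <- tcrossprod(O)
  d <- num / (2 * pmax(co, 1))
  d[co == 0] <- Inf  # no co-observed variants: maximal distance
  diag(d) <- 0
  d
}
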