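#' Simple-matching kinship matrix
#'
#' Pairwise genomic similarity `K[i, j] = mean over variants of
#' (1 - |g_i - g_j| / 2)`, the simple matching coefficient on 0/1/2 dosages.
#' `K` is symmetric with unit diagonal and entries in \[0, 1\]; it is used as
#' the covariance structure of the random genetic effects in the mixed model.
#'
#' @param G a complete (imputed) [geno_matrix] with at least 2 accessions.
#' @return numeric matrix (accessions x accessions) with dimnames.
#' @export
kinship_simple_matching <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  M <- G$dosages
  if (anyNA(M)) stop_bad_arg("kinship requires a complete (imputed) matrix")
  if (nrow(M) < 2) stop_bad_arg("need >= 2 accessions")
  m <- ncol(M)
  # |a-b| on {0,1,2} = (a-b)^2/2 + 1[|a-b| == 1]/2; the indicator counts
  # het/hom mismatches, obtained from the het indicator matrix
  ss <- rowSums(M^2)
  cp <- tcrossprod(M)
  d2 <- outer(ss, ss, "+") - 2 * cp
  H <- (M == 1); storage.mode(H) <- "double"
  hh <- tcrossprod(H)
  h <- rowSums(H)
  n1 <- outer(h, h, "+") - 2 * hh   # pairs with exactly one het
  absd <- d2 / 2 + n1 / 2
  K <- 1 - absd / (2 * m)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(G$accessions, G$accessions)
  K
}

#' Genotype principal components
#'
#' Column-centred (optionally scaled) dosage PCA. Returns per-accession
#' score vectors ordered by decreasing explained variance; computed through
#' the accession-by-accession cross-product when variants outnumber
#' accessions.
#'
#' @param G a complete [geno_matrix].
#' @param n_components number of components (default 3).
#' @param scale. scale columns to unit variance before decomposition
#'   (default `FALSE`; monomorphic columns are left unscaled).
#' @return numeric matrix (accessions x `n_components`) with an
#'   `explained_variance` attribute (fraction per component).
#' @export
genotype_pca <- function(G, n_components = 3, scale. = FALSE) {
  stopifnot(inherits(G, "geno_matrix"), is_count(n_components))
  M <- G$dosages
  if (anyNA(M)) stop_bad_arg("PCA requires a complete (imputed) matrix")
  X <- scale(M, center = TRUE, scale = FALSE)
  if (scale.) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  n <- nrow(X)
  C <- tcrossprod(X) / max(1, n - 1)
  e <- eigen(C, symmetric = TRUE)
  if (max(e$values, 0) <= 1e-12) {   # no genetic variance: all scores zero
    scores <- matrix(0, n, n_components,
                     dimnames = list(G$accessions,
                                     paste0("PC", seq_len(n_components))))
    attr(scores, "explained_variance") <- rep(0, n_components)
    return(scores)
  }
  rank <- sum(e$values > max(e$values, 0) * 1e-9)
  if (n_components > rank)
    stop_bad_arg("n_components (", n_components, ") exceeds rank (", rank, ")")
  idx <- seq_len(n_components)
  scores <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[idx], 0) * (n - 1)), n_components)
  dimnames(scores) <- list(G$accessions, paste0("PC", idx))
  attr(scores, "explained_variance") <-
    pmax(e$values[idx], 0) / sum(pmax(e$values, 0))
  scores
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' `r^2` is the squared Pearson correlation of the dosage vectors at two
#' variants over jointly observed accessions, the genotype-level composite
#' measure appropriate for unphased inbred lines. Symmetric in its arguments
#' and invariant under allele relabelling (`g -> 2 - g`).
#'
#' @param G a [geno_matrix].
#' @param a,b variant ids (or column indices).
#' @return a list of class `ld_value`: `a`, `b`, `r2`.
#' @export
ld_r2 <- function(G, a, b) {
  ia <- variant_index(G, a); ib <- variant_index(G, b)
  x <- G$dosages[, ia]; y <- G$dosages[, ib]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0)
    stop_bad_arg("LD undefined: monomorphic dosage vector for ",
                 G$variants$id[ia], " / ", G$variants$id[ib])
  structure(list(a = G$variants$id[ia], b = G$variants$id[ib],
                 r2 = cor(x, y)^2),
            class = "ld_value")
}

variant_index <- function(G, v) {
  i <- if (is.character(v)) match(v, G$variants$id) else as.integer(v)
  if (is.na(i) || i < 1 || i > n_variants(G))
    stop_bad_arg("unknown variant: ", v)
  i
}

# r^2 of one column against a set of columns; NA where undefined.
# internal fast path used by interval extension and Inter-LD.
ld_r2_vec <- function(M, i, js) {
  x <- M[, i]
  out <- rep(NA_real_, length(js))
  for (k in seq_along(js)) {
    y <- M[, js[k]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 2 && sd(x[ok]) > 0 && sd(y[ok]) > 0)
      out[k] <- cor(x[ok], y[ok])^2
  }
  out
}
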