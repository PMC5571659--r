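#' Narrow-sense heritability from the kinship mixed model
#'
#' `h2 = var_g / (var_g + var_e)` from the null mixed model
#' `y = mean + u + e`, `Var(u) = var_g K`, fitted by REML
#' (see [fit_null_mlm()]). Invariant to affine transforms of `y`.
#'
#' @param y named phenotype vector aligned to `K`'s accessions.
#' @param K kinship matrix (e.g. from [kinship_simple_matching()]).
#' @param X optional fixed-effect covariates (default: intercept only).
#' @param normalize Gower-centre and rescale `K` before fitting (default
#'   `TRUE`). Identity-by-state kinship carries a large constant
#'   off-diagonal baseline; without removing it `var_g` absorbs that
#'   constant and the ratio overstates heritability. Centring
#'   (`P K P` with `P = I - 11'/n`, rescaled so the mean diagonal is 1)
#'   makes `var_g` the variance of line deviations and the ratio a
#'   proportion of phenotypic variance.
#' @return heritability fraction in \[0, 1\].
#' @export
estimate_h2 <- function(y, K, X = NULL, normalize = TRUE) {
  if (var(y, na.rm = TRUE) == 0) stop_bad_arg("zero phenotypic variance")
  if (is.null(X)) X <- matrix(1, length(y), 1)
  if (normalize) K <- gower_center(K)
  fit <- fit_null_mlm(y, X, K)
  fit$var_g / (fit$var_g + fit$var_e)
}

# P K P with P = I - J/n, rescaled to mean diagonal 1
gower_center <- function(K) {
  n <- nrow(K)
  rm <- rowMeans(K)
  Kc <- K - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(K)
  Kc * (n / sum(diag(Kc)))
}

#' Classify a trait's distribution type
#'
#' Assigns one of four distribution classes used to group traits for
#' permutation thresholds: `binary` (exactly two distinct values),
#' `binary_like_quant` (the modal value holds more than `modal_cut` of
#' observations, e.g. a count that is mostly zero), `skewed_quant`
#' (absolute sample skewness above `skew_cut`), else `normal_quant`.
#'
#' @param values trait observations (numeric, or any type for the binary
#'   check); missing values are dropped. At least 20 non-missing
#'   observations required.
#' @param modal_cut modal-share cutoff for `binary_like_quant`
#'   (default 0.8).
#' @param skew_cut absolute-skewness cutoff for `skewed_quant` (default 1).
#' @return one of `"binary"`, `"binary_like_quant"`, `"skewed_quant"`,
#'   `"normal_quant"`.
#' @export
classify_trait_type <- function(values, modal_cut = 0.8, skew_cut = 1) {
  v <- values[!is.na(values)]
  if (length(v) < 20) stop_bad_arg("need >= 20 non-missing observations")
  nu <- length(unique(v))
  if (nu < 2) stop_bad_arg("constant trait: unclassifiable")
  if (nu == 2) return("binary")
  if (!is.numeric(v)) stop_bad_arg("non-binary trait must be numeric")
  modal <- max(table(v)) / length(v)
  if (modal > modal_cut) return("binary_like_quant")
  if (abs(sample_skewness(v)) > skew_cut) return("skewed_quant")
  "normal_quant"
}

#' Encode a two-level trait as 0/1
#'
#' Binary traits (e.g. flower colour) are converted to 0/1 before entering
#' trait-trait correlations; the first sorted level maps to 0.
#'
#' @param values a two-level vector.
#' @return numeric 0/1 vector (NA preserved).
#' @export
encode_binary_trait <- function(values) {
  lev <- sort(unique(values[!is.na(values)]))
  if (length(lev) != 2) stop_bad_arg("trait is not binary")
  as.numeric(match(values, lev) - 1)
}

#' Trait-trait Pearson correlations
#'
#' Pairwise-complete Pearson correlations across traits. Input is either a
#' wide matrix/data.frame (rows = accessions, columns = traits; binary
#' traits pre-encoded as 0/1, see [encode_binary_trait()]) or a
#' `pheno_table`, in which case per-accession means over environments and
#' replicates are correlated. Entries with fewer than 3 complete pairs are
#' set to `NA`.
#'
#' @param x wide numeric data, or a `pheno_table`.
#' @param traits optional subset of trait columns.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(x, traits = NULL) {
  if (inherits(x, "pheno_table")) {
    w <- aggregate(value ~ accession + trait, x, mean, na.action = NULL)
    x <- stats::reshape(w, idvar = "accession", timevar = "trait",
                        direction = "wide")
    rownames(x) <- x$accession
    x$accession <- NULL
    names(x) <- sub("^value\\.", "", names(x))
  }
  x <- as.matrix(x)
  if (!is.null(traits)) x <- x[, traits, drop = FALSE]
  storage.mode(x) <- "double"
  cc <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(x))
  cc[npair < 3] <- NA
  diag(cc) <- 1
  cc[is.nan(cc)] <- NA
  cc
}
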