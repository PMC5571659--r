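#' Precompute the decompositions used by the mixed-model scan
#'
#' Builds the eigendecomposition of `K` (for the rotated generalized
#' least-squares scan), the eigendecomposition of `K` projected against the
#' fixed effects `X` (for restricted-likelihood fits of the variance
#' components), and the rotated genotype matrix. The cache depends only on
#' `(G, X, K)`, so permutations, power replicates and repeated traits on the
#' same panel reuse it.
#'
#' @param G a complete [geno_matrix].
#' @param X fixed-effect design matrix (n x q), including the intercept;
#'   default intercept plus the first 3 genotype principal components.
#' @param K kinship matrix; default [kinship_simple_matching()] of `G`.
#' @return a list of class `mlm_cache`.
#' @export
mlm_scan_cache <- function(G, X = NULL, K = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  M <- G$dosages
  if (anyNA(M)) stop_bad_arg("the scan requires a complete (imputed) matrix")
  if (is.null(K)) K <- kinship_simple_matching(G)
  if (is.null(X)) X <- cbind(intercept = 1, genotype_pca(G, 3))
  X <- as.matrix(X)
  n <- nrow(M)
  if (nrow(X) != n || nrow(K) != n)
    stop_bad_arg("y/X/K/G row dimensions must agree")
  check_full_rank(X)
  q <- ncol(X)
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lambda <- pmax(eK$values, 0)
  U <- eK$vectors
  # projected kinship for REML: S K S with S = I - Q Q'
  Q <- qr.Q(qr(X))
  KQ <- K %*% Q
  SKS <- K - Q %*% crossprod(Q, K) - KQ %*% t(Q) +
    Q %*% (crossprod(Q, KQ)) %*% t(Q)
  eS <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
  UR <- eS$vectors[, seq_len(n - q), drop = FALSE]
  xi <- pmax(eS$values[seq_len(n - q)], 0)
  Gr <- crossprod(U, M)
  poly <- apply(M, 2, sd) > 0
  structure(list(U = U, lambda = lambda, UR = UR, xi = xi,
                 Xr = crossprod(U, X), q = q, n = n,
                 Gr = Gr, poly = poly, variants = G$variants,
                 accessions = G$accessions),
            class = "mlm_cache")
}

check_full_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- qrx$pivot[(qrx$rank + 1):ncol(X)]
    nm <- colnames(X) %||% paste0("col", seq_len(ncol(X)))
    stop_bad_arg("covariate matrix rank-deficient; collinear column(s): ",
                 paste(nm[bad], collapse = ", "))
  }
}

#' Fit the null mixed model by restricted maximum likelihood
#'
#' EMMA-style REML for `y = X b + u + e`, `Var(u) = var_g K`,
#' `Var(e) = var_e I`. The variance ratio `delta = var_e / var_g` maximises
#' the restricted likelihood over a log grid on \[1e-5, 1e5\] refined by
#' golden-section search to relative tolerance 1e-6, using a single
#' eigendecomposition of `K` projected against `X`.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design (n x q), including intercept.
#' @param K kinship matrix.
#' @param cache optional [mlm_scan_cache()] built on the same `X`/`K`.
#' @return a list of class `null_model_fit`: `var_g`, `var_e`, `delta`,
#'   `logREML`, `h2` (`var_g / (var_g + var_e)`).
#' @export
fit_null_mlm <- function(y, X = NULL, K = NULL, cache = NULL) {
  if (is.null(cache)) {
    if (is.null(X)) X <- matrix(1, length(y), 1)
    X <- as.matrix(X)
    check_full_rank(X)
    n <- length(y)
    q <- ncol(X)
    if (is.null(K)) stop_bad_arg("K required when no cache is given")
    Q <- qr.Q(qr(X))
    KQ <- K %*% Q
    SKS <- K - Q %*% crossprod(Q, K) - KQ %*% t(Q) +
      Q %*% (crossprod(Q, KQ)) %*% t(Q)
    eS <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
    UR <- eS$vectors[, seq_len(n - q), drop = FALSE]
    xi <- pmax(eS$values[seq_len(n - q)], 0)
  } else {
    UR <- cache$UR; xi <- cache$xi; n <- cache$n; q <- cache$q
  }
  if (length(y) != nrow(UR)) stop_bad_arg("y length does not match the model")
  if (anyNA(y)) stop_bad_arg("y must be complete")
  eta2 <- as.vector(crossprod(UR, y))^2
  nq <- n - q
  ll <- function(logd) {
    d <- exp(logd)
    s <- sum(eta2 / (xi + d))
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(s)) - sum(log(xi + d)))
  }
  grid <- log(10^seq(-5, 5, length.out = 101))
  vals <- vapply(grid, ll, 0)
  if (any(!is.finite(vals))) stop_bad_arg("non-finite restricted likelihood")
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-6)
  delta <- exp(opt$maximum)
  var_g <- sum(eta2 / (xi + delta)) / nq
  var_e <- delta * var_g
  structure(list(var_g = var_g, var_e = var_e, delta = delta,
                 logREML = opt$objective,
                 h2 = var_g / (var_g + var_e)),
            class = "null_model_fit")
}

#' Mixed-linear-model association scan
#'
#' EMMAX-style scan: the variance components are held fixed at the null-model
#' fit (the population-parameters-previously-determined approximation) and
#' each variant is tested by generalized least squares in the rotated
#' (decorrelated) basis. Effects and two-sided P values come from a Wald t
#' statistic with `n - q - 1` degrees of freedom. Variants monomorphic in
#' the analysed accessions are flagged untested (`NA` statistics), never
#' zero-filled.
#'
#' @param y phenotype vector aligned to the panel's accessions.
#' @param G a complete [geno_matrix] (ignored when `cache` is given).
#' @param X fixed-effect design; default intercept + first 3 PCs.
#' @param K kinship; default simple matching.
#' @param fit optional [fit_null_mlm()] result to reuse.
#' @param cache optional [mlm_scan_cache()]; build it once when scanning
#'   many traits or permutations on one panel.
#' @param trait,context labels stored on the result.
#' @return a data.frame of class `assoc_scan` with columns `id`, `chrom`,
#'   `pos`, `effect`, `se`, `p`, `n`, `tested`; attributes `trait`,
#'   `context`, `fit`.
#' @export
gwas_scan <- function(y, G = NULL, X = NULL, K = NULL, fit = NULL,
                      cache = NULL, trait = "trait",
                      context = "full_population") {
  if (is.null(cache)) cache <- mlm_scan_cache(G, X, K)
  if (length(y) != cache$n) stop_bad_arg("y length does not match the panel")
  if (anyNA(y)) stop_bad_arg("y must be complete")
  if (is.null(fit)) fit <- fit_null_mlm(y, cache = cache)
  w <- 1 / (fit$var_g * cache$lambda + fit$var_e)
  sw <- sqrt(w)
  yr <- as.vector(crossprod(cache$U, y)) * sw
  Xw <- cache$Xr * sw
  Qx <- qr.Q(qr(Xw))
  ry <- yr - Qx %*% crossprod(Qx, yr)
  Gw <- cache$Gr * sw
  RG <- Gw - Qx %*% crossprod(Qx, Gw)
  gg <- colSums(RG^2)
  gy <- as.vector(crossprod(RG, ry))
  df <- cache$n - cache$q - 1
  tested <- cache$poly & gg > max(gg, 0) * 1e-12
  effect <- se <- p <- rep(NA_real_, length(gg))
  b <- gy[tested] / gg[tested]
  rss <- sum(ry^2) - b * gy[tested]
  sigma2 <- pmax(rss, 0) / df
  se_t <- sqrt(sigma2 / gg[tested])
  tstat <- b / se_t
  effect[tested] <- b
  se[tested] <- se_t
  p[tested] <- 2 * pt(-abs(tstat), df)
  out <- data.frame(id = cache$variants$id, chrom = cache$variants$chrom,
                    pos = cache$variants$pos, effect = effect, se = se,
                    p = p, n = cache$n, tested = tested,
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "context") <- context
  attr(out, "fit") <- fit
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Permutation-derived genome-wide significance threshold
#'
#' Shuffles the phenotype to break genotype-phenotype links, re-fits the
#' null variance components (cheap through the cached eigendecomposition),
#' runs a full scan and records the genome-wide minimum P value; repeated
#' `n_perm` times. The threshold is the empirical `alpha`-quantile (lowest
#' order statistic convention) of the minimum-P distribution, i.e. the P
#' cutoff with an `alpha` chance of any genome-wide false positive.
#'
#' @inheritParams gwas_scan
#' @param n_perm number of permutations (default 1000); fewer than 20
#'   triggers a warning (quantile unstable).
#' @param alpha type-I error target (default 0.05).
#' @param seed integer seed driving the shuffles.
#' @return a list of class `perm_threshold`: `trait`, `n_perm`, `alpha`,
#'   `threshold` (P-value scale), `minus_log10_minp` (one per permutation).
#' @export
derive_permutation_threshold <- function(y, G = NULL, X = NULL, K = NULL,
                                         n_perm = 1000, alpha = 0.05,
                                         seed = 1, cache = NULL,
                                         trait = "trait") {
  if (!is_count(n_perm)) stop_bad_arg("n_perm must be a positive count")
  if (n_perm < 20) warning("n_perm < 20: empirical quantile is unstable")
  if (is.null(cache)) cache <- mlm_scan_cache(G, X, K)
  minp <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      sc <- gwas_scan(yp, cache = cache)
      min(sc$p, na.rm = TRUE)
    }, 0)
  })
  k <- max(1L, ceiling(alpha * n_perm))
  structure(list(trait = trait, n_perm = n_perm, alpha = alpha,
                 threshold = sort(minp)[k],
                 minus_log10_minp = -log10(minp)),
            class = "perm_threshold")
}

threshold_value <- function(x) {
  if (inherits(x, "perm_threshold")) x$threshold else as.numeric(x)
}

#' Genomic inflation factor
#'
#' Median-based lambda: `median(qchisq(1 - p, 1)) / qchisq(0.5, 1)` over
#' tested variants. Values near 1 indicate well-controlled population
#' structure.
#'
#' @param scan an `assoc_scan` (or a vector of P values).
#' @return numeric lambda.
#' @export
genomic_inflation <- function(scan) {
  p <- if (inherits(scan, "assoc_scan")) scan$p[scan$tested] else scan
  p <- p[!is.na(p)]
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}

#' Conventional fixed genome-wide thresholds by trait type
#'
#' Permutation-derived thresholds group tightly by trait distribution type,
#' so fixed presets are commonly reused instead of re-permuting: on the
#' -log10 scale, 6.7 for binary/normal/skewed quantitative traits and 8.3
#' for binary-like quantitative traits in the full-population scan; 6.6 and
#' 8.4 for the corresponding subgroup (secondary) scans. `2e-7` is the
#' rounded full-population cutoff for normally distributed traits.
#'
#' @param tier `"primary"` (full population) or `"secondary"` (subgroup
#'   re-scan).
#' @return named numeric vector of P-value cutoffs for trait types
#'   `binary`, `normal_quant`, `skewed_quant`, `binary_like_quant`.
#' @export
genomewide_thresholds <- function(tier = c("primary", "secondary")) {
  tier <- match.arg(tier)
  if (tier == "primary")
    c(binary = 10^-6.7, normal_quant = 10^-6.7, skewed_quant = 10^-6.7,
      binary_like_quant = 10^-8.3)
  else
    c(binary = 10^-6.6, normal_quant = 10^-6.6, skewed_quant = 10^-6.6,
      binary_like_quant = 10^-8.4)
}
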