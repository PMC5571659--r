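#' Simulate an additive quantitative trait
#'
#' Draws `n_qtn` causal variants (QTNs) uniformly without replacement from
#' the panel's polymorphic variants, assigns per-allele additive effects from
#' the chosen model, forms genetic values as the dosage-weighted sum and adds
#' residual noise scaled so that the realised sample heritability equals the
#' target exactly (the noise is orthogonalised against the genetic values
#' in-sample before scaling).
#'
#' Effect models: `"gaussian"` draws effects i.i.d. from a standard normal,
#' the convention of mixed-model GWAS power studies and the package default
#' (it yields the mixture of major and minor QTNs that real power curves
#' imply); `"geometric"` sets the k-th effect proportional to `0.9^k` with
#' random signs; `"equal"` gives all QTNs the same magnitude with random
#' signs.
#'
#' @param G a complete [geno_matrix].
#' @param n_qtn number of causal variants (>= 1).
#' @param h2 target narrow-sense heritability, in (0, 1).
#' @param effect_model `"gaussian"`, `"geometric"` or `"equal"`.
#' @param seed integer seed.
#' @return a list: `phenotype` (named numeric vector over accessions) and
#'   `truth`, a `sim_truth` list with `causal_ids`, `causal_idx`, `effects`,
#'   `variance_explained` (per-QTN share of phenotypic variance, summing to
#'   `h2`), `h2`, and `epistatic_pairs` (`NULL` here).
#' @export
simulate_additive_trait <- function(G, n_qtn, h2,
                                    effect_model = c("gaussian", "geometric",
                                                     "equal"),
                                    seed = 1) {
  stopifnot(inherits(G, "geno_matrix"))
  effect_model <- match.arg(effect_model)
  if (!is_count(n_qtn)) stop_bad_arg("n_qtn must be a positive count")
  if (!is.numeric(h2) || h2 <= 0 || h2 >= 1)
    stop_bad_arg("h2 must be in (0, 1)")
  M <- G$dosages
  if (anyNA(M)) stop_bad_arg("trait simulation requires a complete matrix")
  poly <- which(apply(M, 2, sd) > 0)
  if (n_qtn > length(poly))
    stop_bad_arg("n_qtn exceeds polymorphic variant count")
  withr::with_seed(seed, {
    causal <- sort(sample(poly, n_qtn))
    beta <- switch(effect_model,
      gaussian  = rnorm(n_qtn),
      geometric = 0.9^seq_len(n_qtn) * sample(c(-1, 1), n_qtn, replace = TRUE),
      equal     = sample(c(-1, 1), n_qtn, replace = TRUE))
    gv <- as.vector(M[, causal, drop = FALSE] %*% beta)
    e <- rnorm(length(gv))
  })
  y <- add_scaled_noise(gv, e, h2)
  vg <- var(gv)
  vy <- vg / h2
  per_var <- beta^2 * apply(M[, causal, drop = FALSE], 2, var)
  truth <- structure(list(
    causal_ids = G$variants$id[causal],
    causal_idx = causal,
    effects = beta,
    variance_explained = h2 * per_var / sum(per_var),
    h2 = h2,
    epistatic_pairs = NULL), class = "sim_truth")
  list(phenotype = setNames(y, G$accessions), truth = truth)
}

# add noise orthogonal to gv in-sample, scaled so var(gv)/var(y) == h2 exactly
add_scaled_noise <- function(gv, e, h2) {
  if (var(gv) == 0) stop_bad_arg("genetic values are constant")
  e <- e - mean(e)
  e <- e - gv * (sum(e * (gv - mean(gv))) / sum((gv - mean(gv))^2))
  e <- e / sd(e) * sqrt(var(gv) * (1 - h2) / h2)
  gv + e
}

#' Simulate a trait with a background-conditional (epistatic) locus
#'
#' The background locus acts additively everywhere; the dependent locus
#' contributes `beta_dep * dosage` only in accessions homozygous for the
#' background allele (dosage 2 at the background locus). This reproduces the
#' allele-specific pattern in which a locus is detectable only within one
#' homozygous background subgroup. Residual noise is scaled to the exact
#' sample heritability as in [simulate_additive_trait()].
#'
#' @param G a complete [geno_matrix].
#' @param background,dependent variant ids (or indices); must be distinct
#'   and in low LD (`r2 < 0.2`), otherwise the design is confounded.
#' @param beta_bg,beta_dep per-allele effects.
#' @param h2 target heritability of the combined genetic value, in (0, 1).
#' @param seed integer seed.
#' @return as [simulate_additive_trait()]; `truth$epistatic_pairs` is a
#'   one-row data.frame (background, dependent, conditional effect).
#' @export
simulate_epistatic_trait <- function(G, background, dependent,
                                     beta_bg, beta_dep, h2, seed = 1) {
  stopifnot(inherits(G, "geno_matrix"))
  ib <- variant_index(G, background); id <- variant_index(G, dependent)
  if (ib == id) stop_bad_arg("background and dependent loci must differ")
  r2 <- ld_r2(G, ib, id)$r2
  if (r2 >= 0.2)
    stop_bad_arg("loci in high LD (r2 = ", signif(r2, 3),
                 "): confounded design")
  if (!is.numeric(h2) || h2 <= 0 || h2 >= 1)
    stop_bad_arg("h2 must be in (0, 1)")
  M <- G$dosages
  if (anyNA(M)) stop_bad_arg("trait simulation requires a complete matrix")
  carrier <- M[, ib] == 2
  gv <- beta_bg * M[, ib] + beta_dep * M[, id] * as.numeric(carrier)
  e <- withr::with_seed(seed, rnorm(length(gv)))
  y <- add_scaled_noise(gv, e, h2)
  truth <- structure(list(
    causal_ids = G$variants$id[c(ib, id)],
    causal_idx = c(ib, id),
    effects = c(beta_bg, beta_dep),
    variance_explained = NULL,
    h2 = h2,
    epistatic_pairs = data.frame(background = G$variants$id[ib],
                                 dependent = G$variants$id[id],
                                 conditional_effect = beta_dep)),
    class = "sim_truth")
  list(phenotype = setNames(y, G$accessions), truth = truth)
}

#' Simulate a multi-environment phenotype table
#'
#' `value(i, j, k) = mean + env_j + line_i + gxe_ij + e_ijk`, with line,
#' line-by-environment and residual terms drawn independently at the stated
#' variances. Line effects may be supplied (e.g. genetic values from
#' [simulate_additive_trait()]) instead of drawn.
#'
#' @param G a [geno_matrix] (supplies accession labels).
#' @param n_envs number of environments (year-location combinations).
#' @param env_effects per-environment fixed shifts (length `n_envs`;
#'   default 0).
#' @param var_line,var_gxe,var_resid variance components (>= 0).
#' @param reps replicates per accession x environment (default 3).
#' @param line_effects optional fixed per-accession effects overriding the
#'   random draw.
#' @param trait trait label (default `"trait1"`).
#' @param mean overall mean (default 0).
#' @param seed integer seed.
#' @return a long-format data.frame (`accession`, `environment`,
#'   `replicate`, `trait`, `value`) of class `pheno_table`.
#' @export
simulate_multienv <- function(G, n_envs, env_effects = rep(0, n_envs),
                              var_line = 1, var_gxe = 0.5, var_resid = 0.5,
                              reps = 3, line_effects = NULL,
                              trait = "trait1", mean = 0, seed = 1) {
  stopifnot(inherits(G, "geno_matrix"), is_count(n_envs), is_count(reps))
  if (any(c(var_line, var_gxe, var_resid) < 0))
    stop_bad_arg("variances must be >= 0")
  if (length(env_effects) != n_envs)
    stop_bad_arg("env_effects must have length n_envs")
  n <- n_accessions(G)
  withr::with_seed(seed, {
    line <- if (is.null(line_effects)) rnorm(n, 0, sqrt(var_line))
            else rep_len(as.numeric(line_effects), n)
    gxe <- matrix(rnorm(n * n_envs, 0, sqrt(var_gxe)), n, n_envs)
    e <- array(rnorm(n * n_envs * reps, 0, sqrt(var_resid)),
               c(n, n_envs, reps))
  })
  out <- expand.grid(accession = G$accessions,
                     environment = paste0("env", seq_len(n_envs)),
                     replicate = seq_len(reps),
                     stringsAsFactors = FALSE)
  i <- match(out$accession, G$accessions)
  j <- match(out$environment, paste0("env", seq_len(n_envs)))
  out$trait <- trait
  out$value <- mean + env_effects[j] + line[i] + gxe[cbind(i, j)] +
    e[cbind(i, j, out$replicate)]
  attr(out, "out.attrs") <- NULL
  rownames(out) <- NULL
  class(out) <- c("pheno_table", "data.frame")
  out
}

#' Size a conditional effect for a target subgroup variance share
#'
#' Solves for the `beta_dep` of [simulate_epistatic_trait()] such that,
#' within the background-carrier subgroup, the dependent locus explains the
#' requested share of phenotypic variance once the residual noise has been
#' scaled to the overall heritability `h2`. (The residual variance depends
#' on the total genetic variance, which itself depends on `beta_dep`, so the
#' share is the root of a one-dimensional equation.)
#'
#' @inheritParams simulate_epistatic_trait
#' @param share target fraction of phenotypic variance explained by the
#'   dependent locus within the carrier subgroup, in (0, 1).
#' @return the positive `beta_dep`.
#' @export
size_conditional_effect <- function(G, background, dependent, beta_bg, h2,
                                    share = 0.1) {
  ib <- variant_index(G, background); idp <- variant_index(G, dependent)
  M <- G$dosages
  carrier <- M[, ib] == 2
  A <- beta_bg * M[, ib]
  Dm <- M[, idp] * as.numeric(carrier)
  vA <- var(A); vD <- var(Dm); cAD <- cov(A, Dm)
  vdep_c <- var(M[carrier, idp])
  f <- function(b) {
    ve <- (1 - h2) / h2 * (vA + b^2 * vD + 2 * b * cAD)
    b^2 * vdep_c / (b^2 * vdep_c + ve) - share
  }
  stats::uniroot(f, c(1e-6, 1e4))$root
}
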