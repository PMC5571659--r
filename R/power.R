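#' Configuration for the power/FDR simulation grid
#'
#' Defaults reproduce the standard assessment grid: 2, 5 or 10 causal QTNs
#' crossed with heritabilities 0.25, 0.5 and 0.75, scored on LD(>0.6)
#' intervals at the genome-wide threshold 2e-7. The replicate default is the
#' desk-scale 200; raise `n_replicates` to 1000 for a full run.
#'
#' @param qtn_counts causal-variant counts per trait (default `c(2, 5, 10)`).
#' @param h2_levels heritability levels (default `c(0.25, 0.5, 0.75)`).
#' @param n_replicates replicates per grid cell (default 200).
#' @param threshold genome-wide P cutoff (default 2e-7).
#' @param interval_ld LD contiguity for scoring intervals (default 0.6).
#' @param effect_model effect-size law for [simulate_additive_trait()]
#'   (default `"gaussian"`).
#' @param fdr_convention for replicates with zero detection intervals:
#'   `"exclude"` from the FDR average (default) or count as `"zero"`.
#' @param seed integer master seed.
#' @return a list of class `power_config`.
#' @export
power_config <- function(qtn_counts = c(2, 5, 10),
                         h2_levels = c(0.25, 0.5, 0.75),
                         n_replicates = 200, threshold = 2e-7,
                         interval_ld = 0.6,
                         effect_model = c("gaussian", "geometric", "equal"),
                         fdr_convention = c("exclude", "zero"), seed = 1) {
  effect_model <- match.arg(effect_model)
  fdr_convention <- match.arg(fdr_convention)
  if (!all(qtn_counts >= 1)) stop_bad_arg("qtn_counts must be >= 1")
  if (!all(h2_levels > 0 & h2_levels < 1))
    stop_bad_arg("h2_levels must be in (0, 1)")
  if (!is_count(n_replicates)) stop_bad_arg("n_replicates must be a count")
  structure(list(qtn_counts = qtn_counts, h2_levels = h2_levels,
                 n_replicates = n_replicates, threshold = threshold,
                 interval_ld = interval_ld, effect_model = effect_model,
                 fdr_convention = fdr_convention, seed = seed),
            class = "power_config")
}

#' Score one replicate's detections against the simulated truth
#'
#' Intervals are the LD-contiguous regions around above-threshold SNPs
#' (built with [detect_sals()] at `cfg$interval_ld`). Statistical power is
#' variance-weighted: the summed variance explained of causal loci falling
#' inside at least one interval, divided by the total causal variance
#' explained. FDR is the fraction of intervals containing no causal locus;
#' a replicate with no interval has FDR `NA` (excluded from averages) or 0,
#' per `cfg$fdr_convention`.
#'
#' @param scan an `assoc_scan` of the replicate.
#' @param truth the `sim_truth` from [simulate_additive_trait()].
#' @param G the scanned [geno_matrix].
#' @param cfg a [power_config].
#' @return a list: `power`, `fdr`, `n_intervals`, `intervals` (the
#'   `sal_table`).
#' @export
score_detections <- function(scan, truth, G, cfg) {
  if (!all(truth$causal_ids %in% G$variants$id))
    stop_bad_arg("truth causal variants are not all panel variants")
  ints <- detect_sals(scan, cfg$threshold, G, ld_min = cfg$interval_ld)
  causal_idx <- match(truth$causal_ids, G$variants$id)
  v <- truth$variance_explained
  if (nrow(ints)) {
    member_idx <- lapply(ints$members, match, table = G$variants$id)
    span_lo <- vapply(member_idx, min, 0L)
    span_hi <- vapply(member_idx, max, 0L)
    captured <- vapply(causal_idx, function(ci)
      any(ci >= span_lo & ci <= span_hi), TRUE)
    empty <- vapply(seq_len(nrow(ints)), function(i)
      !any(causal_idx >= span_lo[i] & causal_idx <= span_hi[i]), TRUE)
    power <- sum(v[captured]) / sum(v)
    fdr <- sum(empty) / nrow(ints)
  } else {
    power <- 0
    fdr <- if (cfg$fdr_convention == "zero") 0 else NA_real_
  }
  list(power = power, fdr = fdr, n_intervals = nrow(ints), intervals = ints)
}

#' Run the power/FDR simulation grid
#'
#' For every (QTN count, heritability) cell and replicate: draw a causal
#' set, simulate an additive trait, re-fit the null mixed model, scan all
#' variants, build detection intervals at the genome-wide threshold and
#' score variance-weighted power and FDR. The scan machinery (kinship,
#' principal components, eigendecompositions, rotated genotypes) is built
#' once per panel and reused across replicates, which is what makes the
#' full grid tractable on one CPU. Fully reproducible given `cfg$seed`;
#' per-replicate failures are caught, logged and excluded from averages.
#'
#' @param G a complete, filtered [geno_matrix].
#' @param cfg a [power_config].
#' @param n_pcs principal-component covariates (default 3).
#' @param cache optional prebuilt [mlm_scan_cache()].
#' @param verbose print per-cell progress (default `FALSE`).
#' @return a data.frame of class `power_result`: one row per grid cell with
#'   `qtn`, `h2`, `power_mean`, `power_se`, `fdr_mean`, `fdr_se`, `n_ok`.
#' @export
run_power_experiment <- function(G, cfg = power_config(), n_pcs = 3,
                                 cache = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "power_config"))
  if (is.null(cache))
    cache <- mlm_scan_cache(G, cbind(intercept = 1, genotype_pca(G, n_pcs)))
  grid <- expand.grid(qtn = cfg$qtn_counts, h2 = cfg$h2_levels)
  seeds <- matrix(derive_seeds(cfg$seed, nrow(grid) * cfg$n_replicates),
                  nrow(grid), cfg$n_replicates)
  rows <- lapply(seq_len(nrow(grid)), function(gi) {
    pw <- fd <- rep(NA_real_, cfg$n_replicates)
    n_fail <- 0L
    for (r in seq_len(cfg$n_replicates)) {
      res <- tryCatch({
        sim <- simulate_additive_trait(G, grid$qtn[gi], grid$h2[gi],
                                       effect_model = cfg$effect_model,
                                       seed = seeds[gi, r])
        scan <- gwas_scan(sim$phenotype, cache = cache)
        score_detections(scan, sim$truth, G, cfg)
      }, error = function(e) e)
      if (inherits(res, "error")) n_fail <- n_fail + 1L
      else { pw[r] <- res$power; fd[r] <- res$fdr }
    }
    ok <- !is.na(pw)
    okf <- !is.na(fd)
    if (verbose)
      message(sprintf("qtn=%d h2=%.2f: power=%.3f fdr=%.3f (%d ok)",
                      grid$qtn[gi], grid$h2[gi], mean(pw[ok]),
                      mean(fd[okf]), sum(ok)))
    data.frame(qtn = grid$qtn[gi], h2 = grid$h2[gi],
               power_mean = mean(pw[ok]),
               power_se = sd(pw[ok]) / sqrt(sum(ok)),
               fdr_mean = if (any(okf)) mean(fd[okf]) else NA_real_,
               fdr_se = if (sum(okf) > 1) sd(fd[okf]) / sqrt(sum(okf))
                        else NA_real_,
               n_ok = sum(ok))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_result", "data.frame")
  out
}
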