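#' Split a population by genotype at a SAL peak
#'
#' Accessions are partitioned into the two homozygous dosage classes (0 and
#' 2) at the peak variant of a primary SAL; heterozygous and missing calls
#' are excluded (sensible for a selfing panel where heterozygosity is near
#' zero). A group is analysable only if it holds strictly more than `min_n`
#' accessions.
#'
#' @param G a [geno_matrix].
#' @param sal a one-row `sal_table` (or a peak variant id).
#' @param min_n strict minimum group size for analysis (default 100).
#' @return a list of class `subgroup_split`: `split_variant`, `groups`
#'   (named list `hom_ref` / `hom_alt` of accession labels), `excluded`,
#'   `analyzable` (named logical).
#' @export
split_population <- function(G, sal, min_n = 100) {
  peak <- if (is.character(sal)) sal else unlist(sal$peak_id)[1]
  i <- variant_index(G, peak)
  g <- G$dosages[, i]
  hom_ref <- G$accessions[!is.na(g) & g == 0]
  hom_alt <- G$accessions[!is.na(g) & g == 2]
  excluded <- setdiff(G$accessions, c(hom_ref, hom_alt))
  analyzable <- c(hom_ref = length(hom_ref) > min_n,
                  hom_alt = length(hom_alt) > min_n)
  if (length(hom_ref) == 0 || length(hom_alt) == 0)
    stop_bad_arg("split rejected: ", G$variants$id[i],
                 " is monomorphic among homozygous calls")
  if (!any(analyzable))
    stop_bad_arg("split rejected: no homozygous class at ",
                 G$variants$id[i], " exceeds ", min_n, " accessions")
  structure(list(split_variant = G$variants$id[i],
                 groups = list(hom_ref = hom_ref, hom_alt = hom_alt),
                 excluded = excluded, analyzable = analyzable,
                 min_n = min_n),
            class = "subgroup_split")
}

#' Genotype-conditioned subgroup re-scan
#'
#' Runs the mixed-model scan separately in each analysable homozygous
#' subgroup at a primary SAL peak. Per subgroup, variants are re-filtered
#' (MAF >= `maf_min` within the subgroup), the kinship matrix and principal
#' components are recomputed from the subgroup accessions (set
#' `recompute = FALSE` to subset the full-panel covariates instead), the
#' null model is re-fitted and SALs are detected against the subgroup
#' threshold. A subgroup SAL is tiered `secondary` iff it does not
#' [sal_overlap()] any primary SAL of the trait.
#'
#' @param y named phenotype vector over the full panel's accessions.
#' @param G a complete [geno_matrix].
#' @param split a [split_population()] result.
#' @param thresholds significance threshold(s): a single value /
#'   `perm_threshold`, or a named list (`hom_ref`, `hom_alt`). Use
#'   `"permutation"` to derive a fresh permutation threshold per subgroup.
#' @param primary_sals `sal_table` of the trait's primary SALs (for novelty
#'   tiering); may be empty.
#' @param n_pcs number of principal-component covariates (default 3).
#' @param maf_min per-subgroup MAF filter (default 0.05).
#' @param recompute recompute kinship/PCs within each subgroup
#'   (default `TRUE`).
#' @param n_perm,alpha,seed permutation settings when
#'   `thresholds = "permutation"`.
#' @param ld_min LD contiguity for subgroup SAL intervals (default 0.6).
#' @return a list of class `conditional_scan`: `split`, `scans` (per
#'   subgroup `assoc_scan` or an error condition), `thresholds` (per
#'   subgroup, numeric), `sals` (subgroup `sal_table`s row-bound, tier
#'   `secondary` for novel loci, `known` otherwise).
#' @export
conditional_gwas <- function(y, G, split, thresholds = 2e-7,
                             primary_sals = NULL, n_pcs = 3, maf_min = 0.05,
                             recompute = TRUE, n_perm = 1000, alpha = 0.05,
                             seed = 1, ld_min = 0.6) {
  stopifnot(inherits(split, "subgroup_split"))
  if (is.null(names(y))) names(y) <- G$accessions
  scans <- list(); thr_used <- list(); sal_list <- list()
  for (grp in names(split$groups)[split$analyzable]) {
    res <- tryCatch({
      acc <- split$groups[[grp]]
      Gs <- subset_geno(G, accessions = acc)
      Gs <- filter_variants(Gs, maf_min = maf_min, miss_max = 1.01)
      Ks <- if (recompute) kinship_simple_matching(Gs) else {
        K_full <- kinship_simple_matching(G)
        K_full[acc, acc]
      }
      Xs <- if (recompute) cbind(intercept = 1, genotype_pca(Gs, n_pcs))
            else cbind(intercept = 1,
                       genotype_pca(G, n_pcs)[match(acc, G$accessions), ,
                                              drop = FALSE])
      cache <- mlm_scan_cache(Gs, Xs, Ks)
      ys <- y[acc]
      thr <- if (identical(thresholds, "permutation"))
        derive_permutation_threshold(ys, cache = cache, n_perm = n_perm,
                                     alpha = alpha, seed = seed)
      else if (is.list(thresholds) && !inherits(thresholds, "perm_threshold"))
        thresholds[[grp]]
      else thresholds
      sc <- gwas_scan(ys, cache = cache,
                      trait = "trait", context = grp)
      sals <- detect_sals(sc, thr, Gs, ld_min = ld_min, tier = "secondary")
      list(scan = sc, threshold = threshold_value(thr), sals = sals,
           G_sub = Gs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      scans[[grp]] <- res
      next
    }
    scans[[grp]] <- res$scan
    thr_used[[grp]] <- res$threshold
    sals <- res$sals
    if (nrow(sals)) {
      sals$context <- grp
      if (!is.null(primary_sals) && nrow(primary_sals)) {
        novel <- vapply(seq_len(nrow(sals)), function(i) {
          !any(vapply(seq_len(nrow(primary_sals)), function(j)
            sal_overlap(sal_row(sals, i), sal_row(primary_sals, j), G), TRUE))
        }, TRUE)
        sals$tier <- ifelse(novel, "secondary", "known")
      }
      sal_list[[grp]] <- sals
    }
  }
  all_sals <- if (length(sal_list)) do.call(rbind, sal_list) else
    detect_sals(structure(data.frame(id = character(), chrom = character(),
                                     pos = numeric(), effect = numeric(),
                                     se = numeric(), p = numeric(),
                                     n = integer(), tested = logical()),
                          class = c("assoc_scan", "data.frame")),
                1, subset_geno(G, variants = integer(0)))
  rownames(all_sals) <- NULL
  structure(list(split = split, scans = scans, thresholds = thr_used,
                 sals = all_sals),
            class = "conditional_scan")
}

#' Classify the epistatic pattern of a secondary locus
#'
#' A secondary locus shows the allele-specific (epistatic) pattern when its
#' peak passes the subgroup threshold in exactly one of the two homozygous
#' subgroups; a locus significant in both subgroups is an ordinary additive
#' signal. If the peak passes in neither subgroup no call is made, and if
#' only one subgroup was analysable the pattern is undeterminable.
#'
#' @param cond a [conditional_gwas()] result.
#' @param secondary one row of `cond$sals` (a `sal_table` row or its index).
#' @param primary the primary `sal_table` row the split was made on
#'   (stored on the call for reporting; optional).
#' @return a list of class `epistasis_call`: `primary`, `secondary_peak`,
#'   `pattern` (`"one_subgroup_only"`, `"both_subgroups"`, `"none"` or
#'   `"undeterminable"`), `subgroup` (of detection, for the one-subgroup
#'   pattern), `p_by_subgroup`.
#' @export
classify_epistasis <- function(cond, secondary, primary = NULL) {
  stopifnot(inherits(cond, "conditional_scan"))
  if (is.numeric(secondary)) secondary <- sal_row(cond$sals, secondary)
  else if (inherits(secondary, "data.frame")) secondary <- sal_row(secondary, 1)
  ok <- vapply(cond$scans, inherits, TRUE, what = "assoc_scan")
  if (sum(ok) < 2)
    return(structure(list(primary = primary,
                          secondary_peak = secondary$peak_id,
                          pattern = "undeterminable", subgroup = NA_character_,
                          p_by_subgroup = NULL), class = "epistasis_call"))
  pvals <- vapply(names(cond$scans), function(grp) {
    sc <- cond$scans[[grp]]
    i <- match(secondary$peak_id, sc$id)
    if (is.na(i)) NA_real_ else sc$p[i]
  }, 0)
  hits <- !is.na(pvals) &
    pvals <= vapply(names(pvals), function(g)
      cond$thresholds[[g]] %||% Inf, 0)
  pattern <- if (sum(hits) == 1) "one_subgroup_only"
             else if (sum(hits) == 2) "both_subgroups"
             else "none"
  structure(list(primary = primary, secondary_peak = secondary$peak_id,
                 pattern = pattern,
                 subgroup = if (sum(hits) == 1) names(hits)[hits]
                            else NA_character_,
                 p_by_subgroup = pvals),
            class = "epistasis_call")
}
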