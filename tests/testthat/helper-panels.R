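# Shared fixture builders. Panels are generated in code, cached per test run.

.panel_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.panel_cache[[key]])) .panel_cache[[key]] <- force(expr)
  .panel_cache[[key]]
}

# hand-built genotype matrix from a dosage matrix (one chromosome unless
# chrom given); positions 100, 200, ...
make_geno <- function(dos, chrom = NULL, pos = NULL) {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) {
    pos <- integer(m)
    for (ch in unique(chrom)) pos[chrom == ch] <- 100 * seq_len(sum(chrom == ch))
  }
  rownames(dos) <- paste0("a", seq_len(nrow(dos)))
  geno_matrix(dos, data.frame(id = paste0(chrom, "_", pos),
                              chrom = chrom, pos = pos))
}

# small structured panel reused across modules
small_panel <- function() cached("small", simulate_panel(
  panel_config(n_accessions = 300, n_variants = 1000, n_chromosomes = 5,
               n_subpops = 3, seed = 4242)))

# medium panel for scan-level tests
scan_panel <- function() cached("scan", {
  G <- simulate_panel(panel_config(n_accessions = 500, n_variants = 2000,
                                   n_chromosomes = 10, n_subpops = 4,
                                   seed = 2024))
  list(G = G, cache = mlm_scan_cache(G))
})

# independent-variant panel (no LD, no structure) with identity kinship
indep_panel <- function(n = 300, m = 1000, seed = 99) {
  withr::with_seed(seed, {
    p <- runif(m, 0.1, 0.9)
    dos <- matrix(2 * rbinom(n * m, 1, rep(p, each = n)), n, m)
  })
  G <- make_geno(dos)
  K <- diag(n)
  dimnames(K) <- list(G$accessions, G$accessions)
  list(G = G, K = K)
}

# brute-force Inter-LD oracle: plain double loops over member SNPs
brute_inter_ld <- function(ma, mb, G) {
  r2 <- function(u, v) {
    x <- G$dosages[, u]; y <- G$dosages[, v]
    cor(x, y)^2
  }
  cross <- mean(outer(ma, mb, Vectorize(r2)))
  pmax1 <- function(mm) {
    means <- sapply(mm, function(u) mean(sapply(mm, function(v)
      if (u == v) 1 else r2(u, v))))
    max(means)
  }
  pa <- pmax1(ma); pb <- pmax1(mb)
  list(cross_ld = cross, pmax_a = pa, pmax_b = pb,
       inter_ld = 0.5 * (cross / pa + cross / pb))
}

# brute-force power/FDR scorer on explicit interval spans
brute_score <- function(span_lo, span_hi, causal_idx, v) {
  if (length(span_lo) == 0)
    return(list(power = 0, fdr = NA_real_))
  cap <- sapply(causal_idx, function(ci) any(ci >= span_lo & ci <= span_hi))
  emp <- sapply(seq_along(span_lo), function(i)
    !any(causal_idx >= span_lo[i] & causal_idx <= span_hi[i]))
  list(power = sum(v[cap]) / sum(v), fdr = sum(emp) / length(span_lo))
}

# conditional-scan fixture: 809 accessions with a background locus (carrier
# fraction ~0.6), an unlinked background-conditional locus and an unlinked
# additive control locus. Mildly related panel: the subgroup re-scan
# property concerns the method's power gain, not the effective-sample-size
# cost of close kin.
cond_fixture <- function() cached("cond", {
  G <- simulate_panel(panel_config(n_accessions = 809, n_variants = 2000,
                                   n_chromosomes = 10, n_subpops = 4,
                                   founder_share = 0.25, seed = 21))
  M <- G$dosages
  p2 <- colMeans(M == 2)
  bg <- which(p2 > 0.55 & p2 < 0.65 & G$variants$chrom == "chr1")[1]
  cand <- which(G$variants$chrom == "chr5" & apply(M, 2, sd) > 0.5)
  dep <- cand[which(ld_r2_vec(M, bg, cand) < 0.05)[1]]
  add <- {
    cand2 <- which(G$variants$chrom == "chr8" & apply(M, 2, sd) > 0.5)
    cand2[which(ld_r2_vec(M, bg, cand2) < 0.05)[1]]
  }
  list(G = G, bg = bg, dep = dep, add = add, cache = mlm_scan_cache(G))
})
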