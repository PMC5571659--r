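#' Configuration for a synthetic genotype panel
#'
#' Defaults emulate a selfing-species diversity panel of the size used in
#' large crop association studies: 809 accessions, 20,000 biallelic SNPs on
#' 20 chromosomes, 4 subpopulations with moderate divergence, LD blocks of
#' 10 variants, a 0.05 MAF floor and near-zero heterozygosity.
#'
#' @param n_accessions,n_variants,n_chromosomes,n_subpops panel dimensions.
#' @param fst_like_divergence Balding-Nichols-style divergence of
#'   subpopulation allele frequencies around the ancestral frequency,
#'   in \[0, 1).
#' @param ld_block_length variants per LD block.
#' @param maf_floor minimum realised minor allele frequency (< 0.5).
#' @param het_rate expected fraction of heterozygous calls.
#' @param founder_share fraction of each accession's latent blocks copied
#'   from a within-subpopulation founder line (families of about four
#'   accessions per founder), in \[0, 1). Germplasm collections hold groups
#'   of related lines; 0 gives a panel of unrelated accessions.
#' @param seed integer seed; generation is a pure function of the config.
#' @return a list of class `panel_config`.
#' @export
panel_config <- function(n_accessions = 809, n_variants = 20000,
                         n_chromosomes = 20, n_subpops = 4,
                         fst_like_divergence = 0.1, ld_block_length = 10,
                         maf_floor = 0.05, het_rate = 0.0017,
                         founder_share = 0.5, seed = 1) {
  cfg <- list(n_accessions = n_accessions, n_variants = n_variants,
              n_chromosomes = n_chromosomes, n_subpops = n_subpops,
              fst_like_divergence = fst_like_divergence,
              ld_block_length = ld_block_length, maf_floor = maf_floor,
              het_rate = het_rate, founder_share = founder_share,
              seed = seed)
  for (f in c("n_accessions", "n_variants", "n_chromosomes", "n_subpops",
              "ld_block_length"))
    if (!is_count(cfg[[f]])) stop_bad_arg(f, " must be a positive count")
  for (f in c("fst_like_divergence", "het_rate", "founder_share"))
    if (!is_fraction(cfg[[f]]) || cfg[[f]] >= 1)
      stop_bad_arg(f, " must be in [0, 1)")
  if (!is.numeric(cfg$maf_floor) || cfg$maf_floor < 0 || cfg$maf_floor >= 0.5)
    stop_bad_arg("maf_floor must be in [0, 0.5)")
  if (cfg$n_subpops > cfg$n_accessions)
    stop_bad_arg("more subpopulations than accessions")
  structure(cfg, class = "panel_config")
}

#' Simulate a structured genotype panel
#'
#' Generates an inbred diversity panel with subpopulation structure and
#' block LD. Variants are grouped into consecutive blocks; within a block
#' each accession carries a latent block haplotype (drawn from its
#' subpopulation's block frequency, itself a Balding-Nichols draw around a
#' shared ancestral frequency) and each variant copies that haplotype with a
#' small variant-specific flip probability, producing high within-block and
#' low cross-block r-squared. Dosages are homozygous (0/2) except for a
#' `het_rate` fraction of heterozygous calls. Variants whose realised MAF
#' falls below `maf_floor` are resampled.
#'
#' @param cfg a [panel_config].
#' @return a complete [geno_matrix]; deterministic given `cfg` (including
#'   its seed).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  withr::with_seed(cfg$seed, simulate_panel_impl(cfg))
}

simulate_panel_impl <- function(cfg) {
  n <- cfg$n_accessions; m <- cfg$n_variants
  subpop <- rep_len(seq_len(cfg$n_subpops), n)
  chrom <- paste0("chr", rep_len(seq_len(cfg$n_chromosomes), m))
  chrom <- chrom[order(match(chrom, unique(chrom)))]
  # positions: random increasing within chromosome
  pos <- unlist(lapply(table(factor(chrom, unique(chrom))), function(k)
    cumsum(sample(500:5000, k, replace = TRUE))), use.names = FALSE)
  block <- integer(m)
  b <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    nb <- ceiling(length(idx) / cfg$ld_block_length)
    block[idx] <- b + rep(seq_len(nb), each = cfg$ld_block_length)[seq_along(idx)]
    b <- b + nb
  }
  n_block <- max(block)
  F <- cfg$fst_like_divergence
  anc <- runif(n_block, 0.1, 0.9)
  pfreq <- matrix(0, n_block, cfg$n_subpops)   # block freq per subpop
  for (s in seq_len(cfg$n_subpops))
    pfreq[, s] <- bn_draw(anc, F)
  # latent block haplotype per accession: accessions within a subpopulation
  # descend from a small founder set (germplasm collections hold related
  # lines), each copying a founder's block haplotypes and resampling a
  # fraction of blocks from the subpopulation frequency
  Z <- matrix(0L, n, n_block)
  for (s in seq_len(cfg$n_subpops)) {
    rows <- which(subpop == s)
    ns <- length(rows)
    n_f <- max(2L, ceiling(ns / 4))
    Zf <- matrix(rbinom(n_f * n_block, 1L, rep(pfreq[, s], each = n_f)),
                 n_f, n_block)
    fam <- sample.int(n_f, ns, replace = TRUE)
    Zs <- Zf[fam, , drop = FALSE]
    sw <- matrix(runif(ns * n_block) >= cfg$founder_share, ns, n_block)
    fresh <- matrix(rbinom(ns * n_block, 1L, rep(pfreq[, s], each = ns)),
                    ns, n_block)
    Zs[sw] <- fresh[sw]
    Z[rows, ] <- Zs
  }
  flip <- runif(m, 0.01, 0.15)   # per-variant decoupling from the block
  A <- matrix(0L, n, m)
  for (v in seq_len(m)) {
    z <- Z[, block[v]]
    fl <- rbinom(n, 1L, flip[v])
    A[, v] <- ifelse(fl == 1L, rbinom(n, 1L, 0.5), z)
  }
  dos <- 2 * A
  if (cfg$het_rate > 0) {
    het <- runif(n * m) < cfg$het_rate
    dos[het] <- 1
  }
  # enforce the MAF floor on the final dosages: redraw offending variants as
  # fresh block-free variants with a safely interior frequency
  for (pass in 1:25) {
    p <- colMeans(dos) / 2
    bad <- which(pmin(p, 1 - p) < cfg$maf_floor)
    if (!length(bad)) break
    for (v in bad) {
      pv <- runif(1, 0.2, 0.8)
      ps <- bn_draw(rep(pv, cfg$n_subpops), F)
      gv <- 2L * rbinom(n, 1L, ps[subpop])
      gv[runif(n) < cfg$het_rate] <- 1L
      dos[, v] <- gv
    }
  }
  ids <- paste0(chrom, "_", pos)
  g <- geno_matrix(dos, data.frame(id = ids, chrom = chrom, pos = pos),
                   accessions = sprintf("acc%04d", seq_len(n)))
  attr(g, "subpop") <- subpop
  g
}

# Balding-Nichols draw of subpopulation frequencies around ancestral p
bn_draw <- function(p, F) {
  if (F < 1e-8) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  pmin(pmax(stats::rbeta(length(p), a, b), 1e-3), 1 - 1e-3)
}
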