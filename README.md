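# assocnet

Mixed-model GWAS, conditional subgroup scans and trait–locus networks for
inbred diversity panels.

Association studies in selfing crops face three recurring problems beyond
the single-trait scan: epistatic loci whose effects exist only in one
genetic background and vanish in a whole-population analysis; choosing a
genome-wide significance threshold that respects the panel's LD and each
trait's distribution; and making sense of dozens of traits whose
significant loci overlap. assocnet packages the full chain for these
problems — and a synthetic-data generator with the statistical structure of
a real panel (subpopulations, LD blocks, founder relatedness, MAF floor,
near-zero heterozygosity), so every stage is testable without any
sequencing data.

## What it computes

* **Genotype layer** — VCF/TSV dosage input, MAF ≥ 0.05 / missing-rate
  < 0.1 filtering, k-nearest-neighbour imputation, simple-matching kinship
  `K[i,j] = 1 − mean|gᵢ − gⱼ|/2`, genotype principal components, dosage
  LD (`r²`).
* **Scan layer** — EMMAX-style mixed linear model
  `y = Xβ + u + ε`, `Var(u) = σ²_g K`, REML variance components from one
  eigendecomposition, per-marker generalized-least-squares Wald tests, and
  permutation-derived genome-wide thresholds (empirical 5% quantile of the
  permuted minimum-P distribution).
* **Locus layer** — significantly associated loci (SALs): peak SNPs with
  LD-contiguous intervals (`r² ≥ 0.6` with the peak), overlap tests, BED/TSV
  export.
* **Conditional layer** — the epistasis method: split the panel at a
  primary SAL peak into its two homozygous classes (> 100 accessions each),
  re-scan each subgroup with re-derived kinship/PCs/MAF, tier novel loci as
  secondary, and classify `one_subgroup_only` (allele-specific) vs
  `both_subgroups` patterns.
* **Network layer** — Inter-LD between SALs,
  `½·(LD(S₁,S₂)/PmaxLD(S₁) + LD(S₁,S₂)/PmaxLD(S₂))`, trait–locus networks
  with merged pleiotropic nodes (edges kept at Inter-LD ≥ 0.4), key-node
  ranking, favourable-allele stacking curves, GraphML/SIF export.
* **Assessment layer** — variance-weighted statistical power and
  interval-wise FDR over a (QTN count × h²) simulation grid at threshold
  2 × 10⁻⁷.
* **Phenotype layer** — cross-environment BLUP (fixed: mean + environment;
  random: line, line×environment) by EM-REML, narrow-sense heritability
  from the kinship model, trait-type classification, trait–trait
  correlations.

## A worked example

```r
library(assocnet)

G <- simulate_panel(panel_config(n_accessions = 400, n_variants = 4000,
                                 n_chromosomes = 10, seed = 7))
sim <- simulate_additive_trait(G, n_qtn = 4, h2 = 0.5, seed = 8)

cache <- mlm_scan_cache(G)            # kinship + PCs + eigendecompositions
scan  <- gwas_scan(sim$phenotype, cache = cache)
thr   <- derive_permutation_threshold(sim$phenotype, cache = cache,
                                      n_perm = 200, seed = 9)
sals  <- detect_sals(scan, thr, G)
sals[, c("chrom", "start", "end", "peak_id", "min_p", "n_members")]
```

```
#>   chrom  start    end     peak_id        min_p n_members
#> 1  chr5 759303 784408 chr5_776126 3.460124e-19        10
#> 2  chr4 369597 391077 chr4_374216 2.409516e-10         7
#> 3  chr5 421510 449284 chr5_425404 1.641189e-09        10
#> 4  chr4 400379 400379 chr4_400379 9.998513e-09         1
#> 5  chr4 367310 367310 chr4_367310 1.061553e-05         1
#> 6  chr4 395825 395825 chr4_395825 1.992156e-05         1
```

Each row is one locus: an LD-contiguous interval around the scan's peak
SNP, with `min_p` the peak P value and `n_members` the interval's SNP
count, at the permutation-derived threshold (`thr$threshold`, here
2.6 × 10⁻⁵ from 200 shuffles). This trait was simulated with four causal
SNPs; the three carrying meaningful variance shares (`chr5_776126` 27%,
`chr5_425404` 15%, `chr4_369597` 8%, per `sim$truth$variance_explained`)
each sit inside one of the top three detected intervals, while the fourth
(0.4% of variance) is — correctly — not found. From here,
`split_population()` + `conditional_gwas()` re-scan the two homozygous
subgroups at a primary peak, and `build_network()` links loci across
traits by Inter-LD.

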