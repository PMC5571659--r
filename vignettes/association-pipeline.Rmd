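---
title: "Models and methods behind assocnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind assocnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

assocnet implements an association-mapping pipeline for selfing-species
diversity panels: genotype QC, an EMMAX-style mixed-linear-model (MLM) scan
with permutation thresholds, detection of significantly associated loci
(SALs) as LD-contiguous intervals, a genotype-conditioned subgroup re-scan
for epistatic and minor-effect loci, Inter-LD trait–locus networks,
variance-weighted power/FDR simulation, and cross-environment BLUP. This
vignette documents the models, the tunable parameters, the synthetic-data
generator, and the numerical choices, in the order a user meets them.

## The mixed model and the scan

For a phenotype $y$ ($n$ accessions), covariates $X$ (intercept plus the
first three genotype principal components by default) and kinship $K$, the
null model is

$$ y = X\beta + u + \varepsilon,\qquad u \sim N(0, \sigma_g^2 K),\quad
\varepsilon \sim N(0, \sigma_e^2 I). $$

`fit_null_mlm()` estimates $\delta = \sigma_e^2/\sigma_g^2$ by restricted
maximum likelihood using a single eigendecomposition of $K$ projected
against $X$; the profile restricted likelihood is evaluated on a
$\log_{10}$ grid over $[10^{-5}, 10^5]$ (101 points) and the best bracket is
refined by golden-section search to relative tolerance $10^{-6}$.
`gwas_scan()` then holds the variance components fixed (the
"population parameters previously determined" approximation) and tests each
variant by generalized least squares in the basis that diagonalises
$\sigma_g^2 K + \sigma_e^2 I$, reporting a Wald $t$ statistic with
$n - q - 1$ degrees of freedom. Variants that are monomorphic among the
analysed accessions are flagged `tested = FALSE` with `NA` statistics, never
zero-filled. With $K = I$ (or $\sigma_g^2 = 0$) the scan reduces exactly to
covariate-adjusted ordinary least squares; the test suite verifies the
equivalence to $10^{-8}$.

Kinship is the simple matching coefficient on 0/1/2 dosages,
$K_{ij} = 1 - \overline{|g_i - g_j|}/2$, the similarity measure appropriate
for a nearly homozygous panel. Two notes on its use:

* **Scans** use $K$ as is. Its large constant off-diagonal baseline lies in
  the span of the intercept and does not disturb the per-marker tests.
* **Heritability** (`estimate_h2()`) Gower-centres and rescales $K$ first
  ($PKP$ with $P = I - \mathbf{1}\mathbf{1}'/n$, mean diagonal scaled to 1).
  Without this, $\sigma_g^2$ absorbs the baseline and the ratio
  $\sigma_g^2/(\sigma_g^2+\sigma_e^2)$ badly overstates heritability (a 0.25
  trait reads as roughly 0.5). With it, simulated traits at $h^2 \in
  \{0.25, 0.5, 0.75\}$ on an 800-accession panel are recovered within
  $\pm 0.1$.

## Permutation thresholds and trait types

`derive_permutation_threshold()` shuffles the phenotype (breaking
genotype–phenotype links while keeping the genotype correlation structure),
re-fits the null variance components — cheap, because the projected
eigendecomposition is cached — re-scans, and records the genome-wide
minimum P value. The threshold is the empirical $\alpha$-quantile (lowest
order statistic convention, $k = \lceil \alpha \cdot n_\mathrm{perm}
\rceil$) of that distribution: the cutoff with an $\alpha$ chance of any
genome-wide false positive. On a panel of independent variants it lands
near the Šidák value $1 - (1-\alpha)^{1/M}$; LD between variants raises
(relaxes) it, which is the point of deriving it empirically. Defaults:
1000 permutations, $\alpha = 0.05$.

Traits are grouped for thresholding by `classify_trait_type()`: `binary`
(exactly two values), `binary_like_quant` (modal value holding more than
80% of observations), `skewed_quant` (absolute sample skewness above 1),
else `normal_quant`. The 80% and skewness-1 cutoffs are this package's
quantification of the verbal classes and are arguments, not constants.
Binary traits enter correlation analyses as 0/1 codes
(`encode_binary_trait()`).

## SAL detection

`detect_sals()` turns a scan plus a threshold into loci: repeatedly take
the unassigned significant variant with the lowest P value as a peak (ties
broken by leftmost position), extend the interval over consecutive panel
variants while $r^2$ with the peak stays at or above `ld_min = 0.6`, absorb
every significant variant inside the interval, and repeat. Extension is
peak-anchored ("the consecutive region in LD with the associated locus");
a chained mode (`mode = "chain"`, $r^2$ against the previous variant
outward) is available. A neighbour whose LD is undefined (monomorphic)
stops the extension. Every significant variant belongs to exactly one SAL,
and detection is invariant to the order of scan records. Two SALs are the
same signal (`sal_overlap()`) when their intervals intersect positionally
or their peaks have $r^2 \ge 0.6$.

## The conditional subgroup re-scan

The epistasis method is deliberately simple: split the panel into the two
homozygous dosage classes at a primary SAL peak (`split_population()`;
heterozygous and missing calls are excluded — in a selfing panel they are a
fraction of a percent), and re-run the full machinery inside each subgroup
with more than 100 accessions (a strict inequality). Within a subgroup the
background locus is constant, so a locus whose effect requires that
background stands out, while its whole-population marginal effect — diluted
by the non-carrier fraction — may sit far from the genome-wide threshold.
`conditional_gwas()` re-applies the MAF filter, recomputes kinship and
principal components within the subgroup (a `recompute = FALSE` flag
subsets the full-panel versions instead), fits, scans, and detects SALs
against per-subgroup thresholds (fresh permutations or fixed overrides). A
subgroup SAL that overlaps no primary SAL is tiered `secondary`.
`classify_epistasis()` calls the pattern `one_subgroup_only` when the
secondary peak passes the threshold in exactly one subgroup — the
allele-specific signature — and `both_subgroups` for ordinary additive
signals. One split level only; there is no recursion into sub-subgroups.

## Inter-LD networks, key nodes, allele stacking

The link strength between two SALs is

$$ \mathrm{InterLD}(S_1, S_2) = \tfrac12\left(
\frac{\mathrm{LD}(S_1,S_2)}{\mathrm{PmaxLD}(S_1)} +
\frac{\mathrm{LD}(S_1,S_2)}{\mathrm{PmaxLD}(S_2)}\right), $$

where $\mathrm{LD}(S_1,S_2)$ is the mean pairwise $r^2$ between all member
SNPs of the two loci and $\mathrm{PmaxLD}(S)$ is the largest per-SNP mean
$r^2$ within $S$ (self pairs included, so a single-SNP locus has
$\mathrm{PmaxLD} = 1$ and Inter-LD collapses to the plain $r^2$). The
implementation is checked against an independent brute-force double loop to
$10^{-12}$. `build_network()` merges overlapping SALs across traits into
single locus nodes (members: the union), draws trait–locus membership
edges, and keeps locus–locus edges with Inter-LD at or above
`edge_min = 0.4` (a raw mean-$r^2$ gate is available behind
`edge_stat = "cross_ld"`). Node scores are the lowest member P value.
`key_nodes()` ranks locus nodes by the number of distinct traits reachable
through their own edges (direct membership plus one Inter-LD hop) — the
pleiotropy candidates. `allele_stacking()` counts, per accession, loci
homozygous for the favourable allele (a dosage mode exists) and summarises
the trait by that count together with a least-squares trend.

## Power and FDR simulation

`run_power_experiment()` crosses QTN counts $\{2, 5, 10\}$ with
heritabilities $\{0.25, 0.5, 0.75\}$. Per replicate: draw the causal set,
simulate the trait, re-fit the null model, scan, build detection intervals
around every SNP passing $2\times10^{-7}$ with the LD-0.6 rule, and score

* power = variance-weighted fraction of causal loci inside at least one
  interval (weights: per-causal variance explained);
* FDR = fraction of intervals containing no causal locus.

Replicates with no interval contribute power by the formula (typically 0)
and are excluded from the FDR average by default (`fdr_convention =
"zero"` counts them as 0; the right convention is genuinely ambiguous).
The scan cache — kinship, PCs, both eigendecompositions and the rotated
genotype matrix — is built once per panel, which is what makes 200
replicates on an 809 × 20,000 panel run in minutes on one CPU. The desk
default is 200 replicates; 1000 reproduces a full study-scale run.

## The synthetic-data generator

`simulate_panel()` emulates a selfing diversity panel: 809 accessions,
20,000 SNPs on 20 chromosomes, 4 subpopulations whose block frequencies are
Balding–Nichols draws (divergence 0.1) around shared ancestral frequencies,
LD blocks of 10 variants (each variant copies a latent block haplotype with
a 1–15% flip rate), a 0.05 MAF floor enforced by resampling, and a 0.17%
heterozygote rate. Within a subpopulation, accessions descend from founder
lines (families of about four), copying `founder_share = 0.5` of their
latent blocks from the founder — germplasm collections contain clades of
related lines, and without relatedness nearest-neighbour imputation has no
information to exploit. Fixtures vary this deliberately: the imputation
masking test uses 0.85 (tight families), the conditional-scan fixtures 0.25
(so that subgroup power reflects the method, not kinship shrinkage).

`simulate_additive_trait()` draws causal variants uniformly from the
panel's polymorphic SNPs, so the causal SNP itself is always genotyped.
Effect models: `gaussian` (i.i.d. standard normal, the default — it
produces the mixture of major and minor QTNs that realistic power curves
imply), `geometric` ($0.9^k$ with random signs) and `equal`. Residual noise
is orthogonalised against the genetic values in-sample and scaled so the
realised sample heritability equals the target exactly; this removes one
layer of Monte-Carlo noise from power experiments. Per-causal variance
explained is recorded as $h^2 \beta_k^2 \mathrm{Var}(g_k) / \sum_j
\beta_j^2 \mathrm{Var}(g_j)$ — normalised shares that sum to $h^2$ by
construction and coincide with the direct definition for loci in weak
mutual LD.

`simulate_epistatic_trait()` adds a background-conditional locus: the
dependent locus contributes only in accessions homozygous for the
background allele. `size_conditional_effect()` solves the one-dimensional
root problem of choosing the conditional effect so the dependent locus
explains a requested share of within-carrier variance after the overall-h²
noise scaling. `simulate_multienv()` produces long-format phenotype tables
with line, line-by-environment and residual components at stated variances.

What the generator does **not** emulate: coalescent genealogies,
recombination maps, selection, allele-frequency spectra skewed toward rare
variants, and the marker density of resequencing data (20,000 synthetic
SNPs versus millions of real markers). The last point matters when reading
the power simulation: with the causal SNP genotyped, clean LD blocks and
moderate marker count, the detected peak is almost always the causal SNP
itself, so variance-weighted power saturates near 1 for any well-powered
cell and the interval-misplacement losses of dense real data (a proxy peak
whose LD-0.6 interval misses the causal site) do not occur. Passing power
tests here validate the scoring machinery and the qualitative ordering
(power rises with $h^2$, falls with QTN count at matched $h^2$), not the
absolute power of any real study.

## Cross-environment BLUP

`fit_multienv_blup()` fits, per trait,
`value = mean + environment (fixed) + line + line:environment + residual`
by EM-REML on Henderson's mixed-model equations (dense solves — intended
for panel-scale data, not millions of records), convergence at relative
tolerance $10^{-6}$, at most 500 iterations, non-convergence flagged and
the last iterate returned. EM guarantees non-negative components; the EM
starting values come from the environment-adjusted variance so the fit is
invariant to per-environment shifts. With one environment the
line-by-environment component is pinned at 0. Replicate records feed the
residual by default (`average_replicates = TRUE` collapses them to plot
means first). The test suite cross-checks variance components and
predictions against lme4's REML on a balanced design, and verifies the
noiseless limit (predictions equal centred line means), shrinkage, and
zero-centring.

## Numerical and degenerate-input choices

* Dosages are `{0, 1, 2, NA}`; heterozygote dosage is 1 throughout, with no
  het exclusion at the genotype layer (at a 0.17% het rate the choice is
  numerically immaterial but fixed).
* Coordinates are 1-based inclusive everywhere; BED exports convert to
  0-based half-open.
* kNN imputation distance ignores pairs with missing cells; imputed values
  are rounded means over the k nearest observed neighbours, ties broken by
  accession order; prefer small odd `k` on inbred panels (see above).
* QC order is impute-then-filter when imputation is enabled, and MAF is
  computed on post-imputation dosages; both steps are plain functions, so
  the other order is one line.
* PCA uses the accession-space eigendecomposition when variants outnumber
  accessions; a zero-variance panel returns all-zero scores; requesting
  more components than the matrix rank is an error.
* `ld_r2` on a monomorphic vector is an error, not 0 — callers that merely
  need "stop extending" semantics (interval building) treat it as a break.
* The kinship used in scans gets no ridge; PSD is only needed up to the
  projected eigendecomposition, where small negative eigenvalues are
  clipped at 0.
* Test problem sizes are scaled to desk hardware: panels of 300–809
  accessions and 400–20,000 variants, 200 power replicates, 500
  permutations; every simulation is seeded and the generators are pure
  functions of their inputs and seed.

## A worked example

```{r, eval = FALSE}
library(assocnet)

G <- simulate_panel(panel_config(n_accessions = 400, n_variants = 4000,
                                 n_chromosomes = 10, seed = 7))
sim <- simulate_additive_trait(G, n_qtn = 4, h2 = 0.5, seed = 8)

cache <- mlm_scan_cache(G)          # kinship + PCs + eigendecompositions
scan <- gwas_scan(sim$phenotype, cache = cache)
thr <- derive_permutation_threshold(sim$phenotype, cache = cache,
                                    n_perm = 200, seed = 9)
sals <- detect_sals(scan, thr, G)
sals[, c("chrom", "start", "end", "peak_id", "min_p", "n_members")]

sp <- split_population(G, sals[1, ], min_n = 100)
cond <- conditional_gwas(sim$phenotype, G, sp, thresholds = thr$threshold,
                         primary_sals = sals)
cond$sals
```

## Known limitations

* The power/FDR absolute levels are generator-dependent (see above); only
  orderings and the scorer itself are validated.
* EM-REML converges linearly; for variance ratios near a boundary it can
  take hundreds of iterations (the lme4 cross-check in the tests converges
  the same fits in milliseconds — EM is kept for its transparency and
  guaranteed non-negative components at this scale).
* The kNN imputer is a transparent stand-in for web-service imputation
  tools whose algorithms are unpublished; it is labelled as such and tested
  against a masking oracle, not against any external tool.
* Binary traits are analysed as 0/1 quantitative codes; there are no
  threshold/liability models.
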