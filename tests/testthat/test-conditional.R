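test_that("population splits count homozygous classes and exclude the rest", {
  # constructed peak: 150 hom-ref, 600 hom-alt, 59 het or missing
  withr::with_seed(2, {
    g <- sample(c(rep(0, 150), rep(2, 600), rep(1, 39), rep(NA, 20)))
  })
  dos <- cbind(g, rep(c(0, 2), length.out = 809))
  G <- make_geno(dos)
  sp <- split_population(G, G$variants$id[1], min_n = 100)
  expect_length(sp$groups$hom_ref, 150)
  expect_length(sp$groups$hom_alt, 600)
  expect_length(sp$excluded, 59)
  expect_true(all(sp$analyzable))
})

test_that("the group-size rule is a strict 'more than min_n'", {
  g <- c(rep(0, 100), rep(2, 101))
  G <- make_geno(cbind(g, rep(c(0, 2), length.out = 201)))
  sp <- split_population(G, G$variants$id[1], min_n = 100)
  expect_false(sp$analyzable[["hom_ref"]])   # exactly 100: not analysed
  expect_true(sp$analyzable[["hom_alt"]])
  # a monomorphic peak cannot define a split
  G2 <- make_geno(cbind(rep(2, 201), rep(c(0, 2), length.out = 201),
                        rep(c(0, 0, 2), length.out = 201)))
  expect_error(split_population(G2, G2$variants$id[1]), "monomorphic")
  # both classes at or below min_n: rejected
  G3 <- make_geno(cbind(rep(c(0, 2), length.out = 201),
                        rep(c(0, 0, 2), length.out = 201)))
  expect_error(split_population(G3, G3$variants$id[1], min_n = 150),
               "rejected")
})

test_that("subgroup scans are restricted to subgroup accessions end-to-end", {
  fx <- cond_fixture()
  sim <- simulate_additive_trait(fx$G, 3, 0.5, seed = 31)
  sp <- split_population(fx$G, fx$G$variants$id[fx$bg], min_n = 100)
  cond <- conditional_gwas(sim$phenotype, fx$G, sp, thresholds = 2e-7)
  for (grp in names(sp$groups)) {
    expect_s3_class(cond$scans[[grp]], "assoc_scan")
    expect_equal(unique(cond$scans[[grp]]$n), length(sp$groups[[grp]]))
  }
})

test_that("a null trait produces no secondary loci", {
  fx <- cond_fixture()
  y <- withr::with_seed(12, rnorm(n_accessions(fx$G)))
  names(y) <- fx$G$accessions
  sp <- split_population(fx$G, fx$G$variants$id[fx$bg], min_n = 100)
  cond <- conditional_gwas(y, fx$G, sp, thresholds = 2e-7)
  expect_equal(nrow(cond$sals), 0)
})

test_that("a background-conditional locus is missed genome-wide but found in the carrier subgroup", {
  fx <- cond_fixture()
  G <- fx$G
  bd <- size_conditional_effect(G, fx$bg, fx$dep, beta_bg = 2, h2 = 0.7,
                                share = 0.1)
  sim <- simulate_epistatic_trait(G, fx$bg, fx$dep, 2, bd, h2 = 0.7, seed = 2)
  y <- sim$phenotype
  scan <- gwas_scan(y, cache = fx$cache)
  dep_id <- G$variants$id[fx$dep]
  expect_gt(scan$p[fx$dep], 2e-7)           # invisible in the full population
  primary <- detect_sals(scan, 2e-7, G)
  expect_true(G$variants$id[fx$bg] %in% unlist(primary$members))
  sp <- split_population(G, primary[1, ], min_n = 100)
  cond <- conditional_gwas(y, G, sp, thresholds = 2e-7,
                           primary_sals = primary)
  expect_gt(nrow(cond$sals), 0)
  hit <- sapply(seq_len(nrow(cond$sals)), function(i)
    dep_id %in% cond$sals$members[[i]])
  expect_true(any(hit & cond$sals$tier == "secondary"))
  call <- classify_epistasis(cond, which(hit)[1], primary = primary[1, ])
  expect_equal(call$pattern, "one_subgroup_only")
  expect_equal(call$subgroup, "hom_alt")    # only in background carriers
})

test_that("an additive second locus is detected in both subgroups", {
  fx <- cond_fixture()
  G <- fx$G
  M <- G$dosages
  # strong background plus an unconditional second locus sized to a 15%
  # whole-population variance share at overall h2 = 0.7
  share_of <- function(b) {
    gv <- 2 * M[, fx$bg] + b * M[, fx$add]
    0.7 * b^2 * var(M[, fx$add]) / var(gv)
  }
  b_add <- uniroot(function(b) share_of(b) - 0.15, c(0.01, 50))$root
  gv <- 2 * M[, fx$bg] + b_add * M[, fx$add]
  e <- withr::with_seed(8, rnorm(length(gv)))
  y <- gv + (e - mean(e)) / sd(e) * sqrt(var(gv) * 0.3 / 0.7)
  names(y) <- G$accessions
  scan <- gwas_scan(y, cache = fx$cache)
  primary <- detect_sals(scan, 2e-7, G)
  sp <- split_population(G, primary[1, ], min_n = 100)
  cond <- conditional_gwas(y, G, sp, thresholds = 2e-7,
                           primary_sals = primary)
  add_id <- G$variants$id[fx$add]
  hit <- sapply(seq_len(nrow(cond$sals)), function(i)
    add_id %in% cond$sals$members[[i]])
  expect_true(any(hit))   # re-detected in at least one subgroup
  call <- classify_epistasis(cond, which(hit)[1])
  expect_equal(call$pattern, "both_subgroups")
})

test_that("classification is undeterminable with a single analysable subgroup", {
  fx <- cond_fixture()
  G <- fx$G
  M <- G$dosages
  # a split variant with a small minor class
  small_class <- which(colMeans(M == 0) > 0.02 & colMeans(M == 0) < 0.1)[1]
  expect_false(is.na(small_class))
  sim <- simulate_additive_trait(G, 3, 0.5, seed = 77)
  sp <- split_population(G, G$variants$id[small_class], min_n = 100)
  expect_false(all(sp$analyzable))
  cond <- conditional_gwas(sim$phenotype, G, sp, thresholds = 2e-7)
  call <- classify_epistasis(cond, list(peak_id = G$variants$id[5]))
  expect_equal(call$pattern, "undeterminable")
})

test_that("additive traits rarely trigger one-subgroup-only calls (type-I control)", {
  # scaled-down replicate loop: a clearly detectable additive second locus
  G <- cached("typeI", simulate_panel(
    panel_config(n_accessions = 500, n_variants = 400, n_chromosomes = 4,
                 n_subpops = 2, seed = 61)))
  M <- G$dosages
  p2 <- colMeans(M == 2)
  bg <- which(p2 > 0.4 & p2 < 0.6)[1]
  cand <- which(G$variants$chrom == "chr3" & apply(M, 2, sd) > 0.5)
  add <- cand[which(ld_r2_vec(M, bg, cand) < 0.05)[1]]
  sp <- split_population(G, G$variants$id[bg], min_n = 100)
  gv_base <- 1.5 * M[, bg] + 1.2 * M[, add]
  n_one <- 0L; n_calls <- 0L
  for (s in 1:25) {
    e <- withr::with_seed(900 + s, rnorm(length(gv_base)))
    y <- gv_base + (e - mean(e)) / sd(e) * sqrt(var(gv_base) * 0.25 / 0.75)
    names(y) <- G$accessions
    cond <- conditional_gwas(y, G, sp, thresholds = 2e-7)
    hit <- which(sapply(seq_len(nrow(cond$sals)), function(i)
      G$variants$id[add] %in% cond$sals$members[[i]]))
    if (length(hit)) {
      n_calls <- n_calls + 1L
      cl <- classify_epistasis(cond, hit[1])
      if (cl$pattern == "one_subgroup_only") n_one <- n_one + 1L
    }
  }
  expect_gt(n_calls, 15)
  expect_lte(n_one / max(n_calls, 1), 0.05)
})

test_that("subgroup re-scans gain power for background-conditional effects", {
  fx <- cond_fixture()
  G <- fx$G
  bd <- size_conditional_effect(G, fx$bg, fx$dep, beta_bg = 2, h2 = 0.7,
                                share = 0.055)   # borderline effect
  sp <- split_population(G, G$variants$id[fx$bg], min_n = 100)
  carriers <- sp$groups$hom_alt
  det_full <- det_sub <- logical(20)
  for (s in 1:20) {
    sim <- simulate_epistatic_trait(G, fx$bg, fx$dep, 2, bd, h2 = 0.7,
                                    seed = 400 + s)
    scan <- gwas_scan(sim$phenotype, cache = fx$cache)
    det_full[s] <- scan$p[fx$dep] <= 2e-7
    Gs <- cached("cond_sub_alt", {
      Gsub <- subset_geno(G, accessions = carriers)
      Gsub <- filter_variants(Gsub, maf_min = 0.05, miss_max = 1.01)
      list(G = Gsub, cache = mlm_scan_cache(Gsub))
    })
    scs <- gwas_scan(sim$phenotype[carriers], cache = Gs$cache)
    j <- match(G$variants$id[fx$dep], scs$id)
    det_sub[s] <- !is.na(j) && scs$p[j] <= 2e-7
  }
  expect_gt(sum(det_sub), sum(det_full))
})

test_that("subgroups can derive their own permutation thresholds", {
  G <- cached("typeI", simulate_panel(
    panel_config(n_accessions = 500, n_variants = 400, n_chromosomes = 4,
                 n_subpops = 2, seed = 61)))
  M <- G$dosages
  bg <- which(colMeans(M == 2) > 0.4 & colMeans(M == 2) < 0.6)[1]
  sp <- split_population(G, G$variants$id[bg], min_n = 100)
  y <- withr::with_seed(5, rnorm(n_accessions(G)))
  names(y) <- G$accessions
  cond <- conditional_gwas(y, G, sp, thresholds = "permutation",
                           n_perm = 30, seed = 3)
  for (grp in names(sp$groups)[sp$analyzable]) {
    expect_true(is.numeric(cond$thresholds[[grp]]))
    expect_gt(cond$thresholds[[grp]], 0)
    expect_lt(cond$thresholds[[grp]], 0.05)
  }
})
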