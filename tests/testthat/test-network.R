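test_that("PmaxLD follows its definition on hand-checkable cases", {
  G <- small_panel()
  # single-member locus: only the self r2 contributes
  expect_equal(pmax_ld(G$variants$id[1], G), 1)
  # two members: per-SNP means are both (1 + r2) / 2
  ids <- G$variants$id[5:6]
  r2 <- ld_r2(G, ids[1], ids[2])$r2
  expect_equal(pmax_ld(ids, G), (1 + r2) / 2)
  # multi-member locus vs brute-force double loop
  ids4 <- G$variants$id[11:14]
  M <- G$dosages
  means <- sapply(11:14, function(i)
    mean(sapply(11:14, function(j)
      if (i == j) 1 else cor(M[, i], M[, j])^2)))
  expect_equal(pmax_ld(ids4, G), max(means), tolerance = 1e-12)
  expect_error(pmax_ld(character(0), G), "empty")
})

test_that("Inter-LD matches the brute-force oracle, is symmetric and collapses for single SNPs", {
  G <- small_panel()
  # single-SNP loci: Inter-LD equals the plain r2
  a <- G$variants$id[3]; b <- G$variants$id[250]
  e <- inter_ld(a, b, G)
  expect_equal(e$inter_ld, ld_r2(G, a, b)$r2, tolerance = 1e-12)
  expect_equal(e$pmax_a, 1)
  # multi-member loci against the independent double-loop implementation
  ma <- G$variants$id[21:23]; mb <- G$variants$id[41:42]
  e2 <- inter_ld(ma, mb, G)
  o <- brute_inter_ld(ma, mb, G)
  expect_equal(e2$inter_ld, o$inter_ld, tolerance = 1e-12)
  expect_equal(e2$cross_ld, o$cross_ld, tolerance = 1e-12)
  # symmetry and the component identity
  e3 <- inter_ld(mb, ma, G)
  expect_equal(e2$inter_ld, e3$inter_ld, tolerance = 1e-12)
  expect_equal(e2$inter_ld,
               0.5 * (e2$cross_ld / e2$pmax_a + e2$cross_ld / e2$pmax_b),
               tolerance = 1e-12)
  # self Inter-LD never exceeds 1
  expect_lte(inter_ld(ma, ma, G)$inter_ld, 1 + 1e-12)
})

make_sal_table <- function(G, specs) {
  # specs: list of list(trait, idx (member indices), peak_i)
  rows <- lapply(specs, function(s) {
    data.frame(trait = s$trait, tier = "primary", context = "full_population",
               chrom = G$variants$chrom[s$idx[1]],
               start = min(G$variants$pos[s$idx]),
               end = max(G$variants$pos[s$idx]),
               peak_id = G$variants$id[s$peak], min_p = s$p,
               n_members = length(s$idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(specs, function(s) G$variants$id[s$idx])
  class(out) <- c("sal_table", "data.frame")
  out
}

network_fixture <- function() cached("net", {
  G <- simulate_panel(panel_config(n_accessions = 300, n_variants = 300,
                                   n_chromosomes = 3, ld_block_length = 10,
                                   seed = 303))
  # two traits sharing one locus (pleiotropy), plus two trait-specific loci
  sals <- make_sal_table(G, list(
    list(trait = "PH",  idx = 11:13, peak = 12, p = 1e-10),
    list(trait = "BBD", idx = 12:14, peak = 13, p = 1e-9),
    list(trait = "PH",  idx = 151:152, peak = 151, p = 1e-8),
    list(trait = "R32", idx = 251:253, peak = 252, p = 1e-8)))
  list(G = G, sals = sals)
})

test_that("overlapping SALs from different traits merge into one pleiotropic node", {
  fx <- network_fixture()
  net <- build_network(fx$sals, fx$G, edge_min = 0.4)
  types <- igraph::V(net)$type
  expect_equal(sum(types == "trait"), 3)
  expect_equal(sum(types == "sal"), 3)      # 4 SALs, 2 merged
  merged <- which(types == "sal" &
                    igraph::degree(net, mode = "all") >= 2)
  deg_traits <- sapply(igraph::V(net)[types == "sal"], function(v) {
    nb <- igraph::neighbors(net, v)
    sum(nb$type == "trait")
  })
  expect_equal(sort(unname(deg_traits)), c(1, 1, 2))
  kn <- key_nodes(net, min_traits = 2)
  expect_equal(nrow(kn), 1)
  expect_equal(kn$n_traits, 2)
  expect_true(grepl("SAL:", kn$node))
  # effective score of the merged node is the lowest constituent P
  vsc <- igraph::V(net)$score[types == "sal"]
  expect_true(1e-10 %in% vsc)
})

test_that("edge filtering is monotone and low-LD networks are trait-SAL stars", {
  fx <- network_fixture()
  n_edges <- function(em) igraph::ecount(build_network(fx$sals, fx$G,
                                                       edge_min = em))
  expect_gte(n_edges(0.2), n_edges(0.4))
  expect_gte(n_edges(0.4), n_edges(0.9))
  # with an impossibly high cutoff only membership edges remain
  net <- build_network(fx$sals, fx$G, edge_min = 1.01)
  expect_true(all(igraph::E(net)$kind == "membership"))
  expect_equal(nrow(key_nodes(net, min_traits = 2)), 1)  # merged node remains
})

test_that("network construction is invariant to SAL input order", {
  fx <- network_fixture()
  net1 <- build_network(fx$sals, fx$G)
  shuf <- fx$sals[c(3, 1, 4, 2), ]
  class(shuf) <- class(fx$sals)
  net2 <- build_network(shuf, fx$G)
  expect_setequal(igraph::V(net1)$name, igraph::V(net2)$name)
  e1 <- apply(igraph::as_edgelist(net1), 1, function(r)
    paste(sort(r), collapse = "~"))
  e2 <- apply(igraph::as_edgelist(net2), 1, function(r)
    paste(sort(r), collapse = "~"))
  expect_setequal(e1, e2)
})

test_that("key-node ranking is stable under trait relabelling", {
  fx <- network_fixture()
  net <- build_network(fx$sals, fx$G)
  relab <- fx$sals
  relab$trait <- c("X", "Y", "X", "Z")[match(relab$trait,
                                             c("PH", "BBD", "PH", "R32"))]
  relab$trait <- ifelse(fx$sals$trait == "PH", "X",
                        ifelse(fx$sals$trait == "BBD", "Y", "Z"))
  class(relab) <- class(fx$sals)
  net2 <- build_network(relab, fx$G)
  kn1 <- key_nodes(net, 2); kn2 <- key_nodes(net2, 2)
  expect_equal(kn1$node, kn2$node)
  expect_equal(kn1$n_traits, kn2$n_traits)
})

test_that("network exports produce readable GraphML, SIF and edge tables", {
  fx <- network_fixture()
  net <- build_network(fx$sals, fx$G)
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".sif")
  tsv <- tempfile(fileext = ".tsv")
  write_network_graphml(net, gml)
  write_network_sif(net, sif)
  write_network_edges_tsv(net, tsv)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_equal(length(readLines(sif)), igraph::ecount(net))
  expect_equal(nrow(read.delim(tsv)), igraph::ecount(net))
})

test_that("stacking curves rise with favourable-allele count for additive traits", {
  G <- cached("stackpanel", simulate_panel(
    panel_config(n_accessions = 800, n_variants = 400, n_chromosomes = 4,
                 seed = 88)))
  sim <- simulate_additive_trait(G, 8, 0.6, effect_model = "equal",
                                 seed = 123)
  loci <- data.frame(id = sim$truth$causal_ids,
                     favorable = ifelse(sim$truth$effects > 0, "alt", "ref"))
  st <- allele_stacking(G, loci, sim$phenotype)
  expect_lt(st$slope_p, 0.01)
  expect_gt(st$slope, 0)
  expect_equal(sum(st$curve$n), n_accessions(G))
  # mean trait value increases along most of the curve
  expect_gt(cor(st$curve$k, st$curve$mean), 0.8)
})

test_that("randomised favourable labels weaken the stacking slope", {
  G <- cached("stackpanel", simulate_panel(
    panel_config(n_accessions = 800, n_variants = 400, n_chromosomes = 4,
                 seed = 88)))
  wins <- 0L
  for (s in 1:20) {
    sim <- simulate_additive_trait(G, 8, 0.6, effect_model = "equal",
                                   seed = 600 + s)
    loci_true <- data.frame(
      id = sim$truth$causal_ids,
      favorable = ifelse(sim$truth$effects > 0, "alt", "ref"))
    fav <- withr::with_seed(s, sample(c("alt", "ref"), 8, replace = TRUE))
    loci_rand <- data.frame(id = sim$truth$causal_ids, favorable = fav)
    s_true <- allele_stacking(G, loci_true, sim$phenotype)$slope
    s_rand <- allele_stacking(G, loci_rand, sim$phenotype)$slope
    if (s_true > abs(s_rand)) wins <- wins + 1L
  }
  expect_gte(wins, 16)   # paired: the true orientation dominates
})

test_that("a single stacked locus reproduces its genotype-class means", {
  G <- small_panel()
  v <- which(apply(G$dosages, 2, sd) > 0.5)[1]
  y <- setNames(rnorm(n_accessions(G)) + G$dosages[, v], G$accessions)
  st <- allele_stacking(G, data.frame(id = G$variants$id[v],
                                      favorable = "alt"), y)
  hom_alt <- G$dosages[, v] == 2
  expect_equal(st$curve$mean[st$curve$k == 1], mean(y[hom_alt]))
  expect_equal(st$curve$mean[st$curve$k == 0], mean(y[!hom_alt]))
  expect_error(allele_stacking(G, data.frame(id = character(),
                                             favorable = character()), y),
               "empty")
})
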