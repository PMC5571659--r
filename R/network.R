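#' PmaxLD: the largest attainable within-locus mean LD
#'
#' For each member SNP of a SAL, compute the mean `r2` of that SNP to all
#' member SNPs (self included, so a single-member SAL has PmaxLD 1); PmaxLD
#' is the maximum of these per-SNP means. It normalises between-locus LD in
#' the Inter-LD statistic.
#'
#' @param members member variant ids (or a one-row `sal_table`).
#' @param G the [geno_matrix].
#' @param include_self include the self `r2` (= 1) in each per-SNP mean
#'   (default `TRUE`).
#' @return PmaxLD in (0, 1].
#' @export
pmax_ld <- function(members, G, include_self = TRUE) {
  if (inherits(members, "data.frame")) members <- members$members[[1]]
  if (!length(members)) stop_bad_arg("empty member list")
  idx <- vapply(members, function(v) variant_index(G, v), 0L)
  R <- sal_r2_matrix(G, idx, idx)
  diag(R) <- 1
  if (anyNA(R)) stop_bad_arg("undefined r2 among SAL members")
  if (include_self) max(rowMeans(R))
  else if (length(idx) == 1) 1
  else max((rowSums(R) - 1) / (length(idx) - 1))
}

sal_r2_matrix <- function(G, ia, ib) {
  R <- matrix(NA_real_, length(ia), length(ib))
  for (j in seq_along(ib)) R[, j] <- ld_r2_vec(G$dosages, ib[j], ia)
  R
}

#' Inter-LD between two SALs
#'
#' The normalised between-locus LD statistic
#' `Inter-LD = 1/2 * (LD(S1, S2) / PmaxLD(S1) + LD(S1, S2) / PmaxLD(S2))`,
#' where `LD(S1, S2)` is the mean pairwise `r2` between all member SNPs of
#' the first locus and all member SNPs of the second, and PmaxLD is
#' [pmax_ld()]. Symmetric in its arguments; for two single-SNP loci it
#' collapses to their plain `r2`.
#'
#' @param a,b one-row `sal_table`s (or member-id vectors).
#' @param G the [geno_matrix].
#' @return a list of class `inter_ld_edge`: `cross_ld`, `pmax_a`, `pmax_b`,
#'   `inter_ld`.
#' @export
inter_ld <- function(a, b, G) {
  ma <- if (inherits(a, "data.frame")) a$members[[1]] else a
  mb <- if (inherits(b, "data.frame")) b$members[[1]] else b
  if (!length(ma) || !length(mb)) stop_bad_arg("empty member list")
  ia <- vapply(ma, function(v) variant_index(G, v), 0L)
  ib <- vapply(mb, function(v) variant_index(G, v), 0L)
  R <- sal_r2_matrix(G, ia, ib)
  if (anyNA(R)) {
    bad <- unique(c(ma[rowSums(is.na(R)) > 0][1], mb[colSums(is.na(R)) > 0][1]))
    stop_bad_arg("undefined r2 involving variant(s): ",
                 paste(stats::na.omit(bad), collapse = ", "))
  }
  cross <- mean(R)
  pa <- pmax_ld(ma, G); pb <- pmax_ld(mb, G)
  structure(list(cross_ld = cross, pmax_a = pa, pmax_b = pb,
                 inter_ld = 0.5 * (cross / pa + cross / pb)),
            class = "inter_ld_edge")
}

#' Build the trait-locus association network
#'
#' Nodes are traits and SALs; SALs from different traits that satisfy
#' [sal_overlap()] are merged into a single locus node (members: union of
#' the member sets) before edges are drawn. Each locus node carries a
#' membership edge to every trait it was detected for and an effective
#' score, the lowest P value among its constituent SALs. Locus-locus edges
#' carry the [inter_ld()] statistic and are kept iff it reaches `edge_min`
#' (set `edge_stat = "cross_ld"` to gate on the raw mean cross-`r2`
#' instead).
#'
#' @param sals a `sal_table` pooled across traits.
#' @param G the [geno_matrix].
#' @param edge_min minimum edge statistic (default 0.4).
#' @param edge_stat `"inter_ld"` (default) or `"cross_ld"`.
#' @param overlap_ld peak-LD cutoff used when merging overlapping SALs.
#' @return an \pkg{igraph} graph of class `trait_network`; vertex
#'   attributes `type` (`"trait"`/`"sal"`), `score`, `members`
#'   (comma-separated ids for locus nodes); edge attributes `kind`
#'   (`"membership"`/`"interld"`), `weight` (Inter-LD for locus-locus
#'   edges).
#' @export
build_network <- function(sals, G, edge_min = 0.4,
                          edge_stat = c("inter_ld", "cross_ld"),
                          overlap_ld = 0.6) {
  edge_stat <- match.arg(edge_stat)
  stopifnot(inherits(sals, "data.frame"))
  ns <- nrow(sals)
  if (!ns) stop_bad_arg("no SALs to build a network from")
  # merge overlapping SALs into locus nodes via connected components
  adj <- matrix(FALSE, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) if (j > i)
    adj[i, j] <- adj[j, i] <- sal_overlap(sal_row(sals, i), sal_row(sals, j),
                                          G, ld_min = overlap_ld)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  nodes <- lapply(unique(comp), function(cid) {
    rows <- which(comp == cid)
    best <- rows[which.min(sals$min_p[rows])]
    list(id = paste0("SAL:", sals$chrom[best], ":", sals$peak_id[[best]]),
         members = sort(unique(unlist(sals$members[rows]))),
         traits = unique(unlist(sals$trait[rows])),
         score = min(sals$min_p[rows]))
  })
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids))          # distinct loci sharing a peak label
    ids <- make.unique(ids, sep = "#")
  traits <- unique(unlist(lapply(nodes, `[[`, "traits")))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(traits), name = traits, type = "trait",
                            score = NA_real_, members = "")
  g <- igraph::add_vertices(
    g, length(nodes), name = ids, type = "sal",
    score = vapply(nodes, `[[`, 0, "score"),
    members = vapply(nodes, function(n) paste(n$members, collapse = ","), ""))
  for (k in seq_along(nodes))
    for (tr in nodes[[k]]$traits)
      g <- igraph::add_edges(g, c(tr, ids[k]), kind = "membership",
                             weight = NA_real_)
  if (length(nodes) > 1) {
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) if (j > i) {
      e <- inter_ld(nodes[[i]]$members, nodes[[j]]$members, G)
      w <- if (edge_stat == "inter_ld") e$inter_ld else e$cross_ld
      if (w >= edge_min)
        g <- igraph::add_edges(g, c(ids[i], ids[j]), kind = "interld",
                               weight = w)
    }
  }
  class(g) <- c("trait_network", class(g))
  g
}

#' Pleiotropic key nodes of a trait network
#'
#' Locus nodes reachable from at least `min_traits` distinct traits through
#' their own edges: direct trait-membership edges plus the membership edges
#' of locus neighbours one Inter-LD hop away. Ranked by trait count, then by
#' effective score (lower P first).
#'
#' @param net a [build_network()] result.
#' @param min_traits minimum distinct traits (default 2).
#' @return data.frame: `node`, `n_traits`, `traits` (comma-separated),
#'   `score`, ordered best first.
#' @export
key_nodes <- function(net, min_traits = 2) {
  vt <- igraph::V(net)$type
  sal_v <- which(vt == "sal")
  rows <- lapply(sal_v, function(v) {
    nb <- igraph::neighbors(net, v)
    direct <- nb[nb$type == "trait"]$name
    via <- unlist(lapply(nb[nb$type == "sal"], function(s) {
      nb2 <- igraph::neighbors(net, s)
      nb2[nb2$type == "trait"]$name
    }))
    traits <- unique(c(direct, via))
    data.frame(node = igraph::V(net)$name[v], n_traits = length(traits),
               traits = paste(sort(traits), collapse = ","),
               score = igraph::V(net)$score[v], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_traits >= min_traits, , drop = FALSE]
  out <- out[order(-out$n_traits, out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Favourable-allele stacking curve
#'
#' Counts, per accession, the loci homozygous for the favourable allele and
#' summarises the trait by that count: the classic accumulation curve in
#' which (for an additive architecture) the mean trait value rises with the
#' number of stacked favourable alleles. Accessions with a missing call at
#' any stacked locus are excluded. A least-squares trend of the
#' per-accession trait on the count is reported.
#'
#' @param G a [geno_matrix].
#' @param loci data.frame with columns `id` and `favorable` (`"ref"` or
#'   `"alt"`), one row per stacked locus.
#' @param y named trait vector over accessions.
#' @param dosage_mode count favourable allele dosage 0-2 instead of
#'   homozygous 0/1 per locus (default `FALSE`).
#' @return a list of class `stacking_curve`: `curve` (data.frame `k`, `n`,
#'   `mean`, `sd`), `slope`, `slope_se`, `slope_p`, `counts` (per
#'   accession).
#' @export
allele_stacking <- function(G, loci, y, dosage_mode = FALSE) {
  if (!nrow(loci)) stop_bad_arg("empty loci list")
  idx <- vapply(loci$id, function(v) variant_index(G, v), 0L)
  M <- G$dosages[, idx, drop = FALSE]
  fav_alt <- loci$favorable == "alt"
  fav <- if (dosage_mode) {
    sweep(M, 2, ifelse(fav_alt, 0, 2), function(g, r) abs(g - r)) / 1
  } else {
    t(t(M) == ifelse(fav_alt, 2, 0)) * 1
  }
  keep <- !apply(is.na(M), 1, any)
  if (is.null(names(y))) names(y) <- G$accessions
  y <- y[G$accessions]
  counts <- rowSums(fav[keep, , drop = FALSE])
  yy <- y[keep]
  curve <- data.frame(k = sort(unique(counts)))
  curve$n <- as.integer(table(counts)[as.character(curve$k)])
  curve$mean <- vapply(curve$k, function(k) mean(yy[counts == k]), 0)
  curve$sd <- vapply(curve$k, function(k) sd(yy[counts == k]), 0)
  fit <- summary(lm(yy ~ counts))
  structure(list(curve = curve,
                 slope = fit$coefficients["counts", "Estimate"],
                 slope_se = fit$coefficients["counts", "Std. Error"],
                 slope_p = fit$coefficients["counts", "Pr(>|t|)"],
                 counts = setNames(counts, G$accessions[keep])),
            class = "stacking_curve")
}

#' Export a trait network
#'
#' GraphML via \pkg{igraph}; SIF plus an edge-attribute TSV for standard
#' graph viewers.
#'
#' @param net a [build_network()] result.
#' @param path output file (`.graphml`, `.sif`, or edge TSV).
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- net
  class(g) <- setdiff(class(g), "trait_network")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(net, path) {
  el <- igraph::as_edgelist(net)
  kind <- igraph::E(net)$kind
  writeLines(paste(el[, 1], kind, el[, 2], sep = "\t"), path)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edges_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net)
  out <- data.frame(from = el[, 1], to = el[, 2],
                    kind = igraph::E(net)$kind,
                    inter_ld = igraph::E(net)$weight)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
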