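#' Detect significantly associated loci (SALs)
#'
#' Groups variants passing the significance threshold into peak-anchored
#' LD-contiguous intervals. Greedy procedure: take the unassigned significant
#' variant with the lowest P value as a peak (ties broken by leftmost
#' position), extend the interval left and right over consecutive panel
#' variants on the same chromosome while `r2` with the peak stays at or above
#' `ld_min` (a neighbour with undefined LD stops the extension), absorb every
#' significant variant falling inside the interval, and repeat until no
#' significant variant remains unassigned. Every significant variant is
#' assigned to exactly one SAL.
#'
#' @param scan an `assoc_scan` (same variant order as `G`).
#' @param threshold a `perm_threshold` or a fixed P-value cutoff
#'   (significance means `p <= threshold`).
#' @param G the [geno_matrix] scanned.
#' @param ld_min LD contiguity cutoff (default 0.6).
#' @param mode `"peak"` (r2 measured against the peak, the default) or
#'   `"chain"` (r2 measured against the previous variant outward).
#' @param tier `"primary"` or `"secondary"` label stored on the loci.
#' @return a data.frame of class `sal_table`: one row per SAL with columns
#'   `trait`, `tier`, `context`, `chrom`, `start`, `end`, `peak_id`,
#'   `min_p`, `n_members` and a list-column `members` of member variant ids
#'   (consecutive in panel order).
#' @export
detect_sals <- function(scan, threshold, G, ld_min = 0.6,
                        mode = c("peak", "chain"), tier = "primary") {
  mode <- match.arg(mode)
  thr <- threshold_value(threshold)
  if (nrow(scan) != n_variants(G) || !setequal(scan$id, G$variants$id))
    stop_bad_arg("scan and genotype matrix must cover the same variants")
  if (!all(scan$id == G$variants$id)) {  # accept any record order
    at <- attributes(scan)
    scan <- scan[match(G$variants$id, scan$id), , drop = FALSE]
    attr(scan, "trait") <- at$trait
    attr(scan, "context") <- at$context
  }
  M <- G$dosages
  sig <- which(scan$tested & !is.na(scan$p) & scan$p <= thr)
  sals <- list()
  unassigned <- sig
  chrom <- G$variants$chrom
  while (length(unassigned)) {
    o <- order(scan$p[unassigned], chrom[unassigned], scan$pos[unassigned])
    peak <- unassigned[o[1]]
    lo <- hi <- peak
    anchor <- peak
    while (lo > 1 && chrom[lo - 1] == chrom[peak]) {
      r2 <- ld_r2_vec(M, if (mode == "peak") peak else anchor, lo - 1)
      if (is.na(r2) || r2 < ld_min) break
      lo <- lo - 1; if (mode == "chain") anchor <- lo
    }
    anchor <- peak
    while (hi < nrow(scan) && chrom[hi + 1] == chrom[peak]) {
      r2 <- ld_r2_vec(M, if (mode == "peak") peak else anchor, hi + 1)
      if (is.na(r2) || r2 < ld_min) break
      hi <- hi + 1; if (mode == "chain") anchor <- hi
    }
    members <- lo:hi
    sals[[length(sals) + 1]] <- list(peak = peak, members = members)
    unassigned <- setdiff(unassigned, members)
  }
  out <- data.frame(
    trait = rep(attr(scan, "trait") %||% "trait", length(sals)),
    tier = rep(tier, length(sals)),
    context = rep(attr(scan, "context") %||% "full_population",
                  length(sals)),
    chrom = vapply(sals, function(s) chrom[s$peak], ""),
    start = vapply(sals, function(s) min(G$variants$pos[s$members]), 0),
    end = vapply(sals, function(s) max(G$variants$pos[s$members]), 0),
    peak_id = vapply(sals, function(s) G$variants$id[s$peak], ""),
    min_p = vapply(sals, function(s) scan$p[s$peak], 0),
    n_members = vapply(sals, function(s) length(s$members), 0L),
    stringsAsFactors = FALSE)
  out$members <- lapply(sals, function(s) G$variants$id[s$members])
  if (nrow(out)) out <- out[order(out$min_p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sal_table", "data.frame")
  out
}

#' Do two SALs represent the same signal?
#'
#' `TRUE` iff the two intervals intersect positionally on the same
#' chromosome, or the peak-to-peak dosage `r2` is at or above `ld_min`.
#'
#' @param a,b single rows of a `sal_table` (or equivalent lists with
#'   `chrom`, `start`, `end`, `peak_id`).
#' @param G the [geno_matrix].
#' @param ld_min peak-LD cutoff (default 0.6).
#' @return logical.
#' @export
sal_overlap <- function(a, b, G, ld_min = 0.6) {
  pos_hit <- identical(as.character(a$chrom), as.character(b$chrom)) &&
    a$start <= b$end && b$start <= a$end
  if (pos_hit) return(TRUE)
  ia <- variant_index(G, unlist(a$peak_id))
  ib <- variant_index(G, unlist(b$peak_id))
  r2 <- ld_r2_vec(G$dosages, ia, ib)
  !is.na(r2) && r2 >= ld_min
}

sal_row <- function(sals, i) {
  r <- sals[i, , drop = FALSE]
  list(trait = r$trait, tier = r$tier, chrom = r$chrom, start = r$start,
       end = r$end, peak_id = r$peak_id[[1]], min_p = r$min_p,
       members = r$members[[1]])
}

#' Export SALs as TSV or BED
#'
#' The TSV keeps 1-based inclusive coordinates; the BED export converts to
#' 0-based half-open.
#'
#' @param sals a `sal_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sals_tsv <- function(sals, path) {
  flat <- sals
  flat$members <- vapply(sals$members, paste, "", collapse = ",")
  data.table::fwrite(flat, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_sals_tsv
#' @export
write_sals_bed <- function(sals, path) {
  bed <- data.frame(chrom = sals$chrom, start = sals$start - 1,
                    end = sals$end,
                    name = paste(sals$trait, sals$peak_id, sep = "|"),
                    score = pmin(1000, round(-10 * log10(sals$min_p))),
                    strand = ".")
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
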