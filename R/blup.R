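#' Read / write long-format phenotype tables
#'
#' Columns: `accession`, `environment` (year-location label), `replicate`,
#' `trait`, `value`. The (accession, environment, replicate, trait) key must
#' be unique.
#'
#' @param path file path.
#' @return `read_phenotypes()` a `pheno_table` data.frame;
#'   `write_phenotypes()` the path, invisibly.
#' @export
read_phenotypes <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = c("NA", "")))
  need <- c("accession", "environment", "replicate", "trait", "value")
  if (!all(need %in% names(dt)))
    stop_bad_arg("phenotype TSV needs columns: ", paste(need, collapse = ", "))
  as_pheno_table(dt[need])
}

#' @rdname read_phenotypes
#' @param tbl a `pheno_table`.
#' @export
write_phenotypes <- function(tbl, path) {
  data.table::fwrite(tbl, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname read_phenotypes
#' @param df a data.frame with the five phenotype columns.
#' @export
as_pheno_table <- function(df) {
  key <- do.call(paste, c(df[c("accession", "environment", "replicate",
                               "trait")], sep = "\r"))
  if (anyDuplicated(key))
    stop_bad_arg("duplicate (accession, environment, replicate, trait) keys")
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Cross-environment BLUP of line performance
#'
#' Fits, for one trait, the mixed model
#' `value = mean + environment (fixed) + line + line:environment + residual`
#' with the two random components estimated by EM-REML on Henderson's
#' mixed-model equations, and returns the best linear unbiased predictions
#' of the line effects at the converged variance components. With a single
#' environment the line-by-environment component is fixed at zero.
#'
#' @param tbl a `pheno_table`.
#' @param trait trait id to fit.
#' @param average_replicates average replicate records to plot means before
#'   fitting (default `FALSE`: replicates feed the residual term).
#' @param tol relative convergence tolerance on the variance components
#'   (default 1e-6).
#' @param max_iter maximum EM iterations (default 500); non-convergence is
#'   flagged in the result and the last iterate returned.
#' @return a list of class `blup_result`: `blup` (named vector of line
#'   predictions, centred at zero), `varcomp` (`var_line`, `var_gxe`,
#'   `var_resid`), `fixef` (mean and environment effects), `converged`,
#'   `n_iter`, `n_obs`.
#' @export
fit_multienv_blup <- function(tbl, trait, average_replicates = FALSE,
                              tol = 1e-6, max_iter = 500) {
  d <- tbl[tbl$trait == trait & !is.na(tbl$value), , drop = FALSE]
  if (!nrow(d)) stop_bad_arg("no records for trait ", trait)
  if (!is.numeric(d$value)) stop_bad_arg("trait ", trait, " is not numeric")
  if (length(unique(d$accession)) < 2) stop_bad_arg("need >= 2 accessions")
  if (average_replicates) {
    d <- aggregate(value ~ accession + environment, d, mean)
    d$trait <- trait
  }
  env <- factor(d$environment)
  line <- factor(d$accession)
  y <- d$value
  n <- length(y)
  X <- if (nlevels(env) > 1) model.matrix(~env) else
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Z1 <- model.matrix(~line - 1)
  use_gxe <- nlevels(env) > 1
  Z2 <- if (use_gxe) model.matrix(~line:env - 1) else NULL
  # drop empty line:env cells
  if (use_gxe) Z2 <- Z2[, colSums(Z2) > 0, drop = FALSE]
  q1 <- ncol(Z1); q2 <- if (use_gxe) ncol(Z2) else 0L
  Z <- if (use_gxe) cbind(Z1, Z2) else Z1
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y)
  p <- qr(X)$rank
  # start from the environment-adjusted variance so that the EM path (and
  # hence the converged fit) is invariant to per-environment shifts
  vy <- var(qr.resid(qr(X), y)) + 1e-12
  s1 <- vy / 3; s2 <- if (use_gxe) vy / 3 else 0; se <- vy / 3
  floor_v <- vy * 1e-10
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lam <- c(rep(se / max(s1, floor_v), q1),
             if (use_gxe) rep(se / max(s2, floor_v), q2))
    C <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), ZtZ + diag(lam, length(lam))))
    rhs <- rbind(Xty, Zty)
    Cinv <- solve(C)
    sol <- Cinv %*% rhs
    beta <- sol[seq_len(ncol(X))]
    u <- sol[-seq_len(ncol(X))]
    u1 <- u[seq_len(q1)]
    u2 <- if (use_gxe) u[q1 + seq_len(q2)] else numeric(0)
    dg <- diag(Cinv)[-seq_len(ncol(X))]
    s1_new <- (sum(u1^2) + se * sum(dg[seq_len(q1)])) / q1
    s2_new <- if (use_gxe)
      (sum(u2^2) + se * sum(dg[q1 + seq_len(q2)])) / q2 else 0
    resid <- y - X %*% beta - Z %*% u
    se_new <- sum(y * resid) / (n - p)
    se_new <- max(se_new, floor_v)
    delta <- max(abs(c(s1_new - s1, s2_new - s2, se_new - se))) /
      max(vy, 1e-12)
    s1 <- max(s1_new, 0); s2 <- max(s2_new, 0); se <- se_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  blup <- setNames(as.vector(u1), levels(line))
  fe <- setNames(as.vector(beta), colnames(X))
  structure(list(blup = blup,
                 varcomp = c(var_line = s1,
                             var_gxe = if (use_gxe) s2 else 0,
                             var_resid = se),
                 fixef = fe, converged = converged, n_iter = iter,
                 n_obs = table(line)),
            class = "blup_result")
}

#' @export
print.blup_result <- function(x, ...) {
  cat("blup_result:", length(x$blup), "lines;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "EM iterations\n")
  print(round(x$varcomp, 6))
  invisible(x)
}

#' Write BLUP results as TSV
#'
#' One row per line: `accession`, `trait`, `blup`, `n_obs`.
#'
#' @param fit a [fit_multienv_blup()] result.
#' @param trait trait label for the output.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_blup_tsv <- function(fit, trait, path) {
  out <- data.frame(accession = names(fit$blup), trait = trait,
                    blup = unname(fit$blup),
                    n_obs = as.integer(fit$n_obs[names(fit$blup)]))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
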