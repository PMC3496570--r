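# Shared per-SNP association engine for the GLS (whitened) and OLS scans.
# The whitened system reproduces the GLS normal equations; with a NULL
# whitener the engine is ordinary least squares.

# numeric chromosome ordering with X after the autosomes
chromosome_order <- function(chr) {
  x <- suppressWarnings(as.numeric(chr))
  x[is.na(x) & chr %in% c("X", "x")] <- 1e6
  x[is.na(x)] <- 2e6
  x
}

# deterministic p-value ranking, ties broken by (chromosome, position)
assoc_rank <- function(p, chr, pos) {
  ord <- order(p, chromosome_order(chr), pos, na.last = TRUE)
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  rk[is.na(p)] <- NA_integer_
  rk
}

.solve_wls <- function(xs, ys) {
  xtx <- crossprod(xs)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- drop(backsolve(ch, forwardsolve(t(ch), crossprod(xs, ys))))
  resid <- ys - drop(xs %*% beta)
  k <- ncol(xs)
  n <- length(ys)
  if (n - k < 1) return(NULL)
  list(beta = beta, cov_unscaled = chol2inv(ch),
       s2 = sum(resid^2) / (n - k), k = k, df = n - k)
}

.contrast_row <- function(sol, s) {
  est <- sum(s * sol$beta[seq_along(s)])
  v <- sol$s2 * drop(t(s) %*% sol$cov_unscaled[seq_along(s), seq_along(s)] %*% s)
  if (v <= 0) return(c(est = est, se = 0, t = 0, p = 1))
  se <- sqrt(v)
  tt <- est / se
  c(est = est, se = se, t = tt, p = 2 * stats::pt(-abs(tt), sol$df))
}

assoc_scan_core <- function(g, y, ids, x_extra = NULL, families = NULL,
                            vc = NULL, coding = c("classes", "additive"),
                            contrasts = default_contrasts) {
  coding <- match.arg(coding)
  n <- length(ids)
  d_all <- dosage(g)[ids, , drop = FALSE]
  use_w <- !is.null(vc)
  if (use_w) {
    blocks <- family_index_blocks(families, ids)
    w <- whitener_from_blocks(blocks, vc$sigma_f2, vc$sigma_e2)
  } else w <- NULL
  wh <- function(wht, x) if (is.null(wht)) x else whiten(wht, x)
  ys_full <- wh(w, y)
  ones_full <- wh(w, rep(1, n))
  xe_full <- if (is.null(x_extra)) NULL else wh(w, as.matrix(x_extra))

  m <- n_snps(g)
  res <- matrix(NA_real_, m, 11,
                dimnames = list(NULL, c("n_used", "freq1",
                                        "est_additive", "se_additive",
                                        "t_additive", "p_additive",
                                        "est_dominance", "t_dominance",
                                        "p_dominance", "p", "df")))
  for (j in seq_len(m)) {
    d <- d_all[, j]
    ok <- !is.na(d)
    if (!any(ok)) next
    if (all(ok)) {
      dj <- d; ysj <- ys_full; onesj <- ones_full; xej <- xe_full; wj <- w
    } else {
      idsj <- ids[ok]
      dj <- d[ok]
      wj <- if (use_w)
        whitener_from_blocks(family_index_blocks(families, idsj),
                             vc$sigma_f2, vc$sigma_e2) else NULL
      ysj <- wh(wj, y[ok])
      onesj <- wh(wj, rep(1, length(idsj)))
      xej <- if (is.null(x_extra)) NULL
             else wh(wj, as.matrix(x_extra)[ok, , drop = FALSE])
    }
    nuse <- sum(ok)
    fr <- sum(dj) / (2 * nuse)
    res[j, "n_used"] <- nuse
    res[j, "freq1"] <- fr
    ud <- sort(unique(dj), decreasing = TRUE)
    if (length(ud) < 2) next  # monomorphic in the tested sample: untestable

    if (coding == "classes") {
      xc <- vapply(ud, function(l) as.numeric(dj == l), numeric(length(dj)))
      xcs <- wh(wj, xc)
      sol <- .solve_wls(cbind(xcs, xej), ysj)
      if (is.null(sol)) next
      cons <- contrasts(ud)
      ps <- c()
      for (nm in names(cons)) {
        cr <- .contrast_row(sol, cons[[nm]])
        if (nm == "additive") {
          res[j, c("est_additive", "se_additive",
                   "t_additive", "p_additive")] <- cr
        } else if (nm == "dominance") {
          res[j, c("est_dominance", "t_dominance", "p_dominance")] <-
            cr[c("est", "t", "p")]
        }
        ps <- c(ps, cr["p"])
      }
      if (length(ps)) res[j, "p"] <- min(ps)
      res[j, "df"] <- sol$df
    } else {
      djs <- wh(wj, dj)
      sol <- .solve_wls(cbind(onesj, djs, xej), ysj)
      if (is.null(sol)) next
      cr <- .contrast_row(sol, c(0, 1))
      res[j, c("est_additive", "se_additive",
               "t_additive", "p_additive")] <- cr
      res[j, "p"] <- cr["p"]
      res[j, "df"] <- sol$df
    }
  }
  out <- data.frame(snp_id = g$snp_ids, chromosome = g$chromosome,
                    position = g$position,
                    allele1 = g$alleles[, 1], allele2 = g$alleles[, 2],
                    res, stringsAsFactors = FALSE, row.names = NULL)
  out$rank <- assoc_rank(out$p, out$chromosome, out$position)
  out
}

# family-contiguous individual ordering restricted to ids present in both
# the genotype matrix and the phenotype table
scan_ids <- function(g, phenotypes, families = NULL) {
  present <- intersect(g$individual_ids, phenotypes$id)
  if (length(present) == 0)
    stop("no individuals shared between genotypes and phenotypes")
  if (is.null(families)) return(present)
  ids <- unlist(families$family_blocks, use.names = FALSE)
  ids[ids %in% present]
}

align_covariates <- function(covariates, ids) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "pca_basis")) covariates <- covariates$vectors
  covariates <- as.matrix(covariates)
  if (!is.null(rownames(covariates))) {
    if (!all(ids %in% rownames(covariates)))
      stop("covariate rows missing for some individuals")
    covariates <- covariates[ids, , drop = FALSE]
  } else if (nrow(covariates) != length(ids)) {
    stop("covariate matrix not aligned with individuals")
  }
  covariates
}

#' Half-sib GLS association scan
#'
#' For one trait: estimates the intraclass variance components once under
#' the null model (no SNP; intercept + covariates), builds the O(n)
#' whitening factor, then tests every SNP. With the default 3-genotype-
#' class coding the additive contrast (1, 0, -1) and the dominance
#' contrast (-1, 2, -1)/2 are tested and the per-SNP summary p-value is
#' their minimum (both are retained); \code{coding = "additive"} regresses
#' on the 0/1/2 dosage instead and tests the slope. Individuals with a
#' missing call at a SNP are excluded from that SNP's test (the whitener
#' is rebuilt for the reduced family sizes, reusing the null variance
#' components). Monomorphic SNPs are flagged untestable (p = NA).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param phenotypes data.frame with column \code{id} and one column per
#'   trait.
#' @param trait trait (column) name to scan.
#' @param families a \code{\link{family_structure}}.
#' @param covariates optional covariate matrix (rows named by id) or a
#'   \code{\link{compute_pcs}} result — the GLS-PCA variant.
#' @param vc optional precomputed \code{\link{estimate_vc_ml}} result.
#' @param reml use REML for the variance components (default ML).
#' @param coding "classes" (default) or "additive".
#' @param contrasts contrast provider, see \code{\link{default_contrasts}}.
#' @return data.frame of class \code{assoc_result} with one row per SNP
#'   (estimates, t statistics, two-sided p-values, rank) and attributes
#'   \code{method}, \code{trait}, \code{vc}.
#' @export
gls_scan <- function(g, phenotypes, trait, families, covariates = NULL,
                     vc = NULL, reml = FALSE,
                     coding = c("classes", "additive"),
                     contrasts = default_contrasts) {
  coding <- match.arg(coding)
  if (!trait %in% names(phenotypes)) stop("unknown trait: ", trait)
  ids <- scan_ids(g, phenotypes, families)
  y <- stats::setNames(phenotypes[[trait]][match(ids, phenotypes$id)], ids)
  xe <- align_covariates(covariates, ids)
  if (is.null(vc))
    vc <- estimate_vc_ml(y, families, x_null = xe, ids = ids, reml = reml)
  out <- assoc_scan_core(g[ids, ], y, ids, x_extra = xe,
                         families = families, vc = vc,
                         coding = coding, contrasts = contrasts)
  attr(out, "method") <- if (is.null(covariates)) "GLS" else "GLS-PCA"
  attr(out, "trait") <- trait
  attr(out, "vc") <- vc
  class(out) <- c("assoc_result", class(out))
  out
}

#' Least-squares association scan (with optional PCA correction)
#'
#' Ordinary least squares per SNP with the same genotype-class coding and
#' contrasts as \code{\link{gls_scan}} but no family covariance. Passing
#' principal components (or \code{n_pcs > 0}) gives the PCA-corrected
#' method; \code{exclude} drops individuals (e.g. the elite family) and
#' recomputes allele frequencies and PCs on the retained sample — the
#' elite-removal sensitivity rerun.
#'
#' @inheritParams gls_scan
#' @param n_pcs when > 0 and \code{covariates} is NULL, this many PCs are
#'   computed from the (retained) genotypes and used as covariates.
#' @param exclude individual ids to drop before any computation.
#' @return an \code{assoc_result} data.frame (method "LS", "PCA" or
#'   "LS_excl").
#' @export
ls_scan <- function(g, phenotypes, trait, covariates = NULL, n_pcs = 0,
                    exclude = NULL, coding = c("classes", "additive"),
                    contrasts = default_contrasts) {
  coding <- match.arg(coding)
  if (!trait %in% names(phenotypes)) stop("unknown trait: ", trait)
  if (!is.null(exclude)) {
    keep <- setdiff(g$individual_ids, exclude)
    g <- g[keep, ]
  }
  ids <- scan_ids(g, phenotypes)
  g <- g[ids, ]
  if (is.null(covariates) && n_pcs > 0)
    covariates <- compute_pcs(g, n_components = n_pcs)
  y <- stats::setNames(phenotypes[[trait]][match(ids, phenotypes$id)], ids)
  xe <- align_covariates(covariates, ids)
  out <- assoc_scan_core(g, y, ids, x_extra = xe,
                         coding = coding, contrasts = contrasts)
  attr(out, "method") <- if (!is.null(xe)) "PCA"
                         else if (!is.null(exclude)) "LS_excl" else "LS"
  attr(out, "trait") <- trait
  class(out) <- c("assoc_result", class(out))
  out
}
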