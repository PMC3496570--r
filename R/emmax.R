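#' Mixed-model variance components with a genome-wide kinship
#'
#' Fits the null model \code{y = X b + u + e} with \code{var(u) =
#' K sigma_a2}, \code{var(e) = I sigma_e2}. K is eigendecomposed once;
#' writing \code{delta = sigma_e2 / sigma_a2}, the (restricted or full)
#' log-likelihood is profiled over delta on a log grid spanning
#' 1e-5 ... 1e5 with closed-form \code{sigma_a2(delta)} at each point,
#' then refined by Brent search. REML is the default criterion (the
#' convention of mixed-model association software); set
#' \code{reml = FALSE} for ML, e.g. when comparing against
#' \code{\link{estimate_vc_ml}}.
#'
#' @param y phenotype vector named by individual id.
#' @param K a \code{\link{kinship_matrix}} (or plain symmetric matrix with
#'   id dimnames) covering the ids.
#' @param x_null optional covariate matrix (intercept added).
#' @param ids ids aligned with \code{y}; default \code{names(y)}.
#' @param reml restricted (default) or full maximum likelihood.
#' @param n_grid grid points over log10(delta).
#' @return An object of class \code{mixed_vc}: \code{sigma_a2},
#'   \code{sigma_e2}, \code{delta}, \code{log_likelihood},
#'   \code{criterion}, \code{flavor}, \code{ids} and the cached
#'   \code{eigen} decomposition (reused by \code{\link{emmax_scan}}).
#' @export
estimate_vc_emma <- function(y, K, x_null = NULL, ids = names(y),
                             reml = TRUE, n_grid = 100) {
  if (is.null(ids)) stop("y must be named by individual id (or supply ids)")
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  flavor <- if (inherits(K, "kinship_matrix")) K$flavor else "matrix"
  kv <- if (inherits(K, "kinship_matrix")) K$values else K
  if (!all(ids %in% rownames(kv))) stop("kinship matrix missing ids")
  kv <- kv[ids, ids]
  n <- length(y)
  ek <- eigen(kv, symmetric = TRUE)
  tolv <- 1e-8 * max(abs(ek$values))
  if (min(ek$values) < -tolv) stop("kinship matrix is not PSD")
  vals <- pmax(ek$values, 0)
  u <- ek$vectors
  x <- if (is.null(x_null)) matrix(1, n, 1) else cbind(1, x_null)
  k <- qr(x)$rank
  if (k < ncol(x)) stop("null-model covariates are rank deficient")
  yt <- drop(crossprod(u, y))
  xt <- crossprod(u, x)

  prof <- function(ld) {
    delta <- 10^ld
    w <- vals + delta
    sw <- 1 / sqrt(w)
    fit <- stats::lm.fit(xt * sw, yt * sw)
    rss <- sum(fit$residuals^2)
    if (reml) {
      s2 <- rss / (n - k)
      ldx <- as.numeric(determinant(crossprod(xt * sw), TRUE)$modulus)
      ldx0 <- as.numeric(determinant(crossprod(x), TRUE)$modulus)
      -0.5 * ((n - k) * log(2 * pi) + (n - k) * log(s2) + sum(log(w)) +
                ldx - ldx0 + (n - k))
    } else {
      s2 <- rss / n
      -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(w)) + n)
    }
  }

  grid <- seq(-5, 5, length.out = n_grid)
  ll <- vapply(grid, prof, 0)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
  ld <- opt$maximum
  if (ll[i] > opt$objective) ld <- grid[i]
  delta <- 10^ld
  w <- vals + delta
  sw <- 1 / sqrt(w)
  fit <- stats::lm.fit(xt * sw, yt * sw)
  rss <- sum(fit$residuals^2)
  s_a2 <- if (reml) rss / (n - k) else rss / n
  structure(list(sigma_a2 = s_a2, sigma_e2 = delta * s_a2, delta = delta,
                 log_likelihood = prof(ld),
                 criterion = if (reml) "REML" else "ML",
                 flavor = flavor, ids = ids, k_null = k,
                 eigen = list(values = vals, vectors = u),
                 profile = list(log10_delta = grid, log_likelihood = ll)),
            class = "mixed_vc")
}

#' @export
print.mixed_vc <- function(x, ...) {
  cat(sprintf("mixed_vc (%s, K = %s): sigma_a2 = %.4g, sigma_e2 = %.4g (h2 = %.3f)\n",
              x$criterion, x$flavor, x$sigma_a2, x$sigma_e2,
              x$sigma_a2 / (x$sigma_a2 + x$sigma_e2)))
  invisible(x)
}

#' EMMAX-style association scan
#'
#' Tests each SNP by additive-dosage (0/1/2) generalized least squares
#' with the covariance fixed at \code{V = sigma_a2 K + sigma_e2 I} from
#' the null-model fit: the cached spectral decomposition of K rotates the
#' phenotype, covariates and all dosages once, after which every SNP is an
#' O(n) weighted regression (Frisch-Waugh projection of the rotated
#' dosage on the rotated covariates). Missing dosages are mean-imputed per
#' SNP for the scan only. Optional PC covariates give the EMMAX-PCA
#' variant. t statistics use n - k degrees of freedom.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param phenotypes data.frame with column \code{id} plus traits.
#' @param trait trait name.
#' @param K kinship (see \code{\link{estimate_vc_emma}}); ignored when
#'   \code{vc} is supplied.
#' @param covariates optional matrix / \code{\link{compute_pcs}} result.
#' @param vc optional precomputed \code{\link{estimate_vc_emma}} result.
#' @param reml criterion for the variance components if estimated here.
#' @return an \code{assoc_result} data.frame (method "EMMAX-<flavor>" or
#'   "EMMAX-PCA") with additive-effect columns filled.
#' @export
emmax_scan <- function(g, phenotypes, trait, K = NULL, covariates = NULL,
                       vc = NULL, reml = TRUE) {
  if (!trait %in% names(phenotypes)) stop("unknown trait: ", trait)
  ids <- scan_ids(g, phenotypes)
  g <- g[ids, ]
  y <- stats::setNames(phenotypes[[trait]][match(ids, phenotypes$id)], ids)
  xe <- align_covariates(covariates, ids)
  if (is.null(vc)) {
    if (is.null(K)) stop("supply K or a precomputed vc")
    vc <- estimate_vc_emma(y, K, x_null = xe, ids = ids, reml = reml)
  }
  if (!identical(vc$ids, ids))
    stop("variance-component fit covers different individuals")
  u <- vc$eigen$vectors
  w <- vc$eigen$values + vc$delta
  sw <- 1 / sqrt(w)

  d <- dosage(g)
  nmiss <- colSums(is.na(d))
  if (any(nmiss > 0)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  n <- length(ids)
  x0 <- cbind(rep(1, n), xe)
  x0s <- crossprod(u, x0) * sw
  ys <- drop(crossprod(u, y)) * sw
  gs <- crossprod(u, d) * sw

  a <- crossprod(x0s)
  ainv <- chol2inv(chol(a))
  proj <- x0s %*% (ainv %*% crossprod(x0s, gs))
  rg <- gs - proj
  ry <- ys - drop(x0s %*% (ainv %*% crossprod(x0s, ys)))
  gg <- colSums(rg^2)
  gy <- drop(crossprod(rg, ry))
  yy <- sum(ry^2)
  k0 <- ncol(x0)
  df <- n - k0 - 1
  # a SNP is testable if its rotated dosage keeps non-negligible variation
  # after projecting out the covariates (scale-invariant cutoff)
  testable <- gg > 1e-10 * colSums(gs^2)
  beta <- ifelse(testable, gy / gg, NA_real_)
  s2 <- (yy - beta^2 * gg) / df
  se <- sqrt(s2 / gg)
  tt <- beta / se
  pv <- 2 * stats::pt(-abs(tt), df)

  out <- data.frame(snp_id = g$snp_ids, chromosome = g$chromosome,
                    position = g$position,
                    allele1 = g$alleles[, 1], allele2 = g$alleles[, 2],
                    n_used = n - nmiss, freq1 = colMeans(d) / 2,
                    est_additive = beta, se_additive = se,
                    t_additive = tt, p_additive = pv,
                    est_dominance = NA_real_, t_dominance = NA_real_,
                    p_dominance = NA_real_,
                    p = pv, df = df,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank <- assoc_rank(out$p, out$chromosome, out$position)
  attr(out, "method") <- if (is.null(covariates))
    paste0("EMMAX-", vc$flavor) else "EMMAX-PCA"
  attr(out, "trait") <- trait
  attr(out, "vc") <- vc
  class(out) <- c("assoc_result", class(out))
  out
}
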