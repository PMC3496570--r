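#' Maximum-likelihood variance components under intraclass correlation
#'
#' Fits the null (no-SNP) half-sib model \code{y = X b + Z f + e} with
#' \code{var(f) = I sigma_f2}, \code{var(e) = I sigma_e2}, i.e. a
#' compound-symmetry covariance within each sire family. Writing
#' \code{sigma2 = sigma_f2 + sigma_e2} and intraclass correlation
#' \code{rho = sigma_f2 / sigma2}, the Gaussian likelihood is profiled:
#' for each \code{rho}, the GLS mean and the closed-form
#' \code{sigma2_hat(rho)} are computed through the O(n) whitening factor,
#' the profile is evaluated on a grid over [0, 0.999] and the optimum
#' refined by Brent search; the boundary \code{rho = 0} is admissible.
#'
#' @param y numeric phenotype vector named by individual id (or aligned
#'   with \code{ids}).
#' @param families a \code{\link{family_structure}} covering all ids.
#' @param x_null covariate matrix of the null model (default: intercept
#'   only), rows aligned with \code{y}.
#' @param ids individual ids aligned with \code{y}; default
#'   \code{names(y)}.
#' @param reml use the restricted likelihood instead of full ML.
#' @param n_grid grid points for the initial profile over rho.
#' @return An object of class \code{intraclass_vc} with elements
#'   \code{sigma_f2}, \code{sigma_e2}, \code{sigma2}, \code{rho},
#'   \code{r} and \code{lambda} (per family), \code{log_likelihood},
#'   \code{criterion}, \code{family_sizes}, \code{ids}.
#' @export
estimate_vc_ml <- function(y, families, x_null = NULL, ids = names(y),
                           reml = FALSE, n_grid = 100) {
  if (is.null(ids)) stop("y must be named by individual id (or supply ids)")
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  blocks <- family_index_blocks(families, ids)
  n <- length(y)
  x <- if (is.null(x_null)) matrix(1, n, 1) else cbind(1, x_null)
  k <- qr(x)$rank
  if (k < ncol(x)) stop("null-model covariates are rank deficient")
  if (n <= k) stop("more covariates than observations")
  sizes <- lengths(blocks)

  prof <- function(rho) {
    w <- whitener_from_blocks(blocks, sigma_f2 = rho, sigma_e2 = 1 - rho)
    ys <- whiten(w, y)
    xs <- whiten(w, x)
    fit <- stats::lm.fit(xs, ys)
    rss <- sum(fit$residuals^2)
    ldet <- sum((sizes - 1) * log(1 - rho) + log(1 + (sizes - 1) * rho))
    if (reml) {
      s2 <- rss / (n - k)
      ldx <- determinant(crossprod(xs), logarithm = TRUE)$modulus
      -0.5 * ((n - k) * log(2 * pi) + (n - k) * log(s2) + ldet +
                as.numeric(ldx) + (n - k))
    } else {
      s2 <- rss / n
      -0.5 * (n * log(2 * pi) + n * log(s2) + ldet + n)
    }
  }

  grid <- seq(0, 0.999, length.out = n_grid)
  ll <- vapply(grid, prof, 0)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
  rho <- opt$maximum
  if (prof(grid[i]) > opt$objective) rho <- grid[i]  # keep boundary optima
  # closed-form sigma2 at the optimum
  w <- whitener_from_blocks(blocks, sigma_f2 = rho, sigma_e2 = 1 - rho)
  fit <- stats::lm.fit(whiten(w, x), whiten(w, y))
  rss <- sum(fit$residuals^2)
  s2 <- if (reml) rss / (n - k) else rss / n
  r <- rho / (1 + (sizes - 1) * rho)
  structure(list(sigma_f2 = rho * s2, sigma_e2 = (1 - rho) * s2,
                 sigma2 = s2, rho = rho,
                 r = r, lambda = r / (1 - r),
                 log_likelihood = prof(rho),
                 criterion = if (reml) "REML" else "ML",
                 family_sizes = sizes, ids = ids),
            class = "intraclass_vc")
}

#' @export
print.intraclass_vc <- function(x, ...) {
  cat(sprintf("intraclass_vc (%s): sigma_f2 = %.4g, sigma_e2 = %.4g, rho = %.4f\n",
              x$criterion, x$sigma_f2, x$sigma_e2, x$rho))
  invisible(x)
}

# Structured upper-triangular factor for one compound-symmetry block.
# V = sigma_e2 * I + sigma_f2 * J has V^{-1} = (1/sigma_e2) * (I - r J)
# with r = sigma_f2 / (sigma_e2 + n * sigma_f2). An upper-triangular L
# with L'L = V^{-1} exists whose row i has diagonal d_i and a constant
# value o_i on all columns j > i; matching entries of L'L gives the O(n)
# recurrence below (a = diagonal target, b = off-diagonal target,
# S = running sum of squared off-diagonal values).
block_factor <- function(n_i, sigma_f2, sigma_e2) {
  cc <- 1 / sigma_e2
  r <- sigma_f2 / (sigma_e2 + n_i * sigma_f2)
  a <- cc * (1 - r)
  b <- -cc * r
  d <- numeric(n_i); o <- numeric(n_i)
  s <- 0
  for (i in seq_len(n_i)) {
    d2 <- a - s
    if (d2 <= 0) stop("whitener breakdown: sigma_e2 too small (",
                      format(sigma_e2), ")")
    d[i] <- sqrt(d2)
    if (i < n_i) {
      o[i] <- (b - s) / d[i]
      s <- s + o[i]^2
    }
  }
  list(d = d, o = o)
}

whitener_from_blocks <- function(blocks, sigma_f2, sigma_e2) {
  if (sigma_e2 <= 1e-12)
    stop("whitener breakdown: sigma_e2 underflows (", format(sigma_e2), ")")
  sizes <- lengths(blocks)
  facs <- lapply(unique(sizes), block_factor,
                 sigma_f2 = sigma_f2, sigma_e2 = sigma_e2)
  names(facs) <- as.character(unique(sizes))
  structure(list(blocks = blocks,
                 factors = facs,
                 sigma_f2 = sigma_f2, sigma_e2 = sigma_e2),
            class = "whitener")
}

#' Closed-form whitening factor for half-sib GLS
#'
#' Builds, family by family, the structured upper-triangular factor L with
#' \code{L'L = V^{-1}}, where \code{V = sigma_e2 I + sigma_f2 J} is the
#' compound-symmetry block of the family. L is stored as O(n_i) numbers
#' per family (a per-row diagonal and a per-row constant off-diagonal
#' value), and applying it to a vector costs O(n_i) using running suffix
#' sums — the V inverse is never formed.
#'
#' @param families a \code{\link{family_structure}}.
#' @param vc an \code{\link{estimate_vc_ml}} result (or any list with
#'   \code{sigma_f2}, \code{sigma_e2}).
#' @param ids individual ordering; default the ordering stored in
#'   \code{vc}, else family-block order. Must be family-contiguous.
#' @return An object of class \code{whitener}.
#' @export
build_whitener <- function(families, vc, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (!is.null(vc$ids)) vc$ids
    else unlist(families$family_blocks, use.names = FALSE)
  }
  whitener_from_blocks(family_index_blocks(families, ids),
                       sigma_f2 = vc$sigma_f2, sigma_e2 = vc$sigma_e2)
}

#' Apply a whitening factor
#'
#' Computes \code{L x} block by block in O(n) per column:
#' \code{(Lx)_i = d_i x_i + o_i * sum_{j > i} x_j} within each family.
#'
#' @param w a \code{whitener}.
#' @param x numeric vector or matrix in the whitener's individual order.
#' @return whitened vector / matrix.
#' @export
whiten <- function(w, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  out <- x * 0
  for (b in w$blocks) {
    n_i <- length(b)
    f <- w$factors[[as.character(n_i)]]
    xb <- x[b, , drop = FALSE]
    if (n_i == 1) {
      out[b, ] <- f$d * xb
    } else {
      cs <- apply(xb, 2, function(col) rev(cumsum(rev(col))))
      cs <- matrix(cs, n_i)
      suf <- rbind(cs[-1, , drop = FALSE], 0)
      out[b, ] <- f$d * xb + f$o * suf
    }
  }
  if (vec) drop(out) else out
}

#' Dense version of a whitening factor
#'
#' Materializes L as a full matrix (testing / inspection only; the scan
#' never builds it).
#'
#' @param w a \code{whitener}.
#' @return dense upper-triangular (block) matrix.
#' @export
whitener_dense <- function(w) {
  n <- sum(lengths(w$blocks))
  l <- matrix(0, n, n)
  for (b in w$blocks) {
    f <- w$factors[[as.character(length(b))]]
    for (i in seq_along(b)) {
      l[b[i], b[i]] <- f$d[i]
      if (i < length(b)) l[b[i], b[(i + 1):length(b)]] <- f$o[i]
    }
  }
  l
}

#' Genotype-class GLS fit
#'
#' Whitens the response and design with the factor L and solves ordinary
#' least squares on the whitened system, which reproduces the GLS normal
#' equations \code{(X' V^{-1} X) g = X' V^{-1} y}. The design is the
#' genotype-class indicator block (one column per observed class, ordered
#' by decreasing allele-1 dosage) followed by any extra covariates.
#'
#' @param y phenotype vector in whitener order.
#' @param classes factor/vector of genotype classes (dosage values), or
#'   \code{NULL} for a covariate-only fit with intercept.
#' @param x_extra optional covariate matrix (no intercept column; when
#'   \code{classes} is given the class indicators span the intercept).
#' @param whitener a \code{\link{build_whitener}} result, or \code{NULL}
#'   for the identity (ordinary least squares).
#' @return An object of class \code{gls_fit}: \code{ghat} (all
#'   coefficients; the first \code{n_classes} are genotype-class values),
#'   \code{class_dosages}, \code{n_classes}, \code{cov_unscaled}
#'   (\code{(X' V^{-1} X)^{-1}}), \code{s2}, \code{k}, \code{df}.
#' @export
gls_fit <- function(y, classes = NULL, x_extra = NULL, whitener = NULL) {
  n <- length(y)
  if (is.null(classes)) {
    x <- cbind(intercept = rep(1, n))
    cd <- numeric(0)
  } else {
    lev <- sort(unique(classes), decreasing = TRUE)
    x <- vapply(lev, function(l) as.numeric(classes == l), numeric(n))
    colnames(x) <- paste0("class", lev)
    cd <- lev
  }
  if (!is.null(x_extra)) x <- cbind(x, as.matrix(x_extra))
  ys <- if (is.null(whitener)) y else whiten(whitener, y)
  xs <- if (is.null(whitener)) x else whiten(whitener, x)
  xtx <- crossprod(xs)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(ch)) {
    piv <- qr(xs)
    bad <- colnames(x)[piv$pivot[-seq_len(piv$rank)]]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- drop(backsolve(ch, forwardsolve(t(ch), crossprod(xs, ys))))
  names(beta) <- colnames(x)
  resid <- ys - drop(xs %*% beta)
  k <- ncol(x)
  if (n - k < 1) stop("no residual degrees of freedom")
  s2 <- sum(resid^2) / (n - k)
  structure(list(ghat = beta, class_dosages = cd,
                 n_classes = length(cd),
                 cov_unscaled = chol2inv(ch),
                 s2 = s2, k = k, df = n - k, n = n),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("gls_fit: %d coefficient(s) (%d genotype classes), s2 = %.4g, df = %d\n",
              length(x$ghat), x$n_classes, x$s2, x$df))
  invisible(x)
}

#' Contrast t-test on genotype-class values
#'
#' Tests \code{s' ghat = 0} with
#' \code{T = s' ghat / sqrt(s2 * s' (X' V^{-1} X)^{-1} s)}, referred to a
#' Student-t distribution with \code{n - k} degrees of freedom (two-sided).
#'
#' @param fit a \code{\link{gls_fit}}.
#' @param s contrast coefficients over the genotype classes (length
#'   \code{fit$n_classes}; padded with zeros over covariates), or over all
#'   coefficients.
#' @param label effect label, e.g. "additive" or "dominance".
#' @return data.frame row: estimate, se, t, p, df, label.
#' @export
contrast_test <- function(fit, s, label = "contrast") {
  p <- length(fit$ghat)
  if (length(s) == fit$n_classes && fit$n_classes < p)
    s <- c(s, rep(0, p - fit$n_classes))
  stopifnot(length(s) == p)
  est <- sum(s * fit$ghat)
  v <- fit$s2 * drop(t(s) %*% fit$cov_unscaled %*% s)
  if (v <= 0) {
    if (abs(est) > 1e-12)
      stop("zero standard error with nonzero contrast estimate")
    return(data.frame(label = label, estimate = est, se = 0,
                      t = 0, p = 1, df = fit$df))
  }
  se <- sqrt(v)
  tt <- est / se
  data.frame(label = label, estimate = est, se = se, t = tt,
             p = 2 * stats::pt(-abs(tt), fit$df), df = fit$df)
}

#' Default additive / dominance contrast provider
#'
#' Given the observed genotype-class dosages in decreasing order, returns
#' the equal-weight orthogonal contrasts: additive \code{(1, 0, -1)} and
#' dominance \code{(-1, 2, -1)/2} for three classes; the two-class
#' difference contrast (labelled additive) when only two classes are
#' observed. Supply your own provider to \code{\link{gls_scan}} for e.g.
#' frequency-weighted contrasts.
#'
#' @param class_dosages numeric vector of observed dosages, decreasing.
#' @return named list of contrast vectors.
#' @export
default_contrasts <- function(class_dosages) {
  if (length(class_dosages) == 3) {
    list(additive = c(1, 0, -1), dominance = c(-1, 2, -1) / 2)
  } else if (length(class_dosages) == 2) {
    list(additive = c(1, -1))
  } else {
    list()
  }
}
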