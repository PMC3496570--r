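# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# dense compound-symmetry covariance for a family-size vector
dense_cs_cov <- function(sizes, sigma_f2, sigma_e2) {
  sire <- rep(seq_along(sizes), sizes)
  sigma_e2 * diag(sum(sizes)) + sigma_f2 * outer(sire, sire, `==`)
}

# dense GLS solution with an explicitly inverted V
dense_gls <- function(y, x, v) {
  vi <- solve(v)
  covb <- solve(t(x) %*% vi %*% x)
  beta <- covb %*% t(x) %*% vi %*% y
  n <- length(y); k <- ncol(x)
  # residual mean square on the decorrelated scale
  r <- y - x %*% beta
  s2 <- drop(t(r) %*% vi %*% r) / (n - k)
  list(beta = drop(beta), cov_unscaled = covb, s2 = s2, df = n - k)
}

dense_gls_contrast <- function(fit, s) {
  est <- sum(s * fit$beta)
  se <- sqrt(fit$s2 * drop(t(s) %*% fit$cov_unscaled %*% s))
  tt <- est / se
  list(estimate = est, t = tt, p = 2 * pt(-abs(tt), fit$df))
}

# exhaustive pairwise IBS count (shared alleles / 2, pairwise complete)
brute_ibs <- function(d) {
  n <- nrow(d)
  s <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(d[i, ]) & !is.na(d[j, ])
    s[i, j] <- s[j, i] <- mean((2 - abs(d[i, ok] - d[j, ok])) / 2)
  }
  s
}

# loop-based Balding-Nichols standardization
brute_bn <- function(d) {
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  z <- matrix(0, nrow(d), ncol(d))
  for (j in seq_len(ncol(d))) {
    zj <- (d[, j] - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
    zj[is.na(zj)] <- 0
    z[, j] <- zj
  }
  z %*% t(z) / ncol(z)
}

# exhaustive DFS over pedigree edges (child -> parents), descending
brute_descendants <- function(ped, ancestor) {
  kids_of <- function(p) ped$child[!is.na(ped$sire) & ped$sire == p |
                                     !is.na(ped$dam) & ped$dam == p]
  out <- character(0)
  stack <- ancestor
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    kk <- setdiff(kids_of(cur), out)
    out <- c(out, kk)
    stack <- c(stack, kk)
  }
  out
}

# dense ML profile over rho with explicit V construction/inversion
brute_rho_ml <- function(y, sizes, step = 1e-4) {
  n <- length(y)
  x <- matrix(1, n, 1)
  ll <- function(rho) {
    v <- dense_cs_cov(sizes, rho, 1 - rho)
    vi <- solve(v)
    beta <- solve(t(x) %*% vi %*% x, t(x) %*% vi %*% y)
    r <- y - x %*% beta
    s2 <- drop(t(r) %*% vi %*% r) / n
    -0.5 * (n * log(2 * pi) + n * log(s2) +
              determinant(v, TRUE)$modulus + n)
  }
  grid <- seq(0, 0.999, by = step)
  grid[which.max(vapply(grid, ll, 0))]
}

# small random genotype matrix with optional missing calls
random_genotypes <- function(n, m, seed, miss_rate = 0) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  a1 <- matrix(rbinom(n * m, 1, rep(p, each = n)) + 1L, n, m)
  a2 <- matrix(rbinom(n * m, 1, rep(p, each = n)) + 1L, n, m)
  if (miss_rate > 0) {
    na <- matrix(runif(n * m) < miss_rate, n, m)
    a1[na] <- NA; a2[na] <- NA
  }
  genotype_matrix(sprintf("i%03d", 1:n), sprintf("s%03d", 1:m),
                  rep("1", m), seq_len(m) * 1000L,
                  matrix(rep(c("A", "G"), each = m), m, 2),
                  a1, a2)
}

# intraclass correlation by one-way ANOVA moment estimator
anova_icc <- function(y, fam) {
  fit <- anova(lm(y ~ factor(fam)))
  msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
  n0 <- mean(table(fam))
  (msb - msw) / (msb + (n0 - 1) * msw)
}
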