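fam_of_sizes <- function(sizes) {
  ids <- sprintf("i%03d", seq_len(sum(sizes)))
  family_structure(setNames(rep(sprintf("s%02d", seq_along(sizes)), sizes),
                            ids))
}

test_that("whitener satisfies L'L = V^-1 for the stated grid", {
  for (ni in c(1, 2, 5, 160)) {
    for (rho in c(0, 0.1, 0.5, 0.9)) {
      fam <- fam_of_sizes(ni)
      w <- build_whitener(fam, list(sigma_f2 = rho, sigma_e2 = 1 - rho),
                          ids = names(fam$sire_of))
      l <- whitener_dense(w)
      # closed-form compound-symmetry inverse
      r <- rho / (1 + (ni - 1) * rho)
      vi <- (1 / (1 - rho)) * (diag(ni) - r * matrix(1, ni, ni))
      expect_lt(max(abs(t(l) %*% l - vi)), 1e-8)
      # dense triangular-factorization oracle (chol of V^-1)
      lo <- chol(vi)
      expect_lt(max(abs(t(lo) %*% lo - t(l) %*% l)), 1e-8)
      # structure: upper triangular with constant off-diagonal per row
      expect_true(all(l[lower.tri(l)] == 0))
      if (ni > 2)
        expect_lt(max(abs(l[1, 2:ni] - l[1, 2])), 1e-12)
    }
  }
})

test_that("whitener degenerate cases take closed forms", {
  fam <- fam_of_sizes(c(3, 1))
  # rho = 0: diagonal 1/sigma_e
  w0 <- build_whitener(fam, list(sigma_f2 = 0, sigma_e2 = 4),
                       ids = names(fam$sire_of))
  l0 <- whitener_dense(w0)
  expect_equal(l0, diag(1 / 2, 4))
  # singleton family: single entry 1/sqrt(sigma2)
  w1 <- build_whitener(fam, list(sigma_f2 = 3, sigma_e2 = 1),
                       ids = names(fam$sire_of))
  expect_equal(whitener_dense(w1)[4, 4], 1 / 2)
  # sigma_e2 underflow reported
  expect_error(build_whitener(fam, list(sigma_f2 = 1, sigma_e2 = 1e-15),
                              ids = names(fam$sire_of)), "underflow")
})

test_that("whitening a vector matches the dense product in O(n) form", {
  set.seed(71)
  fam <- fam_of_sizes(c(4, 7, 1, 12))
  w <- build_whitener(fam, list(sigma_f2 = 0.6, sigma_e2 = 1.7),
                      ids = names(fam$sire_of))
  x <- matrix(rnorm(48), 24, 2)
  expect_lt(max(abs(whiten(w, x) - whitener_dense(w) %*% x)), 1e-12)
})

test_that("ML variance components match trivial and dense-grid oracles", {
  # zero within-family variance drives rho to the upper boundary
  fam <- fam_of_sizes(c(2, 2))
  y <- setNames(c(1, 1, 5, 5), names(fam$sire_of))
  vc <- estimate_vc_ml(y, fam)
  expect_gt(vc$rho, 0.99)

  # 4 families, n = 20: matches dense brute-force profile to 1e-3
  set.seed(73)
  fam2 <- fam_of_sizes(c(6, 5, 5, 4))
  sizes <- c(6, 5, 5, 4)
  v <- dense_cs_cov(sizes, 0.5, 1)
  y2 <- drop(chol(v) %*% rnorm(20))
  names(y2) <- names(fam2$sire_of)
  vc2 <- estimate_vc_ml(y2, fam2)
  rho_oracle <- brute_rho_ml(unname(y2), sizes)
  expect_lt(abs(vc2$rho - rho_oracle), 1e-3)
  # r decreases with family size when rho > 0
  expect_true(all(diff(vc2$r[order(vc2$family_sizes)]) <= 0))
})

test_that("GLS fit equals dense GLS with explicit V inverse", {
  set.seed(79)
  sizes <- c(12, 8, 10)
  fam <- fam_of_sizes(sizes)
  n <- 30
  y <- rnorm(n)
  cls <- sample(0:2, n, replace = TRUE)
  sf <- 0.8; se2 <- 1.5
  w <- build_whitener(fam, list(sigma_f2 = sf, sigma_e2 = se2),
                      ids = names(fam$sire_of))
  fit <- gls_fit(y, classes = cls, whitener = w)
  x <- vapply(sort(unique(cls), decreasing = TRUE),
              function(l) as.numeric(cls == l), numeric(n))
  oracle <- dense_gls(y, x, dense_cs_cov(sizes, sf, se2))
  expect_lt(max(abs(fit$ghat - oracle$beta)), 1e-9)
  expect_lt(max(abs(fit$cov_unscaled - oracle$cov_unscaled)), 1e-9)
  expect_lt(abs(fit$s2 - oracle$s2), 1e-9)
  # contrast t and p match the dense construction
  ct <- contrast_test(fit, c(1, 0, -1), "additive")
  od <- dense_gls_contrast(oracle, c(1, 0, -1))
  expect_lt(abs(ct$t - od$t), 1e-9)
  expect_lt(abs(ct$p - od$p), 1e-9)
})

test_that("rho = 0 with intercept-only design reduces to OLS", {
  set.seed(83)
  fam <- fam_of_sizes(rep(1, 15))
  y <- rnorm(15)
  w <- build_whitener(fam, list(sigma_f2 = 0, sigma_e2 = 1),
                      ids = names(fam$sire_of))
  fit <- gls_fit(y, whitener = w)
  expect_equal(unname(fit$ghat), mean(y))
  # against lm
  cls <- sample(0:2, 15, replace = TRUE)
  fit2 <- gls_fit(y, classes = cls, whitener = w)
  lmfit <- lm(y ~ 0 + factor(cls, levels = sort(unique(cls),
                                                decreasing = TRUE)))
  expect_equal(unname(fit2$ghat), unname(coef(lmfit)), tolerance = 1e-10)
})

test_that("two-class contrast reproduces the pooled two-sample t-test", {
  set.seed(89)
  fam <- fam_of_sizes(rep(1, 24))
  cls <- rep(c(2, 0), c(10, 14))
  y <- rnorm(24) + 0.8 * (cls == 2)
  w <- build_whitener(fam, list(sigma_f2 = 0, sigma_e2 = 1),
                      ids = names(fam$sire_of))
  fit <- gls_fit(y, classes = cls, whitener = w)
  ct <- contrast_test(fit, c(1, -1), "additive")
  tt <- t.test(y[cls == 2], y[cls == 0], var.equal = TRUE)
  expect_lt(abs(ct$t - tt$statistic), 1e-10)
  expect_lt(abs(ct$p - tt$p.value), 1e-10)
  # exactly null contrast: T = 0, p = 1
  ct0 <- contrast_test(fit, c(0, 0), "null")
  expect_equal(ct0$t, 0)
  expect_equal(ct0$p, 1)
})

test_that("gls_scan flags monomorphic SNPs and finds a planted effect", {
  planted <- data.frame(chr = "1", index = 10, elite_freq = 0.5,
                        average_freq = 0.5, effect = 1.2, trait = "MY")
  cfg <- sim_config(n_individuals = 300, n_sires = 30,
                    elite_family_size = 10, family_sizes = rep(10L, 30),
                    n_autosomes = 1, include_x = FALSE,
                    n_snps_per_chr = 60, planted_loci = planted,
                    sigma_f2 = 1, sigma_e2 = 3,
                    trait_catalog = default_trait_catalog()[1, ],
                    seed = 97)
  pop <- simulate_population(cfg)
  g <- pop$genotypes
  # graft a monomorphic SNP
  g$a1[, 1] <- 1L; g$a2[, 1] <- 1L
  res <- gls_scan(g, pop$phenotypes, "MY", pop$families)
  expect_true(is.na(res$p[1]))
  expect_equal(res$snp_id[which.min(res$p)], pop$truth$snp_id)
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  # ranks are a permutation over tested SNPs
  expect_setequal(res$rank[!is.na(res$p)], seq_len(sum(!is.na(res$p))))
  expect_error(gls_scan(g, pop$phenotypes, "FY", pop$families),
               "unknown trait")
})

test_that("scan handles missing calls by excluding individuals", {
  cfg <- sim_null_config(n_families = 10, family_size = 6, n_snps = 20,
                         seed = 101)
  pop <- simulate_population(cfg)
  g <- pop$genotypes
  set.seed(5)
  drop_idx <- sample(60, 12)
  g$a1[drop_idx, 3] <- NA; g$a2[drop_idx, 3] <- NA
  res <- gls_scan(g, pop$phenotypes, "MY", pop$families)
  expect_equal(res$n_used[3], 60 - length(unique(drop_idx)))
  expect_false(is.na(res$p[3]))
})
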