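fake_results <- function(p, chr = NULL, pos = NULL, ids = NULL) {
  m <- length(p)
  data.frame(snp_id = ids %||% sprintf("s%03d", seq_len(m)),
             chromosome = chr %||% rep("1", m),
             position = pos %||% seq_len(m) * 10L,
             p = p, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("top_k selects smallest p with deterministic tie-breaking", {
  r <- fake_results(c(0.5, 0.01, 0.2, 0.03, 0.9))
  expect_equal(top_k(r, 3)$snp_id, c("s002", "s004", "s003"))
  # tie at the k-th place: earlier (chr, pos) wins
  r2 <- fake_results(c(0.5, 0.1, 0.1, 0.1), chr = c("1", "2", "1", "1"),
                     pos = c(5L, 5L, 9L, 2L))
  expect_equal(top_k(r2, 2)$snp_id, c("s004", "s003"))
  # full-sort oracle on random tables
  set.seed(181)
  for (rep in 1:5) {
    p <- round(runif(40), 2)      # forces ties
    r3 <- fake_results(p)
    expect_equal(top_k(r3, 10)$snp_id,
                 r3$snp_id[order(p, r3$position)][1:10])
  }
})

test_that("overlap accounting handles identical, disjoint and real lists", {
  mk <- function(p) fake_results(p)
  p0 <- seq(0.001, 0.4, length.out = 20)
  res <- list(T1 = list(LS = mk(p0), E = mk(p0), G = mk(p0), P = mk(p0)))
  tab <- overlap_table(res, "LS", c("E", "G", "P"), k = 5)
  expect_true(all(tab[1, -1] == 5))
  # disjoint top lists -> all zero
  res2 <- list(T1 = list(LS = mk(p0), E = mk(rev(p0))))
  expect_equal(overlap_table(res2, "LS", "E", k = 5)[1, 2], 0)
  # subset monotonicity on random rankings
  set.seed(191)
  for (rep in 1:5) {
    res3 <- list(T1 = list(LS = mk(runif(30)), E = mk(runif(30)),
                           G = mk(runif(30)), P = mk(runif(30))))
    tb <- overlap_table(res3, "LS", c("E", "G", "P"), k = 10)
    expect_lte(tb$EGP, min(tb$EG, tb$EP, tb$GP))
    expect_lte(tb$EG, min(tb$E, tb$G))
    expect_lte(tb$EP, min(tb$E, tb$P))
    expect_lte(tb$GP, min(tb$G, tb$P))
  }
})

test_that("published per-trait overlap counts aggregate to block totals", {
  counts <- holstein_overlap_counts()
  expect_equal(nrow(counts), 31)
  tot <- overlap_block_totals(counts)
  phr <- tot[tot$block == "production_health_reproduction", ]
  conf <- tot[tot$block == "conformation", ]
  expect_equal(unname(unlist(phr[c("E", "G", "P", "EG", "EP", "GP", "EGP")])),
               c(96, 97, 44, 36, 35, 34, 28))
  expect_equal(unname(unlist(conf[c("E", "G", "P", "EG", "EP", "GP", "EGP")])),
               c(174, 267, 51, 60, 31, 17, 13))
  # subset monotonicity holds row-wise in the published table too
  expect_true(all(counts$EGP <= pmin(counts$EG, counts$EP, counts$GP)))
})

test_that("significance threshold is Bonferroni with explicit override", {
  expect_equal(significance_threshold(0.05, 10), 0.005)
  expect_equal(significance_threshold(0.05, 1), 0.05)
  expect_equal(significance_threshold(0.05, 45878), 0.05 / 45878,
               tolerance = 1e-12)
  expect_equal(significance_threshold(0.05, 10, override = 10^-6.4),
               10^-6.4)
  expect_error(significance_threshold(1.5, 10), "alpha")
})

test_that("manhattan export is ordered, flagged inclusively, and counted", {
  p <- c(1, 0.5, 10^-6.4, NA, 1e-8)
  r <- fake_results(p, chr = c("2", "1", "X", "1", "1"),
                    pos = c(10L, 30L, 5L, 2L, 20L))
  out <- manhattan_export(r, threshold = 10^-6.4)
  expect_equal(attr(out, "n_missing"), 1)
  expect_equal(nrow(out), 4)
  # ordering: chromosome 1 before 2 before X
  expect_equal(out$chromosome, c("1", "1", "2", "X"))
  expect_equal(out$neg_log10_p[out$snp_id == "s001"], 0)
  # p equal to the threshold is significant (inclusive rule)
  expect_true(out$significant[out$snp_id == "s003"])
  expect_false(out$significant[out$snp_id == "s002"])
})
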