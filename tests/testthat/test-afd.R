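test_that("favorable allele follows the trait-direction sign rule", {
  expect_equal(favorable_allele(0.5, "high"), 1L)
  expect_equal(favorable_allele(-0.5, "high"), 2L)
  # positive estimate on a low-favorable trait: the other allele wins
  expect_equal(favorable_allele(0.5, "low"), 2L)
  expect_equal(favorable_allele(-0.5, "low"), 1L)
  expect_true(is.na(favorable_allele(0, "high")))
  expect_error(favorable_allele(1, "sideways"), "direction")
})

test_that("cluster frequencies match direct counting", {
  # elite = {AA, AA}, average = {GG, GG} -> (1, 0) for allele A
  sc <- synthetic_cluster_genotypes(1, 0, n_per_cluster = 2)
  cf <- cluster_frequencies(sc$genotypes, sc$clusters)
  expect_equal(cf$freq_elite, 1)
  expect_equal(cf$freq_average, 0)

  # one heterozygote only -> 0.5
  sc2 <- synthetic_cluster_genotypes(0.5, 0.5, n_per_cluster = 1)
  cf2 <- cluster_frequencies(sc2$genotypes, sc2$clusters)
  expect_equal(cf2$freq_elite, 0.5)

  # random fixture vs per-individual tallying oracle
  g <- random_genotypes(20, 15, seed = 167, miss_rate = 0.1)
  ids <- g$individual_ids
  lab <- setNames(rep(c("elite", "average"), c(6, 14)), ids)
  clusters <- structure(list(labels = lab, elite_ids = ids[1:6],
                             average_ids = ids[7:20], method = "fixed"),
                        class = "cluster_assignment")
  cf3 <- cluster_frequencies(g, clusters)
  d <- dosage(g)
  for (j in c(1, 8, 15)) {
    de <- d[1:6, j]
    expect_equal(cf3$freq_elite[j],
                 sum(de, na.rm = TRUE) / (2 * sum(!is.na(de))))
  }
})

test_that("AFD arithmetic reproduces reported frequency pairs", {
  ref <- holstein_afd_examples()
  for (i in seq_len(nrow(ref))) {
    sc <- synthetic_cluster_genotypes(ref$freq_elite[i],
                                      ref$freq_average[i])
    afd <- afd_table(sc$genotypes, sc$clusters)$table$afd
    expect_equal(round(afd, 2), ref$afd_reported[i])
  }
  # identical frequencies give AFD 0
  sc0 <- synthetic_cluster_genotypes(0.3, 0.3)
  expect_equal(afd_table(sc0$genotypes, sc0$clusters)$table$afd, 0)
})

test_that("AFD is invariant to allele designation and cluster order", {
  g <- random_genotypes(30, 25, seed = 173)
  ids <- g$individual_ids
  mk <- function(el, av) structure(
    list(labels = setNames(ifelse(ids %in% el, "elite", "average"), ids),
         elite_ids = el, average_ids = av, method = "fixed"),
    class = "cluster_assignment")
  cl <- mk(ids[1:10], ids[11:30])
  t1 <- afd_table(g, cl)$table
  # allele-2 frequencies give the same absolute difference
  cf <- cluster_frequencies(g, cl, allele = 2L)
  expect_equal(t1$afd, abs(cf$freq_elite - cf$freq_average))
  # swapped clusters give the same AFD
  t2 <- afd_table(g, mk(ids[11:30], ids[1:10]))$table
  expect_equal(t1$afd, t2$afd)
})

test_that("planted divergent loci dominate the AFD ranking", {
  hit <- sapply(1:20, function(s) {
    cfg <- sim_elite_confounded_config(n_snps = 120, n_planted = 5,
                                       seed = 300 + s)
    pop <- simulate_population(cfg)
    cl <- assign_clusters(
      classical_mds(ibs_similarity(pop$genotypes), 2,
                    elite_ids = pop$elite_ids),
      known_elite_family = pop$elite_sire, families = pop$families)
    tab <- afd_table(pop$genotypes, cl)$table
    all(tab$rank[match(pop$truth$snp_id, tab$snp_id)] <= 5)
  })
  expect_gte(mean(hit), 0.9)
})

test_that("threshold counts are computed over requested cutoffs", {
  g <- random_genotypes(40, 30, seed = 179)
  ids <- g$individual_ids
  cl <- structure(list(labels = setNames(rep(c("elite", "average"),
                                             c(15, 25)), ids),
                       elite_ids = ids[1:15], average_ids = ids[16:40],
                       method = "fixed"), class = "cluster_assignment")
  out <- afd_table(g, cl, thresholds = c(0.1, 0.2))
  expect_equal(unname(out$counts[1]), sum(out$table$afd >= 0.1))
  expect_equal(unname(out$counts[2]), sum(out$table$afd >= 0.2))
})
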