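test_that("simulation is seed-deterministic and conserves structure", {
  cfg <- sim_config(n_individuals = 120, n_sires = 12,
                    elite_family_size = 30, n_autosomes = 2,
                    include_x = TRUE, n_snps_per_chr = 40,
                    trait_catalog = default_trait_catalog()[1:3, ],
                    seed = 42)
  pop1 <- simulate_population(cfg)
  pop2 <- simulate_population(cfg)
  expect_identical(pop1, pop2)

  g <- pop1$genotypes
  expect_equal(sum(family_sizes(pop1$families)), 120)
  expect_equal(length(pop1$elite_ids), 30)
  # every individual has exactly one sire label
  expect_true(all(g$individual_ids %in% names(pop1$families$sire_of)))
  # dosages are complete and in {0,1,2}
  d <- dosage(g)
  expect_false(anyNA(d))
  expect_true(all(d %in% 0:2))
  # allele labels valid and distinct per SNP
  expect_true(all(g$alleles[, 1] != g$alleles[, 2]))
})

test_that("default study emulation has families from 1 to 160", {
  cfg <- sim_config(n_snps_per_chr = 2, n_autosomes = 2, include_x = FALSE,
                    trait_catalog = default_trait_catalog()[1, ], seed = 1)
  expect_equal(cfg$n_individuals, 1654L)
  expect_equal(cfg$n_sires, 355L)
  sz <- cfg$family_sizes
  expect_equal(sum(sz), 1654L)
  expect_equal(max(sz), 160L)
  expect_equal(min(sz), 1L)
  pop <- simulate_population(cfg)
  expect_equal(max(family_sizes(pop$families)), 160L)
})

test_that("single sire without recombination shares one X haplotype", {
  cfg <- sim_config(n_individuals = 25, n_sires = 1, elite_family_size = 25,
                    n_autosomes = 0, include_x = TRUE, n_snps_per_chr = 60,
                    recombination_rate = 0,
                    trait_catalog = default_trait_catalog()[1, ], seed = 7)
  pop <- simulate_population(cfg)
  a1 <- pop$genotypes$a1     # paternal copy
  expect_true(all(apply(a1, 2, function(col) length(unique(col)) == 1)))
})

test_that("all daughters of a sire share the sire-derived X haplotype", {
  cfg <- sim_mds_config(n_autosomes = 1, snps_per_chr = 50, seed = 11)
  pop <- simulate_population(cfg)
  g <- pop$genotypes
  xcols <- g$chromosome == "X"
  for (blk in pop$families$family_blocks[1:10]) {
    pat <- g$a1[blk, xcols, drop = FALSE]
    expect_true(all(apply(pat, 2, function(col) length(unique(col)) == 1)))
  }
})

test_that("planted loci realize the designated frequency gap", {
  # 200 elite + 2000 average, planted 0.9 vs 0.1: realized gap near 0.8
  planted <- data.frame(chr = "1", index = 1, elite_freq = 0.9,
                        average_freq = 0.1, effect = 0, trait = "MY")
  cfg <- sim_config(n_individuals = 2200, n_sires = 201,
                    elite_family_size = 200,
                    family_sizes = c(200L, rep(10L, 200)),
                    n_autosomes = 1, include_x = FALSE,
                    n_snps_per_chr = 5, planted_loci = planted,
                    trait_catalog = default_trait_catalog()[1, ], seed = 5)
  pop <- simulate_population(cfg)
  gap <- pop$truth$elite_freq - pop$truth$average_freq
  expect_lt(abs(gap - 0.8), 0.06)
  # independent frequency-count oracle
  d <- dosage(pop$genotypes[, pop$truth$snp_id])
  fe <- sum(d[pop$elite_ids, 1]) / (2 * length(pop$elite_ids))
  avg <- setdiff(pop$genotypes$individual_ids, pop$elite_ids)
  fa <- sum(d[avg, 1]) / (2 * length(avg))
  expect_equal(pop$truth$elite_freq, fe)
  expect_equal(pop$truth$average_freq, fa)
})

test_that("average-cluster frequencies converge to base frequencies", {
  cfg <- sim_null_config(n_families = 150, family_size = 10,
                         n_snps = 200, seed = 13)
  pop <- simulate_population(cfg)
  p_hat <- allele_freq(pop$genotypes)
  # binomial bound 4*sqrt(p(1-p)/2n) around the realized mean; the base
  # draw itself is random so compare against a wide envelope
  expect_true(all(p_hat > 0.01 & p_hat < 0.99))
  expect_lt(abs(mean(p_hat) - 0.5), 0.03)
})

test_that("phenotype model degenerates and recovers correctly", {
  base <- list(n_individuals = 40, n_sires = 4, elite_family_size = 10,
               family_sizes = rep(10L, 4), n_autosomes = 1,
               include_x = FALSE, n_snps_per_chr = 3,
               trait_catalog = default_trait_catalog()[1, ])
  # zero variances, no loci: all phenotypes equal mu
  cfg0 <- do.call(sim_config, c(base, list(sigma_f2 = 0, sigma_e2 = 0,
                                           mu = 2.5, seed = 3)))
  pop0 <- simulate_population(cfg0)
  expect_equal(pop0$phenotypes$MY, rep(2.5, 40))

  # one causal locus, noiseless: dosage-2 minus dosage-0 equals 2a
  planted <- data.frame(chr = "1", index = 2, elite_freq = 0.5,
                        average_freq = 0.5, effect = 1.7, trait = "MY")
  cfg1 <- do.call(sim_config, c(base, list(sigma_f2 = 0, sigma_e2 = 0,
                                           planted_loci = planted,
                                           seed = 3)))
  pop1 <- simulate_population(cfg1)
  d <- dosage(pop1$genotypes)[, 2]
  y <- pop1$phenotypes$MY
  expect_equal(mean(y[d == 2]) - mean(y[d == 0]), 2 * 1.7)

  # low-favorable trait: favorable allele decreases the value
  cat_low <- data.frame(trait = "SCS", name = "somatic cell score",
                        direction = "low", block = "x")
  planted$trait <- "SCS"
  cfg2 <- do.call(sim_config, c(base[setdiff(names(base), "trait_catalog")],
                                list(trait_catalog = cat_low,
                                     sigma_f2 = 0, sigma_e2 = 0,
                                     planted_loci = planted, seed = 3)))
  pop2 <- simulate_population(cfg2)
  d2 <- dosage(pop2$genotypes)[, 2]
  y2 <- pop2$phenotypes$SCS
  expect_equal(mean(y2[d2 == 2]) - mean(y2[d2 == 0]), -2 * 1.7)
})

test_that("intraclass correlation of simulated phenotypes matches rho", {
  cfg <- sim_null_config(n_families = 500, family_size = 10, n_snps = 2,
                         seed = 17)
  pop <- simulate_population(cfg)
  fam <- pop$families$sire_of[pop$phenotypes$id]
  icc <- anova_icc(pop$phenotypes$MY, fam)
  expect_lt(abs(icc - 0.25), 0.03)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_individuals = 10, n_sires = 2,
                          elite_family_size = 5,
                          family_sizes = c(5L, 4L)), "sum")
  expect_error(sim_config(planted_loci = data.frame(
    chr = "1", index = 1e7, elite_freq = 0.9, average_freq = 0.1,
    effect = 1, trait = "MY")), "out of range")
  expect_error(sim_config(n_autosomes = 1, include_x = FALSE,
                          n_snps_per_chr = 5,
                          planted_loci = data.frame(
                            chr = "1", index = 1, elite_freq = 0.9,
                            average_freq = 0.1, effect = 1,
                            trait = "NOT_A_TRAIT")), "absent")
})
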