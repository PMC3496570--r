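#' Simulation configuration for a half-sib dairy population
#'
#' Defines the conditions of a forward simulation of a genotyped cow
#' population made of paternal half-sib families, one of which is a large
#' "elite" family whose sire carries, at planted loci, alleles that are
#' rare in the rest of the population. Defaults emulate a contemporary
#' U.S. Holstein association sample: 1,654 cows from 355 sires with family
#' sizes from 1 to 160, a 160-daughter elite family, 45,878 array SNPs on
#' 29 autosomes plus X, and phenotypes with a family variance component
#' (sigma_f2 = 1, sigma_e2 = 3, intraclass correlation 0.25).
#'
#' All simulated individuals are cows, so the X chromosome is diploid.
#' Daughters receive one recombined paternal autosome haplotype (Poisson
#' crossover count, uniform breakpoints) and one maternal haplotype drawn
#' site-wise from the population allele frequencies; dams are unrelated.
#' The sire's X is transmitted to every daughter without recombination
#' outside the pseudo-autosomal region (\code{par_boundary_bp}, default 0 =
#' no pseudo-autosomal sites).
#'
#' @param n_individuals total number of cows.
#' @param n_sires number of half-sib families.
#' @param elite_family_size number of daughters of the elite sire.
#' @param family_sizes optional explicit vector of family sizes (elite
#'   family first); must sum to \code{n_individuals}. When \code{NULL} a
#'   deterministic skewed allocation with minimum size 1 is used.
#' @param n_autosomes number of autosomes.
#' @param include_x simulate an X chromosome.
#' @param n_snps_per_chr SNPs per chromosome: a scalar, or a named vector
#'   over chromosome labels. Default spreads 45,878 SNPs over the genome.
#' @param base_freq_range allele-1 frequencies are drawn uniformly from
#'   this interval (array-ascertained common variants).
#' @param planted_loci \code{NULL} or a data.frame with columns \code{chr},
#'   \code{index} (SNP index within the chromosome), \code{elite_freq},
#'   \code{average_freq}, \code{effect} (trait units per favorable allele)
#'   and \code{trait}.
#' @param sigma_f2,sigma_e2 family and residual phenotype variances
#'   (trait units squared).
#' @param mu phenotype grand mean.
#' @param elite_mean_shift additional phenotype shift (trait units) of the
#'   elite family, applied in each trait's favorable direction; models
#'   polygenic merit of the elite sire beyond the typed loci.
#' @param trait_catalog data.frame with columns \code{trait} and
#'   \code{direction} ("high"/"low"); default \code{\link{default_trait_catalog}}.
#' @param recombination_rate expected crossovers per autosome per meiosis.
#' @param par_boundary_bp X positions at or below this bound are treated as
#'   pseudo-autosomal (paternal allele drawn from either sire X-arm copy).
#' @param seed integer seed; identical configs give bit-identical output.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 1654L,
                       n_sires = 355L,
                       elite_family_size = 160L,
                       family_sizes = NULL,
                       n_autosomes = 29L,
                       include_x = TRUE,
                       n_snps_per_chr = NULL,
                       base_freq_range = c(0.05, 0.95),
                       planted_loci = NULL,
                       sigma_f2 = 1,
                       sigma_e2 = 3,
                       mu = 0,
                       elite_mean_shift = 0,
                       trait_catalog = default_trait_catalog(),
                       recombination_rate = 1,
                       par_boundary_bp = 0,
                       seed = 1L) {
  chroms <- c(if (n_autosomes > 0) as.character(seq_len(n_autosomes)),
              if (include_x) "X")
  if (length(chroms) == 0) stop("no chromosomes requested")
  if (is.null(n_snps_per_chr)) {
    # 45,878 markers spread over the genome
    base <- 45878L %/% length(chroms)
    n_snps_per_chr <- stats::setNames(rep(base, length(chroms)), chroms)
    n_snps_per_chr[length(chroms)] <-
      n_snps_per_chr[length(chroms)] + 45878L - sum(n_snps_per_chr)
  } else if (length(n_snps_per_chr) == 1 && is.null(names(n_snps_per_chr))) {
    n_snps_per_chr <- stats::setNames(rep(as.integer(n_snps_per_chr),
                                          length(chroms)), chroms)
  } else {
    if (!all(chroms %in% names(n_snps_per_chr)))
      stop("n_snps_per_chr must name every chromosome")
    n_snps_per_chr <- n_snps_per_chr[chroms]
  }
  if (is.null(family_sizes)) {
    family_sizes <- default_family_sizes(n_individuals, n_sires,
                                         elite_family_size)
  }
  if (sum(family_sizes) != n_individuals)
    stop("family sizes must sum to n_individuals")
  if (length(family_sizes) != n_sires)
    stop("family_sizes must have one entry per sire")
  if (elite_family_size > n_individuals)
    stop("elite_family_size exceeds n_individuals")
  stopifnot(sigma_f2 >= 0, sigma_e2 >= 0,
            base_freq_range[1] > 0, base_freq_range[2] < 1)
  if (!is.null(planted_loci)) {
    need <- c("chr", "index", "elite_freq", "average_freq", "effect", "trait")
    stopifnot(all(need %in% names(planted_loci)))
    planted_loci$chr <- as.character(planted_loci$chr)
    if (!all(planted_loci$chr %in% chroms))
      stop("planted locus on absent chromosome")
    bad <- planted_loci$index < 1 |
      planted_loci$index > n_snps_per_chr[planted_loci$chr]
    if (any(bad)) stop("planted locus index out of range")
    if (any(planted_loci$elite_freq <= 0 | planted_loci$elite_freq >= 1 |
            planted_loci$average_freq <= 0 | planted_loci$average_freq >= 1))
      stop("planted frequencies must lie in (0,1)")
    if (!all(planted_loci$trait %in% trait_catalog$trait))
      stop("planted locus refers to a trait absent from trait_catalog")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_sires = as.integer(n_sires),
                 elite_family_size = as.integer(elite_family_size),
                 family_sizes = as.integer(family_sizes),
                 chromosomes = chroms,
                 n_snps_per_chr = as.integer(n_snps_per_chr) |>
                   stats::setNames(chroms),
                 base_freq_range = base_freq_range,
                 planted_loci = planted_loci,
                 sigma_f2 = sigma_f2, sigma_e2 = sigma_e2, mu = mu,
                 elite_mean_shift = elite_mean_shift,
                 trait_catalog = trait_catalog,
                 recombination_rate = recombination_rate,
                 par_boundary_bp = par_boundary_bp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Deterministic skewed family-size allocation
#'
#' One family of \code{elite_size}, the rest a right-skewed allocation with
#' minimum size 1, mimicking the long tail of daughters-per-sire counts in
#' progeny-tested dairy populations.
#'
#' @param n total individuals; @param n_sires number of families;
#' @param elite_size size of the first (elite) family.
#' @return integer vector of length \code{n_sires} summing to \code{n}.
#' @export
default_family_sizes <- function(n, n_sires, elite_size) {
  k <- n_sires - 1L
  r <- n - elite_size
  if (k == 0L) return(as.integer(elite_size))
  if (r < k) stop("cannot give every sire at least one daughter")
  w <- (seq_len(k))^(-0.85)
  extra <- r - k
  alloc <- floor(extra * w / sum(w))
  short <- extra - sum(alloc)
  if (short > 0) alloc[seq_len(short)] <- alloc[seq_len(short)] + 1L
  c(elite_size, 1L + alloc) |> as.integer()
}

#' Simulate a half-sib population
#'
#' Draws sire haplotypes from the base allele frequencies, overrides the
#' elite sire's haplotypes at planted loci so the elite family realizes the
#' designated elite allele frequencies, and builds each daughter from one
#' recombined paternal haplotype plus one maternal haplotype drawn
#' site-wise from the base (planted loci: average-cluster) frequencies.
#' Daughters of a sire share his X haplotype identically outside the
#' pseudo-autosomal region. Phenotypes are generated by
#' \code{\link{simulate_phenotypes}}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list of class \code{sim_population} with elements
#'   \code{genotypes} (\code{\link{genotype_matrix}}), \code{families}
#'   (\code{\link{family_structure}}), \code{phenotypes} (data.frame,
#'   individual x trait), \code{truth} (realized frequencies and effects at
#'   planted loci), \code{elite_ids}, \code{elite_sire} and
#'   \code{sire_haplotypes}.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  sizes <- config$family_sizes
  sire_ids <- sprintf("sire%03d", seq_along(sizes))
  ids <- sprintf("cow%05d", seq_len(n))
  sire_of <- stats::setNames(rep(sire_ids, sizes), ids)
  families <- family_structure(sire_of)
  elite_sire <- sire_ids[1]
  elite_ids <- ids[seq_len(sizes[1])]
  fam_first <- cumsum(c(1L, sizes[-length(sizes)]))

  acgt <- c("A", "C", "G", "T")
  chr_all <- character(0); pos_all <- integer(0); snp_all <- character(0)
  a1 <- matrix(NA_integer_, n, 0); a2 <- matrix(NA_integer_, n, 0)
  alleles <- matrix(character(0), 0, 2)
  sire_haps <- list()
  truth_rows <- list()

  for (chr in config$chromosomes) {
    m <- config$n_snps_per_chr[[chr]]
    pos <- as.integer(seq_len(m)) * 50000L
    is_x <- identical(chr, "X")
    p <- stats::runif(m, config$base_freq_range[1], config$base_freq_range[2])
    pl <- config$planted_loci
    pl <- if (is.null(pl)) NULL else pl[pl$chr == chr, , drop = FALSE]
    if (!is.null(pl) && nrow(pl) > 0) p[pl$index] <- pl$average_freq

    # per-SNP allele labels, alphabetical so allele 1 sorts first
    lab <- t(vapply(seq_len(m), function(i) sort(sample(acgt, 2)), c("", "")))

    ns <- length(sizes)
    if (is_x) {
      hapX <- matrix(stats::rbinom(ns * m, 1, rep(p, each = ns)), ns, m)
      hapX2 <- matrix(stats::rbinom(ns * m, 1, rep(p, each = ns)), ns, m)
      q_elite <- p
      if (!is.null(pl) && nrow(pl) > 0) {
        carry <- as.integer(pl$elite_freq >= 0.5)
        hapX[1, pl$index] <- carry
        q_elite[pl$index] <- pmin(1, pmax(0, 2 * pl$elite_freq - carry))
      }
      par_sites <- pos <= config$par_boundary_bp
      pat <- matrix(0L, n, m)
      for (f in seq_len(ns)) {
        rows <- fam_first[f] + seq_len(sizes[f]) - 1L
        pat[rows, ] <- matrix(hapX[f, ], sizes[f], m, byrow = TRUE)
        if (any(par_sites)) {
          # within the pseudo-autosomal segment either sire arm may be passed
          pick2 <- stats::runif(sizes[f]) < 0.5
          if (any(pick2))
            pat[rows[pick2], par_sites] <-
              matrix(hapX2[f, par_sites], sum(pick2), sum(par_sites),
                     byrow = TRUE)
        }
      }
      sire_haps[[chr]] <- list(hap = hapX, par_alt = hapX2)
    } else {
      hapA <- matrix(stats::rbinom(ns * m, 1, rep(p, each = ns)), ns, m)
      hapB <- matrix(stats::rbinom(ns * m, 1, rep(p, each = ns)), ns, m)
      q_elite <- p
      if (!is.null(pl) && nrow(pl) > 0) {
        k <- pmin(2L, pmax(0L, as.integer(round(2 * pl$elite_freq))))
        hapA[1, pl$index] <- as.integer(k >= 1)
        hapB[1, pl$index] <- as.integer(k == 2)
        q_elite[pl$index] <- pmin(1, pmax(0, 2 * pl$elite_freq - k / 2))
      }
      pat <- matrix(0L, n, m)
      for (f in seq_len(ns)) {
        rows <- fam_first[f] + seq_len(sizes[f]) - 1L
        for (d in rows) {
          ncx <- stats::rpois(1, config$recombination_rate)
          start <- stats::rbinom(1, 1, 0.5)
          if (ncx == 0) {
            use_b <- start == 1
            pat[d, ] <- if (use_b) hapB[f, ] else hapA[f, ]
          } else {
            bp <- sort(stats::runif(ncx, 0, m))
            seg <- (start + findInterval(seq_len(m) - 0.5, bp)) %% 2
            pat[d, ] <- ifelse(seg == 0, hapA[f, ], hapB[f, ])
          }
        }
      }
      sire_haps[[chr]] <- list(hapA = hapA, hapB = hapB)
    }

    # maternal haplotypes: unrelated dams drawn from population frequencies
    mat <- matrix(0L, n, m)
    for (f in seq_len(ns)) {
      rows <- fam_first[f] + seq_len(sizes[f]) - 1L
      q <- if (f == 1L) q_elite else p
      mat[rows, ] <- matrix(stats::rbinom(sizes[f] * m, 1,
                                          rep(q, each = sizes[f])),
                            sizes[f], m)
    }

    snp <- sprintf("snp-%s-%05d", chr, seq_len(m))
    chr_all <- c(chr_all, rep(chr, m)); pos_all <- c(pos_all, pos)
    snp_all <- c(snp_all, snp)
    alleles <- rbind(alleles, lab)
    a1 <- cbind(a1, 2L - pat)   # carrying allele 1 -> index 1
    a2 <- cbind(a2, 2L - mat)

    if (!is.null(pl) && nrow(pl) > 0) {
      truth_rows[[chr]] <- data.frame(
        snp_id = snp[pl$index], chromosome = chr, position = pos[pl$index],
        trait = pl$trait, effect = pl$effect,
        target_elite_freq = pl$elite_freq,
        target_average_freq = pl$average_freq,
        favorable_allele = lab[pl$index, 1],
        stringsAsFactors = FALSE)
    }
  }

  g <- genotype_matrix(ids, snp_all, chr_all, pos_all, alleles, a1, a2)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  if (!is.null(truth)) {
    avg_ids <- setdiff(ids, elite_ids)
    gt <- g[, truth$snp_id]
    truth$elite_freq <- allele_freq(gt, elite_ids)
    truth$average_freq <- allele_freq(gt, avg_ids)
    rownames(truth) <- NULL
  }
  pop <- structure(list(genotypes = g, families = families,
                        phenotypes = NULL, truth = truth,
                        elite_ids = elite_ids, elite_sire = elite_sire,
                        sire_haplotypes = sire_haps, config = config),
                   class = "sim_population")
  pop$phenotypes <- simulate_phenotypes(pop, config)
  pop
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sim_population: %d cows, %d families (elite %d), %d SNPs, %d trait(s)\n",
              n_individuals(x$genotypes), length(x$families$family_blocks),
              length(x$elite_ids), n_snps(x$genotypes),
              ncol(x$phenotypes) - 1L))
  invisible(x)
}

#' Simulate phenotypes for a half-sib population
#'
#' For every trait in the catalog, \code{y = mu + sum(dosage * effect * dir)
#' + f + e} where \code{f} is a Gaussian family effect with variance
#' \code{sigma_f2}, \code{e} Gaussian residual with variance \code{sigma_e2},
#' the sum runs over the planted loci affecting the trait, and
#' \code{dir = +1} for high-favorable and \code{-1} for low-favorable traits
#' (so favorable alleles lower e.g. somatic cell score). Elite-family
#' members additionally receive \code{elite_mean_shift * dir}.
#'
#' @param pop a \code{sim_population} built from \code{config}.
#' @param config the matching \code{\link{sim_config}}.
#' @param seed seed for the phenotype draws; default derived from
#'   \code{config$seed} so that standalone calls match the phenotypes
#'   embedded by \code{\link{simulate_population}}.
#' @return data.frame: column \code{id} plus one column per trait.
#' @export
simulate_phenotypes <- function(pop, config, seed = config$seed + 500009L) {
  set.seed(seed)
  g <- pop$genotypes
  ids <- g$individual_ids
  n <- length(ids)
  fam <- factor(pop$families$sire_of[ids],
                levels = unique(unname(pop$families$sire_of[ids])))
  elite <- ids %in% pop$elite_ids
  cat_tr <- config$trait_catalog
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  truth <- pop$truth
  for (i in seq_len(nrow(cat_tr))) {
    tr <- cat_tr$trait[i]
    dir <- if (identical(cat_tr$direction[i], "low")) -1 else 1
    f <- stats::rnorm(nlevels(fam), 0, sqrt(config$sigma_f2))
    e <- stats::rnorm(n, 0, sqrt(config$sigma_e2))
    y <- config$mu + f[as.integer(fam)] + e
    if (!is.null(truth)) {
      hits <- which(truth$trait == tr)
      for (h in hits) {
        d <- dosage(g[, truth$snp_id[h]])[, 1]
        y <- y + d * truth$effect[h] * dir
      }
    }
    y <- y + ifelse(elite, config$elite_mean_shift * dir, 0)
    out[[tr]] <- y
  }
  out
}

#' Simulate a polygenic trait from observed genotypes
#'
#' Every polymorphic SNP receives an i.i.d. normal effect on the
#' frequency-standardized dosage scale; the genetic values are rescaled to
#' an empirical variance of \code{h2} and residuals drawn with variance
#' \code{1 - h2}, so the realized narrow-sense heritability is \code{h2}.
#' Useful for checking variance-component recovery with a genomic kinship.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param h2 target heritability in (0,1).
#' @param seed integer seed.
#' @return numeric phenotype vector named by individual id.
#' @export
simulate_polygenic_trait <- function(g, h2, seed = 1L) {
  stopifnot(h2 > 0, h2 < 1)
  set.seed(seed)
  z <- standardized_dosage(g)
  b <- stats::rnorm(ncol(z), 0, 1 / sqrt(ncol(z)))
  u <- drop(z %*% b)
  u <- u * sqrt(h2 / stats::var(u))
  y <- u + stats::rnorm(nrow(z), 0, sqrt(1 - h2))
  stats::setNames(y, g$individual_ids)
}
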