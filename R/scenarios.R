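#' Preset simulation scenarios
#'
#' Fixed study conditions used throughout the package's tests and
#' replication script. All presets share the contemporary-cow population
#' shape (1,654 cows, 355 sires, one 160-daughter elite family) and differ
#' in which stratification mechanism they switch on; the marker count per
#' scenario is scaled to what each check needs.
#'
#' \describe{
#'   \item{\code{sim_null_config}}{Pure intraclass-correlation null:
#'     balanced families (default 100 x 10), sigma_f2 = 1, sigma_e2 = 3
#'     (rho = 0.25), no planted loci, no elite shift. Used for type-I
#'     error and variance-component recovery.}
#'   \item{\code{sim_cluster_confounded_config}}{Elite-cluster confounding
#'     in isolation: sigma_f2 = 0 so the elite family's mean shift
#'     (2 trait SD) is the only phenotype structure, and the shared elite
#'     sire genome the only genotype structure. The single stratification
#'     axis is then representable by principal components, which is the
#'     mechanism under test for PCA correction.}
#'   \item{\code{sim_elite_confounded_config}}{The full mechanism: family
#'     variance (sigma_f2 = 1, sigma_e2 = 3) plus an elite mean shift plus
#'     planted loci with high elite / low average frequency (default 20
#'     loci at 0.9 vs 0.1, additive effect 0.25 per favorable allele).
#'     Correlation-based corrections absorb the elite family as a family /
#'     kinship effect here.}
#'   \item{\code{sim_mds_config}}{Genome-shaped scenario for
#'     stratification analysis: 5 autosomes plus X (80 SNPs each), no
#'     phenotype confounding. The X chromosome carries the shared sire
#'     haplotype signal. Simulated markers carry no linkage
#'     disequilibrium, so each is fully informative; the per-chromosome
#'     count is scaled to the LD-limited effective marker count of a real
#'     array chromosome — above it, cluster purity saturates at 1 on
#'     every chromosome and the X-versus-autosome contrast has no room to
#'     appear.}
#' }
#'
#' @param n_families,family_size shape of the balanced null population.
#' @param n_snps markers on the single simulated autosome.
#' @param seed simulation seed.
#' @return a \code{\link{sim_config}}.
#' @name scenarios
NULL

single_trait <- function() {
  cat_tr <- default_trait_catalog()
  cat_tr[cat_tr$trait == "MY", , drop = FALSE]
}

#' @rdname scenarios
#' @export
sim_null_config <- function(n_families = 100, family_size = 10,
                            n_snps = 2000, seed = 1L) {
  sim_config(n_individuals = n_families * family_size,
             n_sires = n_families,
             elite_family_size = family_size,
             family_sizes = rep(family_size, n_families),
             n_autosomes = 1L, include_x = FALSE,
             n_snps_per_chr = n_snps,
             sigma_f2 = 1, sigma_e2 = 3,
             trait_catalog = single_trait(),
             seed = seed)
}

#' @rdname scenarios
#' @export
sim_cluster_confounded_config <- function(n_snps = 2000, seed = 1L) {
  sim_config(n_autosomes = 1L, include_x = FALSE,
             n_snps_per_chr = n_snps,
             sigma_f2 = 0, sigma_e2 = 1,
             elite_mean_shift = 2,
             trait_catalog = single_trait(),
             seed = seed)
}

#' @rdname scenarios
#' @param n_planted planted divergent loci (evenly spaced).
#' @param elite_freq,average_freq planted favorable-allele frequencies.
#' @param effect additive effect per favorable allele (trait units).
#' @param elite_mean_shift elite polygenic shift (trait units).
#' @export
sim_elite_confounded_config <- function(n_snps = 500, n_planted = 20,
                                        elite_freq = 0.9,
                                        average_freq = 0.1,
                                        effect = 0.25,
                                        elite_mean_shift = 2,
                                        seed = 1L) {
  idx <- round(seq(1, n_snps, length.out = n_planted + 2))[-c(1, n_planted + 2)]
  planted <- data.frame(chr = "1", index = idx,
                        elite_freq = elite_freq,
                        average_freq = average_freq,
                        effect = effect, trait = "MY",
                        stringsAsFactors = FALSE)
  sim_config(n_autosomes = 1L, include_x = FALSE,
             n_snps_per_chr = n_snps,
             planted_loci = planted,
             sigma_f2 = 1, sigma_e2 = 3,
             elite_mean_shift = elite_mean_shift,
             trait_catalog = single_trait(),
             seed = seed)
}

#' @rdname scenarios
#' @param n_autosomes autosome count; @param snps_per_chr markers per
#'   chromosome (autosomes and X alike).
#' @export
sim_mds_config <- function(n_autosomes = 5, snps_per_chr = 80, seed = 1L) {
  sim_config(n_autosomes = n_autosomes, include_x = TRUE,
             n_snps_per_chr = snps_per_chr,
             sigma_f2 = 1, sigma_e2 = 3,
             trait_catalog = single_trait(),
             seed = seed)
}

#' Published Holstein reference tables
#'
#' Small reference tables shipped with the package, transcribed from
#' published results on elite-versus-average stratification in a
#' 1,654-cow U.S. Holstein association sample. They are used to exercise
#' the package's AFD arithmetic and overlap accounting against externally
#' reported values.
#'
#' \code{holstein_afd_examples()}: five SNPs with reported
#' favorable-allele frequencies in the elite and average clusters and the
#' reported allele frequency difference.
#'
#' \code{holstein_overlap_counts()}: per-trait counts (31 traits) of the
#' top-100 uncorrected least-squares effects that also ranked in the
#' top 100 of EMMAX-IBS (E), GLS (G) and PCA (P) reanalyses, including
#' all intersection columns.
#'
#' @return a data.frame.
#' @export
holstein_afd_examples <- function() {
  utils::read.table(system.file("extdata", "holstein_afd_examples.tsv",
                                package = "dairygwas", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname holstein_afd_examples
#' @export
holstein_overlap_counts <- function() {
  utils::read.table(system.file("extdata", "holstein_top100_overlap.tsv",
                                package = "dairygwas", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Construct genotypes realizing given cluster allele frequencies
#'
#' Builds a synthetic one-SNP genotype matrix and matching cluster
#' assignment whose allele-1 counts reproduce the requested elite and
#' average frequencies exactly (frequencies must be multiples of
#' 1/(2 n) for the chosen cluster size). Used to feed reported frequency
#' pairs through the package's counting machinery.
#'
#' @param freq_elite,freq_average target allele-1 frequencies.
#' @param n_per_cluster individuals per cluster; 2*n_per_cluster must
#'   make both frequencies integral allele counts.
#' @return list with \code{genotypes} and \code{clusters}.
#' @export
synthetic_cluster_genotypes <- function(freq_elite, freq_average,
                                        n_per_cluster = 50) {
  n2 <- 2 * n_per_cluster
  ce <- freq_elite * n2
  ca <- freq_average * n2
  if (abs(ce - round(ce)) > 1e-9 || abs(ca - round(ca)) > 1e-9)
    stop("frequencies not representable with ", n_per_cluster,
         " individuals per cluster")
  fill <- function(count) {
    # spread 'count' copies of allele 1 over n_per_cluster diploid calls
    a <- c(rep(1L, count), rep(2L, n2 - count))
    cbind(a[seq_len(n_per_cluster)], a[n_per_cluster + seq_len(n_per_cluster)])
  }
  ge <- fill(round(ce)); ga <- fill(round(ca))
  ids <- c(sprintf("elite%03d", seq_len(n_per_cluster)),
           sprintf("avg%03d", seq_len(n_per_cluster)))
  g <- genotype_matrix(ids, "snp1", "1", 1L,
                       matrix(c("A", "G"), 1, 2),
                       a1 = matrix(c(ge[, 1], ga[, 1]), ncol = 1),
                       a2 = matrix(c(ge[, 2], ga[, 2]), ncol = 1))
  lab <- c(rep("elite", n_per_cluster), rep("average", n_per_cluster))
  names(lab) <- ids
  clusters <- structure(list(labels = lab,
                             elite_ids = ids[seq_len(n_per_cluster)],
                             average_ids = ids[n_per_cluster +
                                                 seq_len(n_per_cluster)],
                             method = "synthetic"),
                        class = "cluster_assignment")
  list(genotypes = g, clusters = clusters)
}
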