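#' Genotype matrix container
#'
#' Biallelic, diploid SNP calls for a set of individuals, stored as two
#' integer matrices of allele indexes (1 or 2, referring to the per-SNP
#' allele labels; \code{NA} = missing call) together with chromosome and
#' base-pair position metadata. Positions are 1-based (PLINK .map
#' convention); the X chromosome is labelled \code{"X"}.
#'
#' @param individual_ids character vector of unique individual ids (length n).
#' @param snp_ids character vector of unique SNP ids (length m).
#' @param chromosome per-SNP chromosome label, e.g. \code{"1"}..\code{"29"},
#'   \code{"X"}.
#' @param position per-SNP 1-based base-pair coordinate.
#' @param alleles m x 2 character matrix of allele labels (A/C/G/T); the
#'   second column may be \code{NA} for loci where only one allele was seen.
#' @param a1,a2 n x m integer matrices of allele indexes (1 or 2) for the
#'   two chromosome copies; \code{NA} for missing calls.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(individual_ids, snp_ids, chromosome, position,
                            alleles, a1, a2) {
  individual_ids <- as.character(individual_ids)
  snp_ids <- as.character(snp_ids)
  n <- length(individual_ids)
  m <- length(snp_ids)
  stopifnot(!anyDuplicated(individual_ids), !anyDuplicated(snp_ids),
            length(chromosome) == m, length(position) == m,
            is.matrix(alleles), nrow(alleles) == m, ncol(alleles) == 2,
            is.matrix(a1), is.matrix(a2),
            all(dim(a1) == c(n, m)), all(dim(a2) == c(n, m)))
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  ok <- is.na(a1) | a1 %in% c(1L, 2L)
  if (!all(ok)) stop("allele indexes must be 1, 2 or NA")
  ok <- is.na(a2) | a2 %in% c(1L, 2L)
  if (!all(ok)) stop("allele indexes must be 1, 2 or NA")
  # a call must be fully observed or fully missing
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing calls are not supported")
  dimnames(a1) <- dimnames(a2) <- list(individual_ids, snp_ids)
  structure(list(individual_ids = individual_ids,
                 snp_ids = snp_ids,
                 chromosome = as.character(chromosome),
                 position = as.integer(position),
                 alleles = alleles,
                 a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d chromosome(s))\n",
              n_individuals(x), n_snps(x), length(unique(x$chromosome))))
  invisible(x)
}

#' Number of individuals / SNPs
#' @param g a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_individuals <- function(g) length(g$individual_ids)

#' @rdname n_individuals
#' @export
n_snps <- function(g) length(g$snp_ids)

#' Subset a genotype matrix
#'
#' @param x a \code{genotype_matrix}.
#' @param i individual selector (indexes, ids or logical).
#' @param j SNP selector (indexes, ids or logical).
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$individual_ids)
  if (missing(j)) j <- seq_along(x$snp_ids)
  if (is.character(i)) i <- match(i, x$individual_ids)
  if (is.character(j)) j <- match(j, x$snp_ids)
  genotype_matrix(x$individual_ids[i], x$snp_ids[j],
                  x$chromosome[j], x$position[j],
                  x$alleles[j, , drop = FALSE],
                  x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE])
}

#' Allele dosage matrix
#'
#' Counts of a designated allele (by index into the per-SNP allele labels)
#' for every call; values 0, 1, 2 or \code{NA} for missing calls.
#'
#' @param g a \code{genotype_matrix}.
#' @param allele which allele to count: 1 (default) or 2.
#' @return integer matrix, individuals x SNPs.
#' @export
dosage <- function(g, allele = 1L) {
  (g$a1 == allele) + (g$a2 == allele)
}

#' Per-SNP allele-1 frequency
#'
#' Frequency of allele 1 over called genotypes only.
#'
#' @param g a \code{genotype_matrix}.
#' @param individuals optional individual subset (ids or indexes).
#' @return numeric vector, one frequency per SNP (\code{NaN} where no calls).
#' @export
allele_freq <- function(g, individuals = NULL) {
  d <- dosage(g)
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
}

#' Identify polymorphic SNPs
#'
#' A SNP is polymorphic if at least two distinct non-missing dosage values
#' (equivalently, both alleles) are observed.
#'
#' @param g a \code{genotype_matrix}.
#' @return logical vector over SNPs.
#' @export
is_polymorphic <- function(g) {
  p <- allele_freq(g)
  !is.na(p) & p > 0 & p < 1
}
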