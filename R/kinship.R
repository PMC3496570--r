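#' Frequency-standardized dosage matrix
#'
#' Allele-1 dosages centered by \code{2*p} and scaled by
#' \code{sqrt(2*p*(1-p))}, with \code{p} the sample allele-1 frequency.
#' Monomorphic SNPs are dropped; missing calls become 0 after centering
#' (mean imputation on the standardized scale).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return numeric matrix, individuals x polymorphic SNPs.
#' @export
standardized_dosage <- function(g) {
  keep <- is_polymorphic(g)
  if (!any(keep)) stop("all SNPs are monomorphic")
  d <- dosage(g[, keep])
  p <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  z <- sweep(d, 2, 2 * p, `-`)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  z[is.na(z)] <- 0
  z
}

kinship_matrix <- function(values, flavor) {
  structure(list(values = values, flavor = flavor), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix (%s): %d x %d\n", x$flavor,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Identity-by-state kinship
#'
#' The IBS similarity matrix (see \code{\link{ibs_similarity}}) used as a
#' relatedness matrix for the mixed model.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return a \code{kinship_matrix} (flavor "IBS").
#' @export
kinship_ibs <- function(g) {
  kinship_matrix(ibs_similarity(g), "IBS")
}

#' Balding-Nichols-style standardized kinship
#'
#' The allele-frequency-standardized genotype Gram matrix
#' \code{K = Z Z' / m} where \code{Z} is the
#' \code{\link{standardized_dosage}} matrix over the m polymorphic SNPs —
#' the construction used for the "BN" kinship option of mixed-model
#' association software.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return a \code{kinship_matrix} (flavor "BN") with attribute
#'   \code{n_snps_used}.
#' @export
kinship_bn <- function(g) {
  z <- standardized_dosage(g)
  k <- tcrossprod(z) / ncol(z)
  dimnames(k) <- list(g$individual_ids, g$individual_ids)
  out <- kinship_matrix(k, "BN")
  attr(out, "n_snps_used") <- ncol(z)
  out
}

#' Family-incidence kinship
#'
#' \code{K = Z Z'} with \code{Z} the 0/1 family incidence matrix:
#' \code{K[i,j] = 1} if i and j share a sire, else 0. Under this K the
#' mixed model \code{var(y) = K sigma_a2 + I sigma_e2} is exactly the
#' half-sib compound-symmetry covariance of the GLS model, which makes the
#' two association tests comparable on identical footing.
#'
#' @param families a \code{\link{family_structure}}.
#' @param ids optional individual ordering (default: family order).
#' @return a \code{kinship_matrix} (flavor "family").
#' @export
kinship_family <- function(families, ids = NULL) {
  if (is.null(ids)) ids <- unlist(families$family_blocks, use.names = FALSE)
  sire <- families$sire_of[ids]
  k <- outer(sire, sire, `==`) * 1
  dimnames(k) <- list(ids, ids)
  kinship_matrix(k, "family")
}

#' Write / read a kinship matrix
#'
#' Tab-delimited square matrix with individual-id header and rownames.
#'
#' @param k a \code{kinship_matrix}; @param path file path;
#' @param flavor flavor label to attach on read.
#' @export
write_kinship <- function(k, path) {
  utils::write.table(k$values, path, quote = FALSE, sep = "\t",
                     col.names = NA)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path, flavor = "file") {
  v <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  kinship_matrix(v, flavor)
}
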