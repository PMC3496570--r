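#' Principal components of the genotype matrix
#'
#' Computes the top principal components of the frequency-standardized
#' dosage matrix (see \code{\link{standardized_dosage}}; monomorphic SNPs
#' dropped, missing calls mean-imputed). Components are obtained from the
#' eigendecomposition of the individual-by-individual covariance
#' \code{Z Z'}, so the returned component vectors are orthonormal over
#' individuals; used as covariates they implement PCA stratification
#' correction (the study convention is the top 20).
#'
#' @param g a \code{\link{genotype_matrix}} with at least 2 polymorphic
#'   SNPs.
#' @param n_components number of components (must be < n individuals).
#' @return An object of class \code{pca_basis}: \code{vectors}
#'   (individuals x components, orthonormal columns, rows named by id),
#'   \code{explained_variance} (non-increasing eigenvalues of
#'   \code{Z Z' / m}), \code{proportion} and \code{n_components}.
#' @export
compute_pcs <- function(g, n_components = 20) {
  if (sum(is_polymorphic(g)) < 2) stop("need at least 2 polymorphic SNPs")
  if (n_components >= n_individuals(g))
    stop("n_components must be smaller than the number of individuals")
  z <- standardized_dosage(g)
  cv <- tcrossprod(z) / ncol(z)
  ek <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  vec <- ek$vectors[, keep, drop = FALSE]
  rownames(vec) <- g$individual_ids
  colnames(vec) <- paste0("PC", keep)
  structure(list(vectors = vec,
                 explained_variance = ek$values[keep],
                 proportion = ek$values[keep] / sum(pmax(ek$values, 0)),
                 n_components = n_components),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("pca_basis: %d components over %d individuals (top proportion %.3f)\n",
              x$n_components, nrow(x$vectors), x$proportion[1]))
  invisible(x)
}
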