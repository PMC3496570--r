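#' Identity-by-state similarity matrix
#'
#' For each pair of individuals, the mean over usable SNPs of the number of
#' shared alleles divided by two: opposite homozygotes share 0 alleles, a
#' homozygote and a heterozygote share 1, identical genotypes share 2.
#' SNPs with a missing call in either individual contribute only to pairs
#' where both are called; monomorphic and all-missing loci are dropped.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param snp_subset optional SNP ids, indexes or logical selector.
#' @return symmetric n x n matrix in [0,1] with unit diagonal.
#' @export
ibs_similarity <- function(g, snp_subset = NULL) {
  if (!is.null(snp_subset)) g <- g[, snp_subset]
  keep <- is_polymorphic(g)
  if (!any(keep)) stop("no usable (polymorphic, called) SNPs in subset")
  d <- dosage(g[, keep])
  called <- !is.na(d)
  h0 <- (d == 0L) & called; h0[!called] <- FALSE
  h1 <- (d == 1L) & called; h1[!called] <- FALSE
  h2 <- (d == 2L) & called; h2[!called] <- FALSE
  storage.mode(h0) <- storage.mode(h1) <- storage.mode(h2) <- "double"
  cc <- tcrossprod(called * 1)                 # pairwise complete count
  # sum over SNPs of |d_i - d_j|: 2 for opposite homozygotes, 1 for
  # homozygote vs heterozygote
  opp <- tcrossprod(h0, h2); opp <- opp + t(opp)
  hom <- h0 + h2
  adj <- tcrossprod(h1, hom); adj <- adj + t(adj)
  s <- 1 - (2 * opp + adj) / (2 * cc)
  diag(s) <- 1
  dimnames(s) <- list(g$individual_ids, g$individual_ids)
  s
}

#' Classical multidimensional scaling of a similarity matrix
#'
#' Converts similarity to distance \code{D = 1 - similarity} and applies
#' classical (Torgerson) MDS via \code{stats::cmdscale}: double-centered
#' \code{-D^2/2}, eigendecomposition, coordinates scaled by the square
#' roots of the eigenvalues. Dimensions with non-positive eigenvalues are
#' excluded. When an elite id set is supplied, the sign of each axis is
#' fixed so the elite mean coordinate on dimension 1 is positive
#' (reproducible plots).
#'
#' @param similarity symmetric matrix with unit diagonal (row/col names =
#'   individual ids).
#' @param n_dims number of dimensions requested.
#' @param elite_ids optional ids used only to fix axis signs.
#' @param chromosome_scope label stored with the result ("all" or a
#'   chromosome name).
#' @return An object of class \code{mds_result}: \code{coordinates}
#'   (individuals x dims, columns C1, C2, ...), \code{eigenvalues}
#'   (non-increasing, one per returned dimension) and
#'   \code{chromosome_scope}.
#' @export
classical_mds <- function(similarity, n_dims = 2, elite_ids = NULL,
                          chromosome_scope = "all") {
  if (!isSymmetric(unname(similarity), tol = 1e-8))
    stop("similarity matrix must be symmetric")
  d <- 1 - similarity
  # cmdscale warns when fewer than k positive eigenvalues exist; the
  # dimension filtering below handles that case explicitly
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n_dims,
                                          eig = TRUE))
  ev <- fit$eig
  pos <- which(ev > max(ev) * 1e-12 & ev > 0)
  k <- min(n_dims, length(pos))
  if (k == 0) {
    co <- matrix(0, nrow(similarity), 0)
    rownames(co) <- rownames(similarity)
    return(structure(list(coordinates = co, eigenvalues = numeric(0),
                          eigenvalues_all = ev,
                          chromosome_scope = chromosome_scope),
                     class = "mds_result"))
  }
  co <- fit$points[, seq_len(k), drop = FALSE]
  colnames(co) <- paste0("C", seq_len(k))
  rownames(co) <- rownames(similarity)
  if (!is.null(elite_ids)) {
    el <- rownames(co) %in% elite_ids
    if (any(el)) {
      flip <- colMeans(co[el, , drop = FALSE]) < 0
      co[, flip] <- -co[, flip, drop = FALSE]
    }
  }
  structure(list(coordinates = co,
                 eigenvalues = ev[seq_len(k)],
                 eigenvalues_all = ev,
                 chromosome_scope = chromosome_scope),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result (%s): %d individuals, %d dimension(s)\n",
              x$chromosome_scope, nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' Per-chromosome MDS
#'
#' Runs \code{\link{ibs_similarity}} + \code{\link{classical_mds}} for each
#' requested chromosome.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param chromosomes chromosome labels (default: all present).
#' @inheritParams classical_mds
#' @return named list of \code{mds_result}.
#' @export
mds_by_chromosome <- function(g, chromosomes = unique(g$chromosome),
                              n_dims = 2, elite_ids = NULL) {
  out <- lapply(chromosomes, function(ch) {
    classical_mds(ibs_similarity(g, g$chromosome == ch), n_dims,
                  elite_ids = elite_ids, chromosome_scope = ch)
  })
  stats::setNames(out, chromosomes)
}

#' Assign elite / average clusters
#'
#' Either labels the daughters of a designated family as elite
#' (\code{known_elite_family} given, a passthrough of the pedigree
#' information), or runs 2-means on the first two MDS coordinates with a
#' deterministic initialization (the two individuals furthest apart on C1)
#' and labels the smaller cluster elite.
#'
#' @param mds an \code{mds_result} with at least 2 individuals.
#' @param k number of clusters; only 2 is supported.
#' @param known_elite_family optional sire id; requires \code{families}.
#' @param families a \code{\link{family_structure}} (needed with
#'   \code{known_elite_family}).
#' @return An object of class \code{cluster_assignment}: \code{labels}
#'   (named "elite"/"average"), \code{elite_ids}, \code{average_ids},
#'   \code{method}.
#' @export
assign_clusters <- function(mds, k = 2, known_elite_family = NULL,
                            families = NULL) {
  if (k != 2) stop("only k = 2 (elite vs average) is supported")
  ids <- rownames(mds$coordinates)
  if (length(ids) < 2) stop("need at least 2 individuals")
  if (!is.null(known_elite_family)) {
    if (is.null(families)) stop("families required with known_elite_family")
    elite <- names(families$sire_of)[families$sire_of == known_elite_family]
    elite <- intersect(ids, elite)
    if (length(elite) == 0) stop("unknown elite family id")
    lab <- ifelse(ids %in% elite, "elite", "average")
    method <- paste0("family:", known_elite_family)
  } else {
    co <- mds$coordinates[, seq_len(min(2, ncol(mds$coordinates))),
                          drop = FALSE]
    init <- co[c(which.min(co[, 1]), which.max(co[, 1])), , drop = FALSE]
    km <- stats::kmeans(co, centers = init)
    small <- which.min(tabulate(km$cluster, 2))
    lab <- ifelse(km$cluster == small, "elite", "average")
    method <- "kmeans2"
  }
  names(lab) <- ids
  structure(list(labels = lab,
                 elite_ids = ids[lab == "elite"],
                 average_ids = ids[lab == "average"],
                 method = method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d elite, %d average\n",
              x$method, length(x$elite_ids), length(x$average_ids)))
  invisible(x)
}

#' Agreement between a cluster assignment and a known elite set
#'
#' Fraction of individuals on the correct side of the elite/average split:
#' \code{(|elite assigned elite| + |non-elite assigned average|) / n}.
#'
#' @param assignment a \code{cluster_assignment}.
#' @param true_elite_ids the individuals actually in the elite family.
#' @return scalar in [0,1].
#' @export
cluster_purity <- function(assignment, true_elite_ids) {
  ids <- names(assignment$labels)
  truth <- ids %in% true_elite_ids
  mean((assignment$labels == "elite") == truth)
}

#' Export MDS coordinates as a plot-ready table
#'
#' @param mds an \code{mds_result}.
#' @param path optional path; when given the table is written
#'   tab-delimited with a header.
#' @return data.frame (id, scope, C1, C2, ...).
#' @export
mds_table <- function(mds, path = NULL) {
  out <- data.frame(id = rownames(mds$coordinates),
                    scope = mds$chromosome_scope,
                    mds$coordinates, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(path))
    utils::write.table(out, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  out
}
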