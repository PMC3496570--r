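#' Favorable allele of a SNP for a trait
#'
#' For high-favorable traits the favorable allele is the one whose dosage
#' increases the fitted value; for low-favorable traits (somatic cell
#' score, calving ease, stillbirth) it is the allele that decreases it.
#' The additive estimate is on the allele-1 dosage scale, so a positive
#' estimate means allele 1 raises the trait.
#'
#' @param est_additive additive effect estimate (allele-1 dosage scale).
#' @param direction "high" or "low".
#' @return 1L or 2L (allele index), or \code{NA} for a tie (zero effect).
#' @export
favorable_allele <- function(est_additive, direction) {
  if (!direction %in% c("high", "low")) stop("unknown trait direction")
  up <- if (direction == "high") est_additive > 0 else est_additive < 0
  out <- ifelse(est_additive == 0, NA_integer_, ifelse(up, 1L, 2L))
  out
}

#' Per-cluster allele frequencies
#'
#' Allele-count frequency of a designated allele over called genotypes
#' within the elite and average clusters.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param clusters a \code{\link{assign_clusters}} result.
#' @param snp SNP id or index (default: all SNPs, vectorized).
#' @param allele allele index (default 1).
#' @return data.frame: snp_id, freq_elite, freq_average, n_elite_called,
#'   n_average_called (frequencies \code{NaN} where a cluster has no
#'   calls).
#' @export
cluster_frequencies <- function(g, clusters, snp = NULL, allele = 1L) {
  if (length(clusters$elite_ids) == 0 || length(clusters$average_ids) == 0)
    stop("both clusters must be non-empty")
  if (!is.null(snp)) g <- g[, snp]
  d <- dosage(g, allele)
  fe <- d[clusters$elite_ids, , drop = FALSE]
  fa <- d[clusters$average_ids, , drop = FALSE]
  data.frame(snp_id = g$snp_ids,
             freq_elite = colSums(fe, na.rm = TRUE) /
               (2 * colSums(!is.na(fe))),
             freq_average = colSums(fa, na.rm = TRUE) /
               (2 * colSums(!is.na(fa))),
             n_elite_called = colSums(!is.na(fe)),
             n_average_called = colSums(!is.na(fa)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Allele-frequency differences between elite and average clusters
#'
#' For every SNP, the frequency of a designated allele in the elite and
#' average clusters and their absolute difference
#' \code{AFD = |freq_elite - freq_average|}. AFD is invariant to which of
#' the two alleles is designated, so the threshold counts are trait-free;
#' when association results are supplied, the reported allele is oriented
#' to the trait's favorable direction per SNP.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param clusters a \code{\link{assign_clusters}} result.
#' @param results optional \code{assoc_result} for one trait: orients the
#'   reported allele by \code{\link{favorable_allele}}.
#' @param trait_direction "high"/"low"; needed with \code{results}.
#' @param thresholds AFD thresholds to count (default 0.3 and 0.4).
#' @return list with \code{table} (snp_id, chromosome, position, trait,
#'   favorable_allele label, freq_elite, freq_average, afd, rank — ranked
#'   by decreasing AFD, ties by chromosome/position) and \code{counts}
#'   (named vector: SNPs with AFD >= each threshold).
#' @export
afd_table <- function(g, clusters, results = NULL,
                      trait_direction = "high",
                      thresholds = c(0.3, 0.4)) {
  cf <- cluster_frequencies(g, clusters)
  fav_idx <- rep(1L, n_snps(g))
  trait <- NA_character_
  if (!is.null(results)) {
    stopifnot(all(g$snp_ids %in% results$snp_id))
    est <- results$est_additive[match(g$snp_ids, results$snp_id)]
    fi <- favorable_allele(ifelse(is.na(est), 0, est), trait_direction)
    fav_idx <- ifelse(is.na(fi), 1L, fi)
    trait <- attr(results, "trait") %||% NA_character_
  }
  flip <- fav_idx == 2L
  fe <- ifelse(flip, 1 - cf$freq_elite, cf$freq_elite)
  fa <- ifelse(flip, 1 - cf$freq_average, cf$freq_average)
  lab <- g$alleles[cbind(seq_len(n_snps(g)), fav_idx)]
  tab <- data.frame(snp_id = g$snp_ids, chromosome = g$chromosome,
                    position = g$position, trait = trait,
                    favorable_allele = lab,
                    freq_elite = fe, freq_average = fa,
                    afd = abs(fe - fa),
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-tab$afd, chromosome_order(tab$chromosome), tab$position,
               na.last = TRUE)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  counts <- vapply(thresholds, function(th) sum(tab$afd >= th, na.rm = TRUE),
                   0L)
  names(counts) <- paste0("afd_ge_", thresholds)
  list(table = tab, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
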