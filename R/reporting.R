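#' Top-K effects of a scan
#'
#' The k smallest p-values; ties broken by (chromosome, position)
#' ascending. Untestable SNPs (missing p) never enter; fewer than k rows
#' are returned when fewer were tested.
#'
#' @param results an \code{assoc_result} data.frame (needs snp_id,
#'   chromosome, position, p).
#' @param k list length (default 100, the study's per-trait convention).
#' @return the selected rows ordered by rank.
#' @export
top_k <- function(results, k = 100) {
  rk <- assoc_rank(results$p, results$chromosome, results$position)
  sel <- which(!is.na(results$p) & rk <= k)
  results[sel[order(rk[sel])], , drop = FALSE]
}

#' Overlap of top-K lists between a reference and comparison methods
#'
#' For each trait, counts how many of the reference method's top-k SNPs
#' also rank in the top-k of each comparison method and of every
#' intersection of comparison methods (the classical "E, G, P, EG, EP,
#' GP, EGP" accounting when comparing an uncorrected scan against EMMAX,
#' GLS and PCA).
#'
#' @param results nested list: \code{results[[trait]][[method]]} is an
#'   \code{assoc_result}.
#' @param reference reference method name (e.g. "LS").
#' @param comparisons character vector of comparison method names.
#' @param k list length.
#' @param labels optional single-letter labels for the comparison methods
#'   (defaults to their first letters) used to name subset columns.
#' @return data.frame of class \code{overlap_table}: one row per trait,
#'   one column per non-empty subset of comparison methods.
#' @export
overlap_table <- function(results, reference, comparisons, k = 100,
                          labels = NULL) {
  if (is.null(labels)) labels <- substr(comparisons, 1, 1)
  stopifnot(!anyDuplicated(labels), length(labels) == length(comparisons))
  subsets <- unlist(lapply(seq_along(comparisons), function(sz)
    utils::combn(seq_along(comparisons), sz, simplify = FALSE)),
    recursive = FALSE)
  subset_names <- vapply(subsets, function(s) paste(labels[s], collapse = ""),
                         "")
  rows <- lapply(names(results), function(tr) {
    rl <- results[[tr]]
    if (!reference %in% names(rl)) stop("reference results missing for ", tr)
    if (!all(comparisons %in% names(rl)))
      stop("comparison results missing for ", tr)
    ref_ids <- top_k(rl[[reference]], k)$snp_id
    uni <- lapply(rl[comparisons], function(r) r$snp_id)
    if (!all(vapply(uni, function(u) all(ref_ids %in% u), TRUE)))
      stop("mismatched SNP universes between methods for trait ", tr)
    tops <- lapply(rl[comparisons], function(r) top_k(r, k)$snp_id)
    cnt <- vapply(subsets, function(s) {
      inter <- ref_ids
      for (i in s) inter <- intersect(inter, tops[[i]])
      length(inter)
    }, 0L)
    c(list(trait = tr), as.list(cnt))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  names(out) <- c("trait", subset_names)
  class(out) <- c("overlap_table", class(out))
  out
}

#' Block totals of an overlap (or any per-trait count) table
#'
#' Sums count columns within trait blocks, e.g. the 13 production /
#' health / reproduction traits versus the 18 conformation traits.
#'
#' @param tab data.frame with a \code{trait} column and numeric count
#'   columns.
#' @param blocks named character vector or data.frame(trait, block)
#'   assigning each trait to a block; default the
#'   \code{\link{default_trait_catalog}} grouping.
#' @return data.frame: one row per block plus count-column totals.
#' @export
overlap_block_totals <- function(tab, blocks = NULL) {
  if (is.null(blocks)) {
    cat_tr <- default_trait_catalog()
    blocks <- stats::setNames(cat_tr$block, cat_tr$trait)
  } else if (is.data.frame(blocks)) {
    blocks <- stats::setNames(blocks$block, blocks$trait)
  }
  if (!all(tab$trait %in% names(blocks)))
    stop("traits without a block assignment: ",
         paste(setdiff(tab$trait, names(blocks)), collapse = ", "))
  b <- blocks[tab$trait]
  num <- tab[, setdiff(names(tab), "trait"), drop = FALSE]
  agg <- stats::aggregate(num, by = list(block = unname(b)), FUN = sum)
  agg
}

#' Genome-wide significance threshold
#'
#' Bonferroni: \code{alpha / n_tests}. An explicit override value is
#' accepted to replicate an externally stated threshold.
#'
#' @param alpha family-wise type-I error level, in (0,1).
#' @param n_tests number of tests (>= 1).
#' @param override optional explicit p threshold that takes precedence.
#' @return scalar p-value threshold.
#' @export
significance_threshold <- function(alpha = 0.05, n_tests, override = NULL) {
  if (!is.null(override)) return(override)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Manhattan-plot data export
#'
#' Plot-ready table ordered by (chromosome, position): -log10 p and an
#' inclusive above-threshold flag (p equal to the threshold is flagged
#' significant). Rows with missing p are omitted; their count is attached
#' as attribute \code{n_missing}.
#'
#' @param results an \code{assoc_result}.
#' @param threshold p-value threshold for the significance flag.
#' @param path optional path; when given the table is written
#'   tab-delimited with a header.
#' @return data.frame (snp_id, chromosome, position, neg_log10_p,
#'   significant).
#' @export
manhattan_export <- function(results, threshold = NULL, path = NULL) {
  keep <- !is.na(results$p)
  out <- data.frame(snp_id = results$snp_id[keep],
                    chromosome = results$chromosome[keep],
                    position = results$position[keep],
                    neg_log10_p = -log10(results$p[keep]),
                    significant = if (is.null(threshold)) NA
                                  else results$p[keep] <= threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(chromosome_order(out$chromosome), out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing") <- sum(!keep)
  if (!is.null(path))
    utils::write.table(out, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  out
}
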