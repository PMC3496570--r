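#' Half-sib family structure
#'
#' Maps each individual to its sire and partitions the sample into half-sib
#' family blocks. Optionally carries deeper pedigree edges
#' (child, sire, dam, birth year) for descendant tracing.
#'
#' @param sire_of named character vector: names are individual ids, values
#'   are sire ids.
#' @param pedigree optional data.frame with columns \code{child},
#'   \code{sire}, \code{dam} and optionally \code{birth_year}; \code{NA}
#'   for unknown parents.
#' @return An object of class \code{family_structure} with elements
#'   \code{sire_of}, \code{family_blocks} (list of individual-id vectors,
#'   one per sire, in order of first appearance), \code{sires} and
#'   \code{pedigree}.
#' @export
family_structure <- function(sire_of, pedigree = NULL) {
  stopifnot(!is.null(names(sire_of)), !anyDuplicated(names(sire_of)))
  sire_of <- vapply(sire_of, as.character, "")
  sires <- unique(unname(sire_of))
  blocks <- split(names(sire_of), factor(unname(sire_of), levels = sires))
  if (!is.null(pedigree)) {
    stopifnot(all(c("child", "sire", "dam") %in% names(pedigree)))
    pedigree$child <- as.character(pedigree$child)
    pedigree$sire <- as.character(pedigree$sire)
    pedigree$dam <- as.character(pedigree$dam)
  }
  structure(list(sire_of = sire_of, sires = sires,
                 family_blocks = blocks, pedigree = pedigree),
            class = "family_structure")
}

#' @export
print.family_structure <- function(x, ...) {
  sz <- family_sizes(x)
  cat(sprintf("family_structure: %d individuals in %d half-sib families (sizes %d-%d)\n",
              length(x$sire_of), length(sz), min(sz), max(sz)))
  invisible(x)
}

#' Family sizes
#' @param families a \code{family_structure}.
#' @return named integer vector of block sizes (one per sire).
#' @export
family_sizes <- function(families) {
  vapply(families$family_blocks, length, 0L)
}

#' Restrict a family structure to a subset of individuals
#' @param families a \code{family_structure}.
#' @param ids individual ids to keep.
#' @return a \code{family_structure} over \code{ids} (pedigree retained).
#' @export
subset_families <- function(families, ids) {
  keep <- names(families$sire_of) %in% ids
  family_structure(families$sire_of[keep], pedigree = families$pedigree)
}

# Block index list aligned to an individual-id ordering; every id must
# belong to exactly one family.
family_index_blocks <- function(families, ids) {
  sire <- families$sire_of[ids]
  if (anyNA(sire)) stop("individuals without a sire label: ",
                        paste(head(ids[is.na(sire)]), collapse = ", "))
  split(seq_along(ids), factor(unname(sire), levels = unique(unname(sire))))
}
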