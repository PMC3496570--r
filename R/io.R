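#' Read PLINK-style text genotypes
#'
#' Parses a whitespace-delimited .ped file (6 leading columns: family id,
#' individual id, sire id, dam id, sex, phenotype; then two allele columns
#' per SNP) together with its .map file (chromosome, SNP id, genetic
#' distance, base-pair position). The missing-genotype code is \code{"0"}.
#' Allele 1 of each SNP is the alphabetically first allele observed.
#'
#' @param ped_path,map_path file paths.
#' @return A \code{\link{genotype_matrix}} with attributes \code{sire_of}
#'   (named vector from the .ped sire column) and \code{diagnostics}
#'   (a list with counts of individuals, SNPs and missing calls).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chr", "snp", "cm", "pos")
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(tok)
  if (length(unique(len)) > 1)
    stop("ragged .ped rows: row lengths ", paste(unique(len), collapse = ", "))
  if (len[1] != 6 + 2 * m)
    stop(sprintf(".ped has %d genotype columns but .map lists %d SNPs",
                 len[1] - 6, m))
  tok <- matrix(unlist(tok), nrow = length(tok), byrow = TRUE)
  ids <- tok[, 2]
  sire_of <- stats::setNames(tok[, 3], ids)
  ac <- tok[, -(1:6), drop = FALSE]
  c1 <- ac[, seq(1, 2 * m, by = 2), drop = FALSE]
  c2 <- ac[, seq(2, 2 * m, by = 2), drop = FALSE]
  c1[c1 == "0"] <- NA; c2[c2 == "0"] <- NA

  n <- length(ids)
  alleles <- matrix(NA_character_, m, 2)
  a1 <- matrix(NA_integer_, n, m)
  a2 <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- sort(unique(c(c1[, j], c2[, j])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2)
      stop(sprintf("SNP %s has more than 2 alleles: %s",
                   map$snp[j], paste(obs, collapse = "/")))
    alleles[j, seq_along(obs)] <- obs
    a1[, j] <- match(c1[, j], obs)
    a2[, j] <- match(c2[, j], obs)
  }
  g <- genotype_matrix(ids, map$snp, map$chr, map$pos, alleles, a1, a2)
  attr(g, "sire_of") <- sire_of
  attr(g, "diagnostics") <- list(n_individuals = n, n_snps = m,
                                 n_missing_calls = sum(is.na(a1)))
  g
}

#' Write PLINK-style text genotypes
#'
#' Inverse of \code{\link{read_ped_map}}; writers are deterministic given
#' identical inputs. The sire id from \code{families} fills column 3 of the
#' .ped file (dam unknown, sex 2 = female, phenotype placeholder -9).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param ped_path,map_path output paths.
#' @param families optional \code{\link{family_structure}} supplying sire
#'   ids; unknown sires written as \code{"0"}.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(g, ped_path, map_path, families = NULL) {
  if (n_individuals(g) == 0) stop("no individuals to write")
  sire <- rep("0", n_individuals(g))
  if (!is.null(families)) {
    s <- families$sire_of[g$individual_ids]
    sire[!is.na(s)] <- s[!is.na(s)]
  }
  utils::write.table(
    data.frame(g$chromosome, g$snp_ids, 0, g$position),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  lab1 <- matrix(g$alleles[cbind(rep(seq_len(n_snps(g)),
                                     each = n_individuals(g)),
                                 as.vector(g$a1))],
                 n_individuals(g), n_snps(g))
  lab2 <- matrix(g$alleles[cbind(rep(seq_len(n_snps(g)),
                                     each = n_individuals(g)),
                                 as.vector(g$a2))],
                 n_individuals(g), n_snps(g))
  lab1[is.na(lab1)] <- "0"; lab2[is.na(lab2)] <- "0"
  inter <- matrix("", n_individuals(g), 2 * n_snps(g))
  inter[, seq(1, 2 * n_snps(g), 2)] <- lab1
  inter[, seq(2, 2 * n_snps(g), 2)] <- lab2
  lead <- cbind(sire, g$individual_ids, sire, "0", "2", "-9")
  lead[, 1] <- "FAM"
  writeLines(apply(cbind(lead, inter), 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Write / read a phenotype table
#'
#' Tab-delimited with a header; first column \code{id}, one column per
#' trait, values in trait units.
#'
#' @param phenotypes data.frame as produced by
#'   \code{\link{simulate_phenotypes}}.
#' @param path file path.
#' @return \code{read_phenotypes} returns the data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (anyDuplicated(ph$id)) stop("duplicate individual ids in phenotype table")
  ph
}

#' Descendants of a pedigree ancestor
#'
#' Traces child-parent edges downward from \code{ancestor_id} and reports
#' which members of \code{target_set} descend from it. With two ancestors,
#' \code{pedigree_common_descendants} intersects their descendant sets.
#'
#' @param families a \code{\link{family_structure}} whose \code{pedigree}
#'   holds (child, sire, dam) rows.
#' @param ancestor_id pedigree id of the ancestor.
#' @param target_set character vector of ids of interest (default: all
#'   pedigree members).
#' @return list with \code{ids} (members of \code{target_set} descending
#'   from the ancestor) and \code{count}.
#' @export
pedigree_descendants <- function(families, ancestor_id, target_set = NULL) {
  ped <- families$pedigree
  if (is.null(ped)) stop("family structure carries no pedigree edges")
  all_ids <- unique(c(ped$child, ped$sire, ped$dam))
  all_ids <- all_ids[!is.na(all_ids)]
  if (!ancestor_id %in% all_ids) stop("unknown ancestor id: ", ancestor_id)
  if (is.null(target_set)) target_set <- all_ids
  # children indexed by parent
  kids <- split(rep(ped$child, 2), c(ped$sire, ped$dam))
  seen <- character(0)
  frontier <- ancestor_id
  while (length(frontier)) {
    nxt <- unique(unlist(kids[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (ancestor_id %in% seen)
    stop("cycle detected in pedigree: ", ancestor_id,
         " is its own descendant")
  ids <- intersect(target_set, seen)
  list(ids = ids, count = length(ids))
}

#' @rdname pedigree_descendants
#' @param ancestor_id2 second ancestor.
#' @export
pedigree_common_descendants <- function(families, ancestor_id, ancestor_id2,
                                        target_set = NULL) {
  d1 <- pedigree_descendants(families, ancestor_id, target_set)
  d2 <- pedigree_descendants(families, ancestor_id2, target_set)
  ids <- intersect(d1$ids, d2$ids)
  list(ids = ids, count = length(ids))
}
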