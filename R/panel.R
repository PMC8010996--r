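#' Phased haplotype panel
#'
#' A `hap_panel` holds phased biallelic genotypes for N individuals across one
#' or more chromosomes. Alleles are coded 0 (reference) and 1 (alternate).
#' For each chromosome the alleles are stored as an integer matrix with
#' `2 * N` rows -- rows `2i - 1` and `2i` are the two phased haplotypes of
#' individual `i` -- and one column per SNP, ordered by physical position.
#'
#' @param ids character vector of individual identifiers (unique).
#' @param chroms named list; one element per chromosome, each a list with
#'   components `map` (data.frame with columns `snp_id`, `pos`, `ref`, `alt`;
#'   `pos` 1-based, strictly increasing) and `H` (integer matrix,
#'   `2 * length(ids)` rows, `nrow(map)` columns, values in \{0, 1\}).
#' @param validate check the invariants (skip only for internally
#'   constructed panels that are valid by construction).
#'
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(ids, chroms, validate = TRUE) {
  stopifnot(is.character(ids), length(ids) >= 1, !anyDuplicated(ids))
  if (is.null(names(chroms)) || any(!nzchar(names(chroms))))
    stop("chromosomes must be named")
  n2 <- 2L * length(ids)
  if (validate) for (cn in names(chroms)) {
    ch <- chroms[[cn]]
    if (!all(c("map", "H") %in% names(ch)))
      stop("chromosome '", cn, "' must have components 'map' and 'H'")
    if (nrow(ch$H) != n2)
      stop("chromosome '", cn, "': haplotype matrix must have 2N rows")
    if (ncol(ch$H) != nrow(ch$map))
      stop("chromosome '", cn, "': map/matrix SNP count mismatch")
    if (anyNA(ch$H))
      stop("chromosome '", cn, "': panel contains missing alleles")
    if (!all(ch$H == 0L | ch$H == 1L))
      stop("chromosome '", cn, "': alleles must be 0/1")
    if (is.unsorted(ch$map$pos, strictly = TRUE))
      stop("chromosome '", cn, "': positions must be strictly increasing")
  }
  structure(list(ids = ids, chroms = chroms), class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  m <- vapply(x$chroms, function(ch) nrow(ch$map), integer(1))
  cat("hap_panel:", length(x$ids), "individuals,",
      length(x$chroms), "chromosome(s),", sum(m), "SNPs\n")
  for (cn in names(x$chroms))
    cat("  ", cn, ": ", m[[cn]], " SNPs, ",
        x$chroms[[cn]]$map$pos[1], "-", x$chroms[[cn]]$map$pos[m[[cn]]],
        " bp\n", sep = "")
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel a [hap_panel()].
#' @return integer count.
#' @export
n_individuals <- function(panel) length(panel$ids)

#' Alternate-allele dosage matrix
#'
#' Sums the two phased haplotypes into per-individual alt-allele dosages.
#'
#' @param panel a [hap_panel()].
#' @param chrom chromosome name(s); default all.
#' @return integer matrix, individuals x SNPs, values in \{0, 1, 2\}; column
#'   names are SNP ids.
#' @export
dosage_matrix <- function(panel, chrom = names(panel$chroms)) {
  blocks <- lapply(chrom, function(cn) {
    H <- panel$chroms[[cn]]$H
    i1 <- seq(1L, nrow(H), by = 2L)
    D <- H[i1, , drop = FALSE] + H[i1 + 1L, , drop = FALSE]
    colnames(D) <- panel$chroms[[cn]]$map$snp_id
    D
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- panel$ids
  out
}

# Indices of the two haplotype rows of each individual.
.hap_rows <- function(n) list(first = seq(1L, 2L * n, by = 2L),
                              second = seq(2L, 2L * n, by = 2L))
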