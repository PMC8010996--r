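# Carrier-status inference, carrier-class allele-frequency compatibility
# filtering, recessive sequence-variant association and LD.

#' Carrier status for a haplotype call
#'
#' Exact string-match copy count (0/1/2) of the target haplotype per
#' individual, inferred from the phased panel.
#'
#' @param panel a [hap_panel()].
#' @param call a haplotype call (see [haplotype_dosage()]).
#' @return data.frame with columns `id`, `copies`.
#' @export
carrier_status <- function(panel, call) {
  hd <- haplotype_dosage(panel, call, mode = "additive")
  data.frame(id = panel$ids, copies = hd$copies, stringsAsFactors = FALSE)
}

#' Per-carrier-class alternate-allele frequencies
#'
#' Splits individuals into homozygous carriers (2 copies), heterozygous
#' carriers (1) and non-carriers (0) of the target haplotype and computes the
#' alternate-allele frequency of each variant within each class over
#' `2 * n_class` alleles. Empty classes yield `NA` (undefined), not zero.
#'
#' @param variants a `variant_table`.
#' @param status data.frame (`id`, `copies`) from [carrier_status()].
#' @return data.frame: `variant_id`, `af_hom`, `af_het`, `af_non`, and the
#'   class sizes `n_hom`, `n_het`, `n_non`.
#' @export
class_allele_frequencies <- function(variants, status) {
  m <- match(variants$ids, status$id)
  if (anyNA(m)) stop("carrier status does not cover the variant individuals")
  if (length(variants$ids) == 0) stop("no individuals")
  copies <- status$copies[m]
  class_af <- function(sel) {
    if (!any(sel)) return(rep(NA_real_, nrow(variants$geno)))
    rowSums(variants$geno[, sel, drop = FALSE]) / (2 * sum(sel))
  }
  hom <- copies == 2L; het <- copies == 1L; non <- copies == 0L
  data.frame(variant_id = variants$info$variant_id,
             af_hom = class_af(hom), af_het = class_af(het),
             af_non = class_af(non),
             n_hom = sum(hom), n_het = sum(het), n_non = sum(non),
             stringsAsFactors = FALSE)
}

#' Carrier-compatibility filter for candidate causal variants
#'
#' A variant within the region is compatible with recessive inheritance of
#' the top haplotype when, for at least one allele orientation, its allele
#' frequency is greater than `0.8 - slack` in homozygous haplotype carriers,
#' within `[0.4 - slack, 0.6 + slack]` in heterozygous carriers, and less
#' than `0.05 + slack` in non-carriers. Both orientations are tested because
#' the haplotype-linked allele may be either ref or alt; the passing
#' orientation is reported. Boundary semantics are strict for the outer
#' thresholds and inclusive for the heterozygote band. Variants with an
#' undefined class frequency are marked indeterminate, not compatible.
#'
#' @param variants a `variant_table`.
#' @param status data.frame (`id`, `copies`).
#' @param region list with `chrom`, `start`, `end` in bp (e.g. the top
#'   haplotype span widened by 3 Mb on each side), or `NULL` to test every
#'   variant.
#' @param slack optional genotyping-error allowance relaxing every threshold
#'   (default 0 = exact thresholds).
#' @return data.frame: the class frequencies plus `compatible`,
#'   `orientation` (`"alt"`, `"ref"` or `NA`) and `indeterminate`.
#' @export
compatibility_filter <- function(variants, status, region = NULL, slack = 0) {
  keep <- rep(TRUE, nrow(variants$info))
  if (!is.null(region)) {
    keep <- variants$info$chrom == as.character(region$chrom) &
      variants$info$pos >= region$start & variants$info$pos <= region$end
  }
  sub <- variants
  sub$info <- variants$info[keep, , drop = FALSE]
  sub$geno <- variants$geno[keep, , drop = FALSE]
  cf <- class_allele_frequencies(sub, status)
  pass <- function(f_hom, f_het, f_non)
    f_hom > 0.8 - slack &
      f_het >= 0.4 - slack & f_het <= 0.6 + slack &
      f_non < 0.05 + slack
  indeterminate <- is.na(cf$af_hom) | is.na(cf$af_het) | is.na(cf$af_non)
  alt_ok <- !indeterminate & pass(cf$af_hom, cf$af_het, cf$af_non)
  ref_ok <- !indeterminate & pass(1 - cf$af_hom, 1 - cf$af_het, 1 - cf$af_non)
  cf$compatible <- alt_ok | ref_ok
  cf$orientation <- ifelse(alt_ok, "alt", ifelse(ref_ok, "ref", NA_character_))
  cf$indeterminate <- indeterminate
  cf
}

#' Haplotype region widened by a fine-mapping margin
#'
#' @param call a haplotype call with `chrom`, `start_bp`, `end_bp`.
#' @param margin bp added on each side (default 3 Mb).
#' @return list with `chrom`, `start`, `end` (bp, floored at 1).
#' @export
finemap_region <- function(call, margin = 3e6) {
  list(chrom = as.character(call$chrom),
       start = max(1, call$start_bp - margin),
       end = call$end_bp + margin)
}

#' Recessive sequence-variant association
#'
#' Tests imputed sequence variants for association with the phenotype under
#' a recessive coding (indicator of homozygosity for the minor allele),
#' adjusting for principal components and an optional conditional covariate
#' -- the same least-squares machinery as the haplotype scan. Variants with
#' minor allele frequency at or below `maf_min` or imputation quality at or
#' below `r2_min` are excluded and reported.
#'
#' @param variants a `variant_table`.
#' @param phenotypes data.frame (`id`, `y`).
#' @param pcs optional `pcset`.
#' @param conditional optional numeric covariate aligned to `variants$ids`.
#' @param maf_min minor-allele-frequency exclusion bound (strict >;
#'   default 0.05).
#' @param r2_min imputation-quality exclusion bound (strict >; default 0.4).
#' @return list with `results` (data.frame: `variant_id`, `chrom`, `pos`,
#'   `coded_allele`, `freq_hom_coded`, `beta`, `se`, `p`, `n_used`),
#'   `excluded` (data.frame: `variant_id`, `reason`) and `n_tests`.
#' @export
variant_recessive_assoc <- function(variants, phenotypes, pcs = NULL,
                                    conditional = NULL, maf_min = 0.05,
                                    r2_min = 0.4) {
  ids <- variants$ids
  y <- align_phenotypes(phenotypes, ids)
  C <- build_covariates(ids, pcs, conditional)
  af <- rowMeans(variants$geno) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- maf <= maf_min
  fail_r2 <- variants$info$impute_r2 <= r2_min
  excluded <- data.frame(
    variant_id = variants$info$variant_id[fail_maf | fail_r2],
    reason = ifelse(fail_maf[fail_maf | fail_r2], "maf", "impute_r2"),
    stringsAsFactors = FALSE)
  keep <- which(!fail_maf & !fail_r2)
  if (!length(keep)) {
    warning("all variants excluded by MAF / imputation-quality filters")
    return(list(results = data.frame(), excluded = excluded, n_tests = 0L))
  }
  minor_is_alt <- af[keep] <= 0.5
  D <- matrix(0, length(ids), length(keep))
  for (j in seq_along(keep)) {
    g <- variants$geno[keep[j], ]
    D[, j] <- if (minor_is_alt[j]) as.numeric(g == 2L)
              else as.numeric(g == 0L)
  }
  fit <- .ols_batch(y, C, D)
  ok <- !fit$degenerate
  res <- data.frame(variant_id = variants$info$variant_id[keep],
                    chrom = variants$info$chrom[keep],
                    pos = variants$info$pos[keep],
                    coded_allele = ifelse(minor_is_alt, "alt", "ref"),
                    freq_hom_coded = colMeans(D),
                    beta = fit$beta, se = fit$se, p = fit$p,
                    n_used = fit$n_used, stringsAsFactors = FALSE)[ok, ]
  rownames(res) <- NULL
  list(results = res, excluded = excluded, n_tests = nrow(res))
}

#' Linkage disequilibrium between two dosage vectors
#'
#' Squared Pearson correlation of allele dosages.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r-squared, or `NA` (undefined) when either input is constant.
#' @export
ld_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}
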