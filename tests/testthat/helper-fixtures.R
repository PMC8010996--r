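# Shared fixture builders and brute-force oracles.

# Build a hap_panel from per-chromosome lists of haplotype allele strings
# (two consecutive strings per individual).
panel_from_strings <- function(chrom_haps, pos_step = 1000) {
  n <- length(chrom_haps[[1]]) / 2
  chroms <- lapply(chrom_haps, function(haps) {
    H <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
    m <- ncol(H)
    pos <- seq(pos_step, by = pos_step, length.out = m)
    list(map = data.frame(snp_id = paste0("s", seq_len(m)), pos = pos,
                          ref = rep("A", m), alt = rep("C", m),
                          stringsAsFactors = FALSE),
         H = H)
  })
  if (is.null(names(chroms)))
    names(chroms) <- as.character(seq_along(chroms))
  hap_panel(sprintf("i%02d", seq_len(n)), chroms)
}

# Permute the individuals of a panel (both haplotype rows move together).
permute_panel <- function(panel, perm) {
  rows <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  panel$chroms <- lapply(panel$chroms, function(ch) {
    ch$H <- ch$H[rows, , drop = FALSE]
    ch
  })
  panel$ids <- panel$ids[perm]
  panel
}

# Moore-Penrose OLS oracle: beta, se, t, p for the last column of X.
pinv_ols <- function(y, X) {
  s <- svd(X)
  d_inv <- ifelse(s$d > max(s$d) * 1e-12, 1 / s$d, 0)
  beta <- s$v %*% (d_inv * crossprod(s$u, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- s$v %*% (d_inv^2 * t(s$v))
  se <- sqrt(sigma2 * diag(XtX_inv))
  k <- ncol(X)
  t <- beta[k] / se[k]
  list(beta = beta[k], se = se[k], t = t, p = 2 * pt(-abs(t), df))
}

# Small deterministic variant_table built from explicit dosages.
variant_table_from_geno <- function(geno, ids, pos = NULL, chrom = "1",
                                    impute_r2 = NULL) {
  nv <- nrow(geno)
  if (is.null(pos)) pos <- seq(1e6, by = 1e4, length.out = nv)
  if (is.null(impute_r2)) impute_r2 <- rep(0.95, nv)
  vid <- paste0(chrom, ":", pos)
  rownames(geno) <- vid
  colnames(geno) <- ids
  structure(list(
    info = data.frame(variant_id = vid, chrom = chrom, pos = pos,
                      ref = "A", alt = "C", af = rowMeans(geno) / 2,
                      impute_r2 = impute_r2, stringsAsFactors = FALSE),
    geno = geno, ids = ids, causal_variant_id = NA_character_),
    class = "variant_table")
}

# Hand-built ejaculate record with overridable fields.
ejac_record <- function(...) {
  base <- list(bull = "b1", day = 10L, time_s = 3600L, age_days = 500,
               volume_ml = 4, mixed = FALSE, processed = TRUE,
               motility_pct = 80, head_score = 0L, tail_score = 0L,
               sperm_per_straw = 20, sex_sorted = FALSE, collector = "C1",
               handler = "H1", genotyped = TRUE, concentration = 1000,
               interval_days = 3)
  as.data.frame(utils::modifyList(base, list(...)), stringsAsFactors = FALSE)
}
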