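# One replicate of the synthetic mapping study: generate a cohort, embed a
# recessive fertility QTL, scan, and summarise detection.

#' Simulate and scan one synthetic mapping cohort
#'
#' Generates a phased panel, embeds a recessive causal haplotype spanning
#' `causal_span` SNPs (wider than one scan window, so at least one window
#' lies fully inside the causal segment), simulates fertility on the
#' phenotypic-SD scale, computes GRM principal components and runs the
#' recessive sliding-window scan. The defaults reproduce the mapping-study
#' conditions: 3736 bulls, causal haplotype frequency 0.18, homozygote
#' effect -0.8 SD, SNP heritability 0.10, on a 10,000-SNP panel over five
#' chromosomes (dense enough for hundreds of windows per chromosome while
#' keeping a 20-replicate power study tractable on a single CPU).
#'
#' @param seed integer seed for the replicate (sub-generators derive small
#'   offsets from it).
#' @param n_individuals cohort size.
#' @param chrom_sizes SNP counts per chromosome.
#' @param causal_chrom chromosome carrying the causal haplotype.
#' @param causal_span causal-segment length in SNPs.
#' @param target_freq causal haplotype frequency.
#' @param beta_hom homozygote effect in phenotypic SD.
#' @param h2 polygenic SNP heritability.
#' @param k_pcs number of GRM principal components.
#' @param pc_method eigen method for [top_pcs()] (`"randomized"` scales to
#'   thousands of individuals).
#' @param window_size,step,min_freq,min_hom_frac scan settings.
#' @param keep_objects keep the panel/scan objects in the result (memory
#'   heavy; default FALSE).
#' @return list with the causal span (`causal_start`, `causal_end`,
#'   `realized_freq`, `n_hom_true`), the top recessive hit (`top`), a
#'   logical `localized` (top window overlaps the causal segment), and at
#'   the best causal-region haplotype: `p_recessive`, `p_additive` (same
#'   haplotype, additive coding), `beta_hom_est`, `se_hom_est`; plus
#'   `n_tests` and `lambda`.
#' @export
simulate_mapping_study <- function(seed,
                                   n_individuals = 3736,
                                   chrom_sizes = c("1" = 2000, "2" = 2000,
                                                   "3" = 2000, "4" = 2000,
                                                   "5" = 2000),
                                   causal_chrom = "3",
                                   causal_span = 80,
                                   target_freq = 0.18,
                                   beta_hom = -0.8,
                                   h2 = 0.1,
                                   k_pcs = 10,
                                   pc_method = "randomized",
                                   window_size = 50, step = 15,
                                   min_freq = 0.01, min_hom_frac = 0.005,
                                   keep_objects = FALSE) {
  m <- chrom_sizes[[causal_chrom]]
  c_start <- as.integer(m / 2 - causal_span / 2)
  c_end <- c_start + as.integer(causal_span) - 1L
  cfg <- sim_config(n_individuals, chrom_sizes, seed = seed)
  panel <- simulate_panel(cfg)
  cs <- embed_recessive_qtl(panel, causal_chrom, c(c_start, c_end),
                            target_freq, tolerance = 0.02, seed = seed + 1L)
  panel <- cs$panel
  D <- dosage_matrix(panel)
  ph <- simulate_fertility(panel, cs, beta_hom = beta_hom, h2 = h2,
                           seed = seed + 2L, dosage = D)
  grm <- compute_grm(panel, dosage = D)
  rm(D)
  pcs <- top_pcs(grm, k = k_pcs, method = pc_method)
  scan <- hap_scan(panel, ph, pcs, mode = "recessive",
                   window_size = window_size, step = step,
                   min_freq = min_freq, min_hom_frac = min_hom_frac)
  top <- top_hit(scan)
  res <- scan$results
  causal_rows <- res[res$chrom == causal_chrom & res$start <= c_end &
                       res$end >= c_start, , drop = FALSE]
  p_rec <- NA_real_; p_add <- NA_real_
  beta_est <- NA_real_; se_est <- NA_real_
  if (nrow(causal_rows)) {
    best <- causal_rows[order(causal_rows$p, -causal_rows$frequency), ][1, ]
    p_rec <- best$p; beta_est <- best$beta; se_est <- best$se
    hd_add <- haplotype_dosage(panel, best, mode = "additive")
    fit_add <- fit_association(ph, hd_add, covariates = pcs$vectors,
                               ids = panel$ids)
    p_add <- fit_add$p_value
  }
  out <- list(causal_start = c_start, causal_end = c_end,
              realized_freq = cs$realized_frequency,
              n_hom_true = sum(causal_copies(cs) == 2L),
              top = top,
              localized = top$chrom == causal_chrom &&
                top$start <= c_end && top$end >= c_start,
              p_recessive = p_rec, p_additive = p_add,
              beta_hom_est = beta_est, se_hom_est = se_est,
              n_tests = scan$n_tests, lambda = scan$lambda)
  if (keep_objects) {
    out$panel <- panel; out$causal <- cs; out$phenotypes <- ph
    out$pcs <- pcs; out$scan <- scan
  }
  out
}
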