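# Sliding-window haplotype association scan under additive and recessive
# inheritance, with principal-component correction, optional conditional
# covariates, Bonferroni thresholds and the genomic inflation factor.

#' Enumerate sliding windows
#'
#' Windows of `window_size` contiguous SNPs advance in steps of `step` SNPs
#' along each chromosome; trailing partial windows are dropped so every
#' window has the same SNP count. Windows never span chromosomes.
#'
#' @param n_snps_per_chrom named integer vector of SNP counts per chromosome.
#' @param window_size SNPs per window (default 50).
#' @param step SNPs between window starts (default 15).
#' @return data.frame with columns `chrom`, `start`, `end` (1-based SNP
#'   indices, inclusive).
#' @export
enumerate_windows <- function(n_snps_per_chrom, window_size = 50, step = 15) {
  stopifnot(window_size >= 1, step >= 1)
  if (is.null(names(n_snps_per_chrom)))
    names(n_snps_per_chrom) <- as.character(seq_along(n_snps_per_chrom))
  out <- lapply(names(n_snps_per_chrom), function(cn) {
    m <- n_snps_per_chrom[[cn]]
    if (m < window_size) return(NULL)
    starts <- seq(1L, m - window_size + 1L, by = step)
    data.frame(chrom = cn, start = starts,
               end = starts + as.integer(window_size) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out
}

# Numeric code of each haplotype over a SNP-index window. For windows of at
# most 50 SNPs the code is an exact dyadic sum (< 2^50, below the double
# mantissa); wider windows combine chunk codes into a string key.
.window_codes <- function(H, cols) {
  k <- length(cols)
  if (k <= 50) {
    as.vector(H[, cols, drop = FALSE] %*% 2^(seq_len(k) - 1))
  } else {
    chunks <- split(cols, ceiling(seq_along(cols) / 50))
    keys <- lapply(chunks, function(cc)
      as.vector(H[, cc, drop = FALSE] %*% 2^(seq_along(cc) - 1)))
    do.call(paste, c(keys, sep = "_"))
  }
}

# Distinct haplotypes in a window: integer index per haplotype row, counts,
# and representative rows (first occurrence) for decoding allele strings.
.window_tally <- function(H, cols) {
  code <- .window_codes(H, cols)
  first <- which(!duplicated(code))
  idx <- match(code, code[first])
  counts <- tabulate(idx, nbins = length(first))
  list(idx = idx, counts = counts, first = first)
}

.decode_string <- function(H, cols, row) {
  paste(H[row, cols], collapse = "")
}

#' Haplotypes segregating in a window
#'
#' Tallies the distinct allele strings among the `2N` phased haplotypes of a
#' window and keeps those with frequency strictly above `min_freq`.
#'
#' @param panel a [hap_panel()].
#' @param window list or one-row data.frame with `chrom`, `start`, `end`
#'   (SNP indices).
#' @param min_freq haplotype frequency threshold (strict; default 0.01).
#' @return data.frame of haplotype calls: `chrom`, `start`, `end`,
#'   `start_bp`, `end_bp`, `allele_string`, `frequency`, `n_hom`, ordered by
#'   descending frequency (ties by allele string).
#' @export
window_haplotypes <- function(panel, window, min_freq = 0.01) {
  cn <- as.character(window$chrom)
  ch <- panel$chroms[[cn]]
  if (is.null(ch)) stop("unknown chromosome '", cn, "'")
  if (window$start < 1 || window$end > nrow(ch$map))
    stop("window outside chromosome '", cn, "'")
  cols <- window$start:window$end
  tl <- .window_tally(ch$H, cols)
  n2 <- nrow(ch$H)
  freq <- tl$counts / n2
  odd <- seq(1L, n2, by = 2L)
  hom_pairs <- tl$idx[odd] == tl$idx[odd + 1L]
  n_hom <- tabulate(tl$idx[odd][hom_pairs], nbins = length(tl$first))
  keep <- which(freq > min_freq)
  strings <- vapply(tl$first[keep], function(r) .decode_string(ch$H, cols, r),
                    character(1))
  out <- data.frame(chrom = cn, start = window$start, end = window$end,
                    start_bp = ch$map$pos[window$start],
                    end_bp = ch$map$pos[window$end],
                    allele_string = strings, frequency = freq[keep],
                    n_hom = n_hom[keep], stringsAsFactors = FALSE)
  out[order(-out$frequency, out$allele_string), , drop = FALSE]
}

#' Per-individual dosage of a haplotype
#'
#' Counts exact-match copies of a haplotype call per individual and encodes
#' them for the requested mode of inheritance: additive (copies 0/1/2) or
#' recessive (indicator of two copies). A recessive dosage is only produced
#' for haplotypes observed in the homozygous state in at least
#' `min_hom_frac` of individuals; rarer homozygotes yield an ineligible
#' marker instead of a dosage.
#'
#' @param panel a [hap_panel()].
#' @param call one haplotype call (row of [window_haplotypes()] output or a
#'   list with `chrom`, `start`, `end`, `allele_string`).
#' @param mode `"additive"` or `"recessive"`.
#' @param min_hom_frac homozygote-fraction eligibility bound for recessive
#'   tests (default 0.005).
#' @return A `hap_dosage` list: `dosage` (numeric per individual, `NULL` when
#'   ineligible), `mode`, `eligible`, `n_hom`, `copies`.
#' @export
haplotype_dosage <- function(panel, call, mode = c("additive", "recessive"),
                             min_hom_frac = 0.005) {
  mode <- match.arg(mode)
  cn <- as.character(call$chrom)
  ch <- panel$chroms[[cn]]
  cols <- call$start:call$end
  alleles <- as.integer(strsplit(call$allele_string, "")[[1]])
  if (length(alleles) != length(cols))
    stop("allele_string length does not match the window size")
  hit <- colSums(abs(t(ch$H[, cols, drop = FALSE]) - alleles) > 0) == 0
  n <- length(panel$ids)
  idx <- .hap_rows(n)
  copies <- as.integer(hit[idx$first]) + as.integer(hit[idx$second])
  n_hom <- sum(copies == 2L)
  if (mode == "additive") {
    return(structure(list(dosage = as.numeric(copies), mode = mode,
                          eligible = TRUE, n_hom = n_hom, copies = copies),
                     class = "hap_dosage"))
  }
  eligible <- (n_hom / n) >= min_hom_frac
  structure(list(dosage = if (eligible) as.numeric(copies == 2L) else NULL,
                 mode = mode, eligible = eligible, n_hom = n_hom,
                 copies = copies),
            class = "hap_dosage")
}

# Batched OLS of y on [1 | C | d] for every column d of D, via projection on
# the covariate space (Frisch-Waugh-Lovell): identical estimates, SEs and
# t-tests to the full regression, one QR for the whole batch.
.ols_batch <- function(y, C, D) {
  n <- length(y)
  X <- cbind(intercept = rep(1, n), C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient covariates: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  Q <- qr.Q(qrX)
  yr <- y - Q %*% crossprod(Q, y)
  Dr <- D - Q %*% crossprod(Q, D)
  sxx <- colSums(Dr^2)
  sxy <- colSums(Dr * as.vector(yr))
  df <- n - ncol(X) - 1L
  if (df < 1) stop("not enough residual degrees of freedom")
  degenerate <- sxx < n * 1e-12
  beta <- ifelse(degenerate, NA_real_, sxy / sxx)
  rss <- pmax(0, sum(yr^2) - ifelse(degenerate, 0, beta^2 * sxx))
  se <- sqrt(rss / df / sxx)
  se[degenerate | se == 0] <- NA_real_
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, se = se, t = tval, p = p, df = df, n_used = n,
       degenerate = degenerate | is.na(se))
}

#' Single-haplotype (or variant) association fit
#'
#' Ordinary least squares of the phenotype on a dosage with optional
#' covariates (principal components, conditional dosage); two-sided t-test
#' on the dosage coefficient with `n - p` residual degrees of freedom.
#'
#' @param phenotypes data.frame (`id`, `y`) or numeric vector aligned to
#'   `ids`.
#' @param dosage numeric vector or a `hap_dosage` from [haplotype_dosage()].
#' @param covariates numeric matrix of covariates (no intercept column), or
#'   `NULL`.
#' @param ids individual ids the dosage is aligned to (required when
#'   `phenotypes` is a table).
#' @return An `assoc_result` list: `beta`, `se`, `t`, `p_value`, `df`,
#'   `n_used`, `degenerate`.
#' @export
fit_association <- function(phenotypes, dosage, covariates = NULL,
                            ids = NULL) {
  if (inherits(dosage, "hap_dosage")) {
    if (!dosage$eligible)
      stop("dosage is ineligible for the recessive test (too few homozygotes)")
    dosage <- dosage$dosage
  }
  y <- if (is.numeric(phenotypes)) as.numeric(phenotypes)
       else align_phenotypes(phenotypes, ids)
  if (length(y) != length(dosage))
    stop("phenotype and dosage lengths differ")
  fit <- .ols_batch(y, covariates, matrix(dosage, ncol = 1))
  structure(list(beta = fit$beta[1], se = fit$se[1], t = fit$t[1],
                 p_value = fit$p[1], df = fit$df, n_used = fit$n_used,
                 degenerate = fit$degenerate[1]),
            class = "assoc_result")
}

#' Genome-wide sliding-window haplotype scan
#'
#' Tests every haplotype with frequency strictly above `min_freq` in every
#' sliding window, one-vs-rest, under the requested mode of inheritance,
#' adjusting for principal components and an optional conditional dosage
#' covariate. Recessive tests are restricted to haplotypes homozygous in at
#' least `min_hom_frac` of individuals. Monomorphic (constant-dosage)
#' haplotypes are untestable and are skipped. Results are ordered by
#' chromosome, window start and descending frequency.
#'
#' @param panel a [hap_panel()].
#' @param phenotypes data.frame (`id`, `y`, ...) covering the panel ids.
#' @param pcs optional `pcset` of covariate components.
#' @param mode `"additive"` or `"recessive"`.
#' @param window_size,step window geometry in SNPs (defaults 50 / 15).
#' @param min_freq haplotype frequency filter (strict; default 0.01).
#' @param min_hom_frac recessive eligibility bound (default 0.005).
#' @param conditional optional numeric dosage covariate aligned to the panel
#'   ids (e.g. the recessive status of a known QTL haplotype).
#' @return A `scan_result`: list with `results` (data.frame: `chrom`,
#'   `start`, `end`, `start_bp`, `end_bp`, `allele_string`, `frequency`,
#'   `n_hom`, `mode`, `beta`, `se`, `p`, `n_used`), `n_tests`, `mode`,
#'   `lambda` (genomic inflation over the scan's p-values) and `params`.
#' @export
hap_scan <- function(panel, phenotypes, pcs = NULL,
                     mode = c("additive", "recessive"),
                     window_size = 50, step = 15, min_freq = 0.01,
                     min_hom_frac = 0.005, conditional = NULL) {
  mode <- match.arg(mode)
  y <- align_phenotypes(phenotypes, panel$ids)
  C <- build_covariates(panel$ids, pcs, conditional)
  n <- length(panel$ids)
  X <- cbind(rep(1, n), C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient covariates in scan model")
  Q <- qr.Q(qrX)
  yr <- y - Q %*% crossprod(Q, y)
  syy <- sum(yr^2)
  df <- n - ncol(X) - 1L
  idx <- .hap_rows(n)
  min_hom <- min_hom_frac * n
  chunks <- list()
  for (cn in names(panel$chroms)) {
    ch <- panel$chroms[[cn]]
    wins <- enumerate_windows(stats::setNames(nrow(ch$map), cn),
                              window_size, step)
    if (nrow(wins) == 0) next
    for (w in seq_len(nrow(wins))) {
      cols <- wins$start[w]:wins$end[w]
      tl <- .window_tally(ch$H, cols)
      freq <- tl$counts / (2 * n)
      id1 <- tl$idx[idx$first]; id2 <- tl$idx[idx$second]
      keep <- which(freq > min_freq & freq < 1)
      if (!length(keep)) next
      hcols <- list(); meta <- list()
      for (h in keep) {
        copies <- (id1 == h) + (id2 == h)
        n_hom <- sum(copies == 2L)
        d <- if (mode == "additive") as.numeric(copies) else {
          if (n_hom < min_hom) next
          as.numeric(copies == 2L)
        }
        if (stats::var(d) == 0) next
        hcols[[length(hcols) + 1L]] <- d
        meta[[length(meta) + 1L]] <- list(h = h, n_hom = n_hom)
      }
      if (!length(hcols)) next
      D <- do.call(cbind, hcols)
      Dr <- D - Q %*% crossprod(Q, D)
      sxx <- colSums(Dr^2)
      sxy <- colSums(Dr * as.vector(yr))
      beta <- sxy / sxx
      rss <- pmax(0, syy - beta^2 * sxx)
      se <- sqrt(rss / df / sxx)
      ok <- sxx > n * 1e-12 & se > 0
      if (!any(ok)) next
      hsel <- vapply(meta, `[[`, integer(1), "h")[ok]
      strings <- vapply(tl$first[hsel],
                        function(r) .decode_string(ch$H, cols, r),
                        character(1))
      tval <- beta[ok] / se[ok]
      chunks[[length(chunks) + 1L]] <- data.frame(
        chrom = cn, start = wins$start[w], end = wins$end[w],
        start_bp = ch$map$pos[wins$start[w]],
        end_bp = ch$map$pos[wins$end[w]],
        allele_string = strings,
        frequency = freq[hsel],
        n_hom = vapply(meta, `[[`, integer(1), "n_hom")[ok],
        mode = mode, beta = beta[ok], se = se[ok],
        p = 2 * stats::pt(-abs(tval), df),
        n_used = n, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(chunks)) do.call(rbind, chunks)
         else data.frame(chrom = character(), start = integer(),
                         end = integer(), start_bp = integer(),
                         end_bp = integer(), allele_string = character(),
                         frequency = numeric(), n_hom = integer(),
                         mode = character(), beta = numeric(),
                         se = numeric(), p = numeric(), n_used = integer(),
                         stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, -res$frequency, res$allele_string), ]
  rownames(res) <- NULL
  structure(list(results = res, n_tests = nrow(res), mode = mode,
                 lambda = if (nrow(res)) genomic_lambda(res$p) else NA_real_,
                 params = list(window_size = window_size, step = step,
                               min_freq = min_freq,
                               min_hom_frac = min_hom_frac,
                               n_pcs = if (is.null(pcs)) 0L
                                       else ncol(pcs$vectors),
                               conditional = !is.null(conditional))),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result (", x$mode, "): ", x$n_tests, " tests, lambda = ",
      round(x$lambda, 3), "\n", sep = "")
  if (x$n_tests) {
    top <- top_hit(x)
    cat("  top: ", top$chrom, ":", top$start_bp, "-", top$end_bp,
        " freq ", round(top$frequency, 3), " p ",
        format(top$p, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Top-associated haplotype of a scan
#'
#' Smallest p-value; ties broken by higher frequency, then lexicographic
#' allele string.
#'
#' @param scan a `scan_result`.
#' @return one-row data.frame.
#' @export
top_hit <- function(scan) {
  res <- scan$results
  if (!nrow(res)) stop("empty scan result")
  res <- res[order(res$p, -res$frequency, res$allele_string), ]
  res[1, , drop = FALSE]
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests performed.
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count")
  alpha / n_tests
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`: the median
#' association chi-square statistic relative to its null median (about
#' 0.4549). Values near 1 indicate calibrated tests.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return lambda.
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  stats::median(stats::qchisq(1 - p_values, df = 1)) /
    stats::qchisq(0.5, df = 1)
}
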