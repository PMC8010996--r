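# Non-return-rate fertility phenotype: Henderson mixed-model equations on
# 0/1 insemination outcomes, standardization, cohort merging and the
# homozygous-load / heterozygote contrasts.

#' Solve the non-return-rate mixed model by Henderson's equations
#'
#' Fits a linear mixed model to 0/1 first-insemination outcomes (1 = no
#' re-insemination recorded within 56 days): fixed insemination-month,
#' parity, semen-price, breed-combination and technician effects, plus
#' random herd and random bull effects. The 0/1 outcomes are analysed on the
#' linear scale, following the classical sire non-return evaluation. The
#' mixed-model equations are assembled sparsely and solved in units of the
#' residual variance; `variance_ratios` are `var_e / var_u` for each random
#' term, so larger ratios shrink the solutions harder. Bull solutions are
#' deviations from the average non-return rate.
#'
#' @param records data.frame of insemination records with columns `bull`,
#'   `y` (0/1) and any of the fixed-effect factors `month`, `parity`,
#'   `price`, `breed_comb`, `technician`; a `herd` column, when present,
#'   enters as a random effect.
#' @param variance_ratios named numeric, entries `herd` and `bull`
#'   (defaults 9 and 19).
#' @return list with `estimates` (data.frame: `bull`, `effect`,
#'   `n_inseminations`), `herd_effects`, `fixed_effects`, and
#'   `variance_ratios`.
#' @export
solve_nrr_mme <- function(records, variance_ratios = c(herd = 9, bull = 19)) {
  stopifnot(all(c("bull", "y") %in% names(records)))
  if (!all(records$y %in% c(0, 1))) stop("outcomes must be 0/1")
  if (any(variance_ratios <= 0)) stop("variance ratios must be positive")
  y <- as.numeric(records$y)
  nrec <- length(y)
  fixed_terms <- intersect(c("month", "parity", "price", "breed_comb",
                             "technician"), names(records))
  fixed_terms <- fixed_terms[vapply(fixed_terms, function(f)
    length(unique(records[[f]])) > 1, logical(1))]
  X <- if (length(fixed_terms)) {
    fml <- stats::as.formula(paste("~", paste(fixed_terms, collapse = " + ")))
    Matrix::sparse.model.matrix(fml, data = records)
  } else {
    Matrix::Matrix(1, nrec, 1, sparse = TRUE,
                   dimnames = list(NULL, "(Intercept)"))
  }
  qx <- qr(as.matrix(X))
  if (qx$rank < ncol(X))
    stop("singular fixed-effect design; aliased: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  bulls <- sort(unique(records$bull))
  Zs <- Matrix::sparseMatrix(i = seq_len(nrec),
                             j = match(records$bull, bulls),
                             x = 1, dims = c(nrec, length(bulls)))
  has_herd <- "herd" %in% names(records)
  if (has_herd) {
    herds <- sort(unique(records$herd))
    Zh <- Matrix::sparseMatrix(i = seq_len(nrec),
                               j = match(records$herd, herds),
                               x = 1, dims = c(nrec, length(herds)))
    W <- cbind(X, Zh, Zs)
    lam <- c(rep(0, ncol(X)), rep(variance_ratios[["herd"]], ncol(Zh)),
             rep(variance_ratios[["bull"]], ncol(Zs)))
  } else {
    W <- cbind(X, Zs)
    lam <- c(rep(0, ncol(X)), rep(variance_ratios[["bull"]], ncol(Zs)))
  }
  C <- Matrix::crossprod(W) + Matrix::Diagonal(x = lam)
  sol <- as.vector(Matrix::solve(C, Matrix::crossprod(W, y)))
  p <- ncol(X)
  fixed <- stats::setNames(sol[seq_len(p)], colnames(X))
  off <- p
  herd_effects <- NULL
  if (has_herd) {
    herd_effects <- data.frame(herd = herds,
                               effect = sol[off + seq_along(herds)],
                               stringsAsFactors = FALSE)
    off <- off + length(herds)
  }
  est <- data.frame(bull = bulls,
                    effect = sol[off + seq_along(bulls)],
                    n_inseminations = as.integer(table(records$bull)[bulls]),
                    stringsAsFactors = FALSE)
  list(estimates = est, herd_effects = herd_effects, fixed_effects = fixed,
       variance_ratios = variance_ratios)
}

#' Standardize fertility estimates
#'
#' Affine rescale of the bull solutions to a target mean and standard
#' deviation (default 100 +/- 12). Applying the function twice leaves the
#' values unchanged.
#'
#' @param estimates data.frame with a `fertility` column (used when present)
#'   or an `effect` column, or a bare numeric vector.
#' @param mean,sd target mean and standard deviation.
#' @return the input with a (re)computed `fertility` column; for numeric
#'   input, the rescaled vector.
#' @export
standardize_fertility <- function(estimates, mean = 100, sd = 12) {
  vals <- if (is.numeric(estimates)) estimates
          else if (!is.null(estimates$fertility)) estimates$fertility
          else estimates$effect
  if (length(vals) < 2) stop("need at least two bulls")
  s <- stats::sd(vals)
  if (s == 0) stop("zero variance: cannot standardize")
  out <- (vals - base::mean(vals)) / s * sd + mean
  if (is.numeric(estimates)) return(out)
  estimates$fertility <- out
  estimates
}

#' Remove low phenotypic outliers
#'
#' Drops bulls whose standardized fertility lies strictly more than `k`
#' standard deviations below the mean (such extremes may reflect rare
#' genetic conditions and would distort the association model). A bull at
#' exactly `-k` SD is retained.
#'
#' @param estimates data.frame with a `fertility` column.
#' @param k outlier bound in SD units (default 5).
#' @return the filtered data.frame, with the removed bull ids in
#'   `attr(, "removed")`.
#' @export
remove_low_outliers <- function(estimates, k = 5) {
  stopifnot(!is.null(estimates$fertility))
  mu <- base::mean(estimates$fertility)
  s <- stats::sd(estimates$fertility)
  if (s == 0) stop("zero variance in fertility")
  low <- estimates$fertility < mu - k * s
  out <- estimates[!low, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- estimates$bull[low]
  if (any(low))
    message("removed ", sum(low), " low outlier(s): ",
            paste(estimates$bull[low], collapse = ", "))
  out
}

#' Merge per-cohort fertility estimates into a joint mapping phenotype
#'
#' Standardizes the fertility values to zero mean and unit variance within
#' each cohort, then concatenates the cohorts, so cohorts measured on
#' different scales become comparable.
#'
#' @param estimates data.frame with columns `bull` (or `id`), `fertility`
#'   and `cohort`; or a named list of per-cohort data.frames.
#' @return data.frame phenotype table: `id`, `y`, `cohort`.
#' @export
merge_cohorts <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(names(estimates), function(cn) {
      e <- estimates[[cn]]
      e$cohort <- cn
      e
    }))
  }
  stopifnot(!is.null(estimates$cohort), !is.null(estimates$fertility))
  id <- if (!is.null(estimates$bull)) estimates$bull else estimates$id
  sizes <- table(estimates$cohort)
  if (any(sizes < 2))
    stop("singleton cohort(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  z <- stats::ave(estimates$fertility, estimates$cohort,
                  FUN = function(v) (v - mean(v)) / stats::sd(v))
  data.frame(id = id, y = z, cohort = estimates$cohort,
             stringsAsFactors = FALSE)
}

#' Homozygous load across QTL
#'
#' Counts, per bull, at how many of the QTL it is a homozygous carrier of
#' the fertility-decreasing top haplotype, and tallies bulls by load class.
#'
#' @param statuses list of carrier-status data.frames (`id`, `copies`), one
#'   per QTL, all covering the same bulls.
#' @return list with `load` (data.frame: `id`, `load`) and `tally` (named
#'   integer vector over load classes `0..n_qtl`).
#' @export
homozygous_load <- function(statuses) {
  stopifnot(length(statuses) >= 1)
  ids <- statuses[[1]]$id
  H <- vapply(statuses, function(s) {
    m <- match(ids, s$id)
    if (anyNA(m)) stop("carrier-status id mismatch across QTL")
    as.integer(s$copies[m] == 2L)
  }, integer(length(ids)))
  load <- if (is.matrix(H)) rowSums(H) else H
  tally <- table(factor(load, levels = 0:length(statuses)))
  list(load = data.frame(id = ids, load = as.integer(load),
                         stringsAsFactors = FALSE),
       tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Welch two-sample t-test between load groups
#'
#' Two-tailed unequal-variance t-test comparing, e.g., the non-return rate
#' of bulls free of homozygous haplotypes against bulls homozygous for at
#' least one.
#'
#' @param a,b numeric value vectors for the two groups (each of length >= 2).
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
load_contrast_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = NA_real_, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Welch t-test from summary statistics
#'
#' The same two-tailed unequal-variance test computed from group sizes,
#' means and standard deviations (for published summaries).
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 group summaries.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_summary_ttest <- function(n1, mean1, sd1, n2, mean2, sd2) {
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Heterozygote vs non-carrier contrast
#'
#' Tests whether the phenotype differs between heterozygous carriers and
#' non-carriers, excluding homozygotes: under recessive inheritance this
#' contrast is null. OLS of the phenotype on a heterozygote indicator with
#' principal-component and optional conditional covariates.
#'
#' @param phenotypes data.frame (`id`, `y`).
#' @param status data.frame (`id`, `copies`).
#' @param pcs optional `pcset`.
#' @param conditional optional numeric covariate aligned to `status$id`.
#' @return an `assoc_result` (see [fit_association()]).
#' @export
het_vs_noncarrier_test <- function(phenotypes, status, pcs = NULL,
                                   conditional = NULL) {
  if (!any(status$copies == 0)) stop("no non-carriers in status")
  if (!any(status$copies == 1)) stop("no heterozygotes in status")
  keep <- status$copies < 2
  ids <- status$id[keep]
  C <- build_covariates(status$id, pcs, conditional)
  fit_association(phenotypes, as.numeric(status$copies[keep] == 1),
                  covariates = if (is.null(C)) NULL
                               else C[keep, , drop = FALSE],
                  ids = ids)
}
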