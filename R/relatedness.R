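# Genomic relationship matrix, principal components, Haseman-Elston check.

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / sum(2 p_j (1 - p_j))` with `Z` the allele-frequency-centred
#' dosage matrix, emulating the GRM computed by plink from array SNPs. SNPs
#' with minor allele frequency at or below `maf_min` are excluded (strict
#' "greater than" retention).
#'
#' @param panel a [hap_panel()].
#' @param maf_min minor-allele-frequency exclusion boundary (default 0.005).
#' @param dosage optional precomputed [dosage_matrix()] of the panel, to
#'   avoid rebuilding it for large cohorts.
#' @return A `grm` object: list with `ids`, `K` (symmetric matrix) and
#'   `n_snps` (SNPs used).
#' @export
compute_grm <- function(panel, maf_min = 0.005, dosage = NULL) {
  D <- if (is.null(dosage)) dosage_matrix(panel) else dosage
  p <- colMeans(D) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_min
  if (!any(keep)) stop("no SNPs survive the MAF filter")
  D <- D[, keep, drop = FALSE]
  p <- p[keep]
  storage.mode(D) <- "double"
  # Z Z' for Z = D - 1 v' (v = 2p) without materialising Z:
  # D D' - (Dv) 1' - 1 (Dv)' + (v'v) 1 1'
  v <- 2 * p
  Dv <- as.vector(D %*% v)
  K <- tcrossprod(D)
  K <- K - outer(Dv, rep(1, nrow(D))) - outer(rep(1, nrow(D)), Dv) +
    sum(v * v)
  denom <- sum(2 * p * (1 - p))
  K <- K / denom
  structure(list(ids = panel$ids, K = K, n_snps = sum(keep)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$ids), "individuals from", x$n_snps, "SNPs\n")
  invisible(x)
}

#' Top principal components of a GRM
#'
#' Returns the leading eigenvectors of the genomic relationship matrix
#' (population-structure covariates for the association models). The exact
#' method uses a full symmetric eigen-decomposition; the randomized method is
#' a Halko-style subspace iteration (as used by large-scale PCA tools such as
#' plink2) and is preferred for large cohorts.
#'
#' @param grm a `grm` from [compute_grm()].
#' @param k number of components (default 10).
#' @param method `"exact"` or `"randomized"`.
#' @param iters power iterations for the randomized method.
#' @return A `pcset`: list with `ids`, `vectors` (n x k, orthonormal columns,
#'   descending eigenvalue order) and `values` (eigenvalues).
#' @export
top_pcs <- function(grm, k = 10, method = c("exact", "randomized"),
                    iters = 4) {
  method <- match.arg(method)
  n <- length(grm$ids)
  if (k >= n) stop("k must be smaller than the number of individuals")
  if (method == "exact") {
    e <- eigen(grm$K, symmetric = TRUE)
    vec <- e$vectors[, seq_len(k), drop = FALSE]
    val <- e$values[seq_len(k)]
  } else {
    p <- min(n - k, 10L)
    O <- with_preserved_rng({
      set.seed(length(grm$ids) + grm$n_snps)  # deterministic sketch
      matrix(stats::rnorm(n * (k + p)), n)
    })
    Q <- qr.Q(qr(grm$K %*% O))
    for (i in seq_len(iters)) Q <- qr.Q(qr(grm$K %*% Q))
    B <- crossprod(Q, grm$K %*% Q)
    eB <- eigen(B, symmetric = TRUE)
    vec <- (Q %*% eB$vectors)[, seq_len(k), drop = FALSE]
    val <- eB$values[seq_len(k)]
  }
  rownames(vec) <- grm$ids
  colnames(vec) <- paste0("PC", seq_len(k))
  structure(list(ids = grm$ids, vectors = vec, values = val), class = "pcset")
}

#' @export
print.pcset <- function(x, ...) {
  cat("pcset:", ncol(x$vectors), "components,", length(x$ids),
      "individuals\n")
  invisible(x)
}

#' Haseman-Elston regression of cross-products on relatedness
#'
#' Regresses `y_i * y_j` (phenotypes standardized to unit variance) on the
#' off-diagonal GRM entries `G_ij`; the slope estimates the SNP heritability.
#' Because pairs sharing an individual are correlated, the naive regression
#' standard error is anti-conservative; the reported standard error is a
#' leave-one-individual-out jackknife (the convention of HE/moment
#' estimators), computed in closed form from per-individual sums. Used here
#' as a generator-validation check, not as a substitute for REML variance
#' estimation.
#'
#' @param grm a `grm`.
#' @param phenotypes data.frame with columns `id`, `y`.
#' @return list with `h2` (slope), `se` (jackknife standard error), `ci`
#'   (95 percent interval) and `n_pairs`.
#' @export
he_regression <- function(grm, phenotypes) {
  ids <- grm$ids
  n <- length(ids)
  if (n < 10) stop("need at least 10 individuals")
  m <- match(ids, phenotypes$id)
  if (anyNA(m)) stop("phenotype ids do not cover the GRM ids")
  y <- as.vector(scale(phenotypes$y[m]))
  K <- grm$K
  diag(K) <- 0
  # pair sums over j < k (halved double sums)
  Tx <- sum(K) / 2
  Txx <- sum(K^2) / 2
  Ty <- (sum(y)^2 - sum(y^2)) / 2
  Ky <- as.vector(K %*% y)
  Txy <- sum(y * Ky) / 2
  np <- n * (n - 1) / 2
  slope <- function(sx, sxx, sy, sxy, m_) (sxy - sx * sy / m_) /
    (sxx - sx^2 / m_)
  b <- slope(Tx, Txx, Ty, Txy, np)
  # delete-one-individual sums: pairs involving i
  tx <- rowSums(K)
  txx <- rowSums(K^2)
  ty <- y * (sum(y) - y)
  txy <- y * Ky
  m_i <- np - (n - 1)
  b_i <- slope(Tx - tx, Txx - txx, Ty - ty, Txy - txy, m_i)
  se <- sqrt((n - 1) / n * sum((b_i - mean(b_i))^2))
  list(h2 = b, se = se, ci = b + c(-1, 1) * stats::qnorm(0.975) * se,
       n_pairs = np)
}
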