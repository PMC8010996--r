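# Internal helpers.

# Run `expr` without disturbing the caller's RNG stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}

# Align a phenotype table (id, y) to a reference id order; error on mismatch.
align_phenotypes <- function(phenotypes, ids) {
  if (is.numeric(phenotypes)) {
    if (length(phenotypes) != length(ids))
      stop("phenotype length does not match panel individuals")
    return(as.numeric(phenotypes))
  }
  m <- match(ids, phenotypes$id)
  if (anyNA(m))
    stop("phenotype/panel id mismatch: ",
         paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  as.numeric(phenotypes$y[m])
}

# Covariate matrix from an optional pcset and optional conditional dosage.
build_covariates <- function(ids, pcs = NULL, conditional = NULL) {
  C <- NULL
  if (!is.null(pcs)) {
    m <- match(ids, pcs$ids)
    if (anyNA(m)) stop("principal-component ids do not cover the panel ids")
    C <- pcs$vectors[m, , drop = FALSE]
  }
  if (!is.null(conditional)) {
    if (length(conditional) != length(ids))
      stop("conditional covariate length does not match individuals")
    C <- cbind(C, conditional = as.numeric(conditional))
  }
  C
}
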