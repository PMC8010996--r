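# Readers and writers for the formats the pipeline touches. Coordinates are
# 1-based inclusive everywhere (VCF convention); allele coding is 0 = ref,
# 1 = alt, and haplotype allele strings concatenate these digits in SNP
# order. Input is taken as-is: no strand flipping.

#' Write a panel as a phased VCF
#'
#' Plain-text VCFv4.2 with phased GT fields (`|` separator), one record per
#' SNP, individuals as sample columns.
#'
#' @param panel a [hap_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  n <- length(panel$ids)
  idx <- .hap_rows(n)
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$ids), collapse = "\t")), path)
  for (cn in names(panel$chroms)) {
    ch <- panel$chroms[[cn]]
    H <- ch$H
    gt <- matrix(paste0(t(H[idx$first, , drop = FALSE]), "|",
                        t(H[idx$second, , drop = FALSE])),
                 nrow = ncol(H))
    body <- data.table::data.table(
      CHROM = cn, POS = ch$map$pos, ID = ch$map$snp_id, REF = ch$map$ref,
      ALT = ch$map$alt, QUAL = ".", FILTER = "PASS", INFO = ".",
      FORMAT = "GT")
    body <- cbind(body, data.table::as.data.table(gt))
    data.table::fwrite(body, path, sep = "\t", append = TRUE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a phased VCF into a panel
#'
#' Requires complete, phased, biallelic GT fields: an unphased separator
#' (`/`) or a missing genotype raises an error naming the record, matching
#' the imputed-and-phased input the scan assumes.
#'
#' @param path VCF path.
#' @return A [hap_panel()].
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx)))
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || anyNA(gt)) {
    bad <- if (is.null(gt)) "all" else
      paste0(fx[which(rowSums(is.na(gt)) > 0)[1], "CHROM"], ":",
             fx[which(rowSums(is.na(gt)) > 0)[1], "POS"])
    stop("missing GT field(s) at ", bad, ": panel must be complete")
  }
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    r <- which(rowSums(matrix(unphased, nrow(gt))) > 0)[1]
    stop("unphased genotype at ", fx[r, "CHROM"], ":", fx[r, "POS"])
  }
  bad_code <- !gt %in% c("0|0", "0|1", "1|0", "1|1")
  if (any(bad_code)) {
    r <- which(rowSums(matrix(bad_code, nrow(gt))) > 0)[1]
    stop("non-biallelic or malformed genotype at ",
         fx[r, "CHROM"], ":", fx[r, "POS"])
  }
  ids <- colnames(gt)
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt))
  chrom <- fx[, "CHROM"]
  pos <- as.integer(fx[, "POS"])
  n <- length(ids)
  chroms <- lapply(unique(chrom), function(cn) {
    sel <- which(chrom == cn)
    sel <- sel[order(pos[sel])]
    H <- matrix(0L, 2L * n, length(sel))
    H[seq(1L, 2L * n, by = 2L), ] <- t(a1[sel, , drop = FALSE])
    H[seq(2L, 2L * n, by = 2L), ] <- t(a2[sel, , drop = FALSE])
    list(map = data.frame(snp_id = fx[sel, "ID"], pos = pos[sel],
                          ref = fx[sel, "REF"], alt = fx[sel, "ALT"],
                          stringsAsFactors = FALSE),
         H = H)
  })
  names(chroms) <- unique(chrom)
  hap_panel(ids, chroms)
}

#' Read a typed TSV against a schema
#'
#' @param path TSV path with a header row.
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"double"`, `"logical"`).
#' @return data.frame with the schema columns coerced to the given types.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  missing <- setdiff(names(schema), names(dt))
  if (length(missing))
    stop("schema mismatch, missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in names(schema)) {
    raw <- dt[[col]]
    val <- switch(schema[[col]],
                  character = raw,
                  integer = suppressWarnings(as.integer(raw)),
                  double = suppressWarnings(as.numeric(raw)),
                  logical = as.logical(raw),
                  stop("unknown schema type: ", schema[[col]]))
    if (schema[[col]] %in% c("integer", "double")) {
      bad <- which(is.na(val) & !is.na(raw) & nzchar(raw) & raw != "NA")
      if (length(bad))
        stop("parse error in column '", col, "', line ", bad[1] + 1L,
             ": '", raw[bad[1]], "'")
    }
    dt[[col]] <- val
  }
  dt[names(schema)]
}

#' Write scan results as TSV
#'
#' Columns: chromosome, window start/stop SNP index and bp, haplotype allele
#' string, frequency, mode, n_hom, beta, se, p.
#'
#' @param scan a `scan_result` or its `results` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(scan, path) {
  res <- if (inherits(scan, "scan_result")) scan$results else scan
  cols <- c("chrom", "start", "end", "start_bp", "end_bp", "allele_string",
            "frequency", "mode", "n_hom", "beta", "se", "p")
  if (nrow(res) == 0) {
    res <- res[cols[cols %in% names(res)]]
    res[setdiff(cols, names(res))] <- list(character())
  }
  data.table::fwrite(res[cols], path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read scan results written by [write_scan_results()]
#'
#' @param path TSV path.
#' @return data.frame of association results.
#' @export
read_scan_results <- function(path) {
  read_table(path, c(chrom = "character", start = "integer",
                     end = "integer", start_bp = "integer",
                     end_bp = "integer", allele_string = "character",
                     frequency = "double", mode = "character",
                     n_hom = "integer", beta = "double", se = "double",
                     p = "double"))
}

#' Write a plain TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
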