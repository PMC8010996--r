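# Ejaculate filter cascade, per-bull semen-quality means, sperm-morphology
# trait derivation and breeding-suitability rules.

# The 16 exclusive defect categories of the breeding soundness examination,
# with their compensatory/non-compensatory and major/minor classification.
#' Sperm defect category map
#'
#' @return data.frame with columns `defect`, `description`, `compensatory`
#'   (logical) and `major` (logical), one row per category 0-15.
#' @export
defect_categories <- function() {
  data.frame(
    defect = 0:15,
    description = c("abnormal head shape", "vacuoles", "condensed DNA",
                    "micro- or macrocephaly", "loose heads",
                    "knobbed acrosome", "detached acrosome", "dag defect",
                    "curled tail", "middle-piece knobbed",
                    "tail abaxially attached", "tail end loop",
                    "cytoplasmic droplet proximal",
                    "cytoplasmic droplet distal", "underdeveloped",
                    "double form"),
    compensatory = c(FALSE, FALSE, FALSE, rep(TRUE, 13)),
    major = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
              FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Ejaculate quality-filter cascade
#'
#' Applies the fresh-semen filters in their fixed order, recording bull and
#' ejaculate counts after each step: collection age strictly between 400 and
#' 1000 days; interval to the preceding ejaculate known (which drops each
#' bull's first ejaculate); volume recorded; no mixed ejaculates; processed
#' ejaculates only; inter-ejaculate interval of at most 8 days; only the
#' first ejaculate per day (earliest collection time, ties by record order);
#' motility at least 70 percent; plausible (integer 0-3) head and tail
#' anomaly scores; at least 15 million sperm per straw and not sex-sorted;
#' collector and handler known; genotype available; finally only bulls with
#' at least 8 surviving ejaculates are retained.
#'
#' @param records ejaculate data.frame as produced by
#'   [simulate_ejaculates()] (fields: `bull`, `day`, `time_s`, `age_days`,
#'   `interval_days`, `volume_ml`, `mixed`, `processed`, `motility_pct`,
#'   `head_score`, `tail_score`, `sperm_per_straw`, `sex_sorted`,
#'   `collector`, `handler`, `genotyped`).
#' @param min_records minimum surviving ejaculates per bull (default 8).
#' @return list with `records` (surviving rows) and `steps` (data.frame:
#'   `step`, `n_bulls`, `n_ejaculates`).
#' @export
filter_ejaculates <- function(records, min_records = 8) {
  needed <- c("bull", "day", "time_s", "age_days", "interval_days",
              "volume_ml", "mixed", "processed", "motility_pct",
              "head_score", "tail_score", "sperm_per_straw", "sex_sorted",
              "collector", "handler", "genotyped")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("unknown/missing fields: ", paste(missing, collapse = ", "))
  steps <- list()
  note <- function(r, label) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = label, n_bulls = length(unique(r$bull)), n_ejaculates = nrow(r),
      stringsAsFactors = FALSE)
    r
  }
  r <- note(records, "raw data")
  r <- note(r[r$age_days > 400 & r$age_days < 1000, ],
            "age at collection > 400 and < 1000 days")
  r <- note(r[!is.na(r$interval_days), ],
            "interval to preceding ejaculate known")
  r <- note(r[!is.na(r$volume_ml), ], "ejaculate volume recorded")
  r <- note(r[!r$mixed, ], "no mixed ejaculates")
  r <- note(r[r$processed, ], "only processed ejaculates")
  r <- note(r[r$interval_days <= 8, ], "interval between ejaculates <= 8 days")
  ord <- order(r$bull, r$day, r$time_s, seq_len(nrow(r)))
  r <- r[ord, ]
  first <- !duplicated(r[, c("bull", "day")])
  r <- note(r[first, ], "only first ejaculate per day")
  r <- note(r[r$motility_pct >= 70, ], "sperm motility >= 70%")
  plaus <- function(s) !is.na(s) & s %in% 0:3
  r <- note(r[plaus(r$head_score) & plaus(r$tail_score), ],
            "anomaly score plausible")
  r <- note(r[r$sperm_per_straw >= 15 & !r$sex_sorted, ],
            "sperm per straw >= 15 million (not sorted for sex)")
  r <- note(r[!is.na(r$collector) & !is.na(r$handler), ],
            "semen collector and bull handler known")
  r <- note(r[r$genotyped, ], "genotype available")
  counts <- table(r$bull)
  keep_bulls <- names(counts)[counts >= min_records]
  r <- note(r[r$bull %in% keep_bulls, ],
            paste0(">= ", min_records, " records per bull"))
  rownames(r) <- NULL
  list(records = r, steps = do.call(rbind, steps))
}

#' Per-bull mean semen-quality traits
#'
#' Arithmetic means of the quantitative ejaculate fields per bull, over
#' already-filtered records; bulls with fewer than `min_records` records are
#' excluded.
#'
#' @param records filtered ejaculate data.frame.
#' @param min_records minimum records per bull (default 8).
#' @return data.frame: `bull`, `n_ejaculates`, and mean `volume_ml`,
#'   `concentration`, `motility_pct`, `sperm_per_straw`, `head_score`,
#'   `tail_score`.
#' @export
bull_mean_traits <- function(records, min_records = 8) {
  counts <- table(records$bull)
  keep <- names(counts)[counts >= min_records]
  r <- records[records$bull %in% keep, , drop = FALSE]
  fields <- c("volume_ml", "concentration", "motility_pct",
              "sperm_per_straw", "head_score", "tail_score")
  fields <- intersect(fields, names(r))
  agg <- stats::aggregate(r[fields], by = list(bull = r$bull), FUN = mean)
  agg <- cbind(agg[1],
               n_ejaculates = as.integer(counts[agg$bull]),
               agg[-1])
  agg[order(agg$bull), , drop = FALSE]
}

#' Derive per-bull sperm-morphology traits
#'
#' Converts per-ejaculate defect counts into percentages of assessed sperm
#' and averages them per bull. Exams in which fewer than `min_assessed`
#' spermatozoa were classified (evident failures are scored on only 50) are
#' excluded from the proportion traits but still counted in the
#' examination-number trait. Aggregates follow the defect-category map:
#' normal = assessed - sum of defects; non-compensatory = categories 0-2;
#' compensatory = 3-15; major = \{0,1,2,5,7,8,9,12,14\}; minor the rest;
#' the head-shape trait is category 0 alone.
#'
#' @param exams data.frame from [simulate_morphology()] (`bull`, `exam`,
#'   `assessed`, `defect_0` ... `defect_15`).
#' @param min_assessed minimum sperm classified per exam (default 150).
#' @return data.frame, one row per bull: `n_exams` (all exams),
#'   `n_exams_assessed` (exams entering proportions; 0 rows with no such
#'   exam are dropped from proportion columns), `pct_normal`,
#'   `pct_defect_0` ... `pct_defect_15`, `pct_major`, `pct_minor`,
#'   `pct_compensatory`, `pct_non_compensatory`, `pct_head_shape`.
#' @export
derive_morphology_traits <- function(exams, min_assessed = 150) {
  dcols <- paste0("defect_", 0:15)
  stopifnot(all(c("bull", "assessed", dcols) %in% names(exams)))
  defects <- as.matrix(exams[dcols])
  if (any(rowSums(defects) > exams$assessed))
    stop("defect counts exceed assessed sperm")
  cat_map <- defect_categories()
  n_all <- stats::aggregate(list(n_exams = exams$bull),
                            by = list(bull = exams$bull), FUN = length)
  ok <- exams$assessed >= min_assessed
  if (!any(ok)) {
    out <- n_all
    out$n_exams_assessed <- 0L
    return(out[order(out$bull), , drop = FALSE])
  }
  sub <- exams[ok, , drop = FALSE]
  d <- as.matrix(sub[dcols])
  pct <- 100 * d / sub$assessed
  colnames(pct) <- paste0("pct_", dcols)
  per_exam <- data.frame(
    bull = sub$bull,
    pct_normal = 100 * (sub$assessed - rowSums(d)) / sub$assessed,
    pct,
    pct_major = rowSums(pct[, cat_map$major, drop = FALSE]),
    pct_minor = rowSums(pct[, !cat_map$major, drop = FALSE]),
    pct_compensatory = rowSums(pct[, cat_map$compensatory, drop = FALSE]),
    pct_non_compensatory = rowSums(pct[, !cat_map$compensatory,
                                       drop = FALSE]),
    pct_head_shape = pct[, "pct_defect_0"],
    stringsAsFactors = FALSE)
  means <- stats::aggregate(per_exam[-1], by = list(bull = per_exam$bull),
                            FUN = mean)
  n_ok <- stats::aggregate(list(n_exams_assessed = sub$bull),
                           by = list(bull = sub$bull), FUN = length)
  out <- merge(merge(n_all, n_ok, by = "bull", all.x = TRUE), means,
               by = "bull", all.x = TRUE)
  out$n_exams_assessed[is.na(out$n_exams_assessed)] <- 0L
  out[order(out$bull), , drop = FALSE]
}

#' Breeding-suitability classification from morphology aggregates
#'
#' A bull's semen is `suitable` with at least 75 percent normal sperm and at
#' most 20 percent non-compensatory defects; with 65 to just under 75
#' percent normal sperm (and still at most 20 percent non-compensatory) the
#' ejaculates are processed but the reduced quality is compensated with more
#' sperm per dose; anything else fails. The examination is `passed` at 65
#' percent normal or more with at most 20 percent non-compensatory defects.
#'
#' @param pct_normal,pct_non_compensatory percentages in `[0, 100]`
#'   (vectorized).
#' @return data.frame with `category` (factor: `suitable`,
#'   `process_with_compensation`, `fail`) and `passed` (logical).
#' @export
breeding_suitability <- function(pct_normal, pct_non_compensatory) {
  stopifnot(length(pct_normal) == length(pct_non_compensatory),
            all(pct_normal >= 0 & pct_normal <= 100),
            all(pct_non_compensatory >= 0 & pct_non_compensatory <= 100))
  nc_ok <- pct_non_compensatory <= 20
  category <- ifelse(pct_normal >= 75 & nc_ok, "suitable",
                     ifelse(pct_normal >= 65 & nc_ok,
                            "process_with_compensation", "fail"))
  data.frame(category = factor(category,
                               levels = c("suitable",
                                          "process_with_compensation",
                                          "fail")),
             passed = pct_normal >= 65 & nc_ok)
}
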