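# Scoring imputed allotypes against truth: balanced accuracy, precision,
# recall per HLA unit, and per-locus summaries.

#' Evaluate imputed carriership against true allotypes
#'
#' For each imputed unit, compares the carriership calls against the true
#' allotypes over the overlapping samples (restricted, per unit, to samples
#' typed at its locus). Units whose carriership frequency in the truth set
#' falls below `min_freq` are excluded. Balanced accuracy is
#' (TP/(TP+FN) + TN/(TN+FP)) / 2; precision is reported as `NA` (undefined,
#' not 0) when no positive calls were made.
#'
#' @param truth an `hla_cohort` or named list of [hla_allotype()] objects.
#' @param imputed long data.frame from [impute_cohort()] (needs
#'   `sample_id`, `unit`, `called`).
#' @param min_freq truth-side carriership-frequency filter (default 0.05).
#' @return data.frame with one row per evaluated unit: `unit`, `locus`,
#'   `n`, `TP`, `FP`, `TN`, `FN`, `balanced_accuracy`, `precision`,
#'   `recall`, `test_frequency`.
#' @export
evaluate_imputation <- function(truth, imputed, min_freq = 0.05) {
  allot <- if (inherits(truth, "hla_cohort")) truth$allotypes else truth
  common <- intersect(names(allot), unique(imputed$sample_id))
  if (!length(common)) stop("no overlapping samples between truth and imputation")
  allot <- allot[common]
  units <- sort(unique(imputed$unit))
  rows <- lapply(units, function(u) {
    locus <- hla_unit_locus(u)
    typed <- names(allot)[vapply(allot, function(a) locus %in% a$typed_loci,
                                 logical(1))]
    if (!length(typed)) return(NULL)
    truth_carrier <- vapply(allot[typed], function(a) u %in% a$units,
                            logical(1))
    freq <- mean(truth_carrier)
    if (freq < min_freq) return(NULL)
    sub <- imputed[imputed$unit == u & imputed$sample_id %in% typed, ,
                   drop = FALSE]
    pred <- sub$called[match(typed, sub$sample_id)]
    tp <- sum(pred & truth_carrier); fp <- sum(pred & !truth_carrier)
    fn <- sum(!pred & truth_carrier); tn <- sum(!pred & !truth_carrier)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    data.frame(
      unit = u, locus = locus, n = length(typed),
      TP = tp, FP = fp, TN = tn, FN = fn,
      balanced_accuracy = mean(c(sens, spec), na.rm = TRUE),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = sens, test_frequency = freq,
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(unit = character(0), locus = character(0),
                      n = integer(0), TP = integer(0), FP = integer(0),
                      TN = integer(0), FN = integer(0),
                      balanced_accuracy = numeric(0), precision = numeric(0),
                      recall = numeric(0), test_frequency = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise unit evaluations per locus
#'
#' Medians and means of balanced accuracy, precision and recall grouped by
#' locus; undefined precisions (`NA`) are excluded from the summaries.
#'
#' @param evaluations data.frame from [evaluate_imputation()].
#' @return data.frame with one row per locus.
#' @export
summarize_evaluation <- function(evaluations) {
  stopifnot(nrow(evaluations) >= 1L)
  groups <- split(evaluations, evaluations$locus)
  rows <- lapply(groups, function(g) {
    data.frame(
      locus = g$locus[1L], n_units = nrow(g),
      median_balanced_accuracy = stats::median(g$balanced_accuracy),
      mean_balanced_accuracy = mean(g$balanced_accuracy),
      median_precision = stats::median(g$precision, na.rm = TRUE),
      mean_precision = mean(g$precision, na.rm = TRUE),
      median_recall = stats::median(g$recall),
      mean_recall = mean(g$recall),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$locus), , drop = FALSE]
}
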