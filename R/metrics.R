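#' Confusion counts from truth and prediction vectors
#'
#' @param truth,predicted Integer 0/1 vectors (1 = antioxidant, the positive
#'   class).
#' @return A list of class `aodeep_confusion` with fields `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c(0, 1)), all(predicted %in% c(0, 1)))
  structure(list(TP = sum(truth == 1 & predicted == 1),
                 FP = sum(truth == 0 & predicted == 1),
                 TN = sum(truth == 0 & predicted == 0),
                 FN = sum(truth == 1 & predicted == 0)),
            class = "aodeep_confusion")
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity `Sn = TP/(TP+FN)` (recall of positives), specificity
#' `Sp = TN/(TN+FP)`, accuracy, precision `TP/(TP+FP)`, the F1 score (the
#' harmonic mean of precision and sensitivity) and the Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' A statistic whose denominator is zero is reported as `NA` and flagged in
#' the `undefined` column — never coerced to 0.
#'
#' @param counts An `aodeep_confusion` (or list with TP/FP/TN/FN).
#' @return A one-row tibble: `TP`, `FP`, `TN`, `FN`, `Sn`, `Sp`, `Acc`,
#'   `precision`, `F1`, `MCC`, `undefined` (comma-separated names of
#'   undefined statistics, `""` if none).
#' @examples
#' compute_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0))
    abort("Confusion counts must be non-negative.", class = "aodeep_validation_error")
  total <- TP + FP + TN + FN
  if (total == 0)
    abort("Empty evaluation: all confusion counts are zero.",
          class = "aodeep_empty_input_error")

  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  Sn <- safe_div(TP, TP + FN)
  Sp <- safe_div(TN, TN + FP)
  Acc <- (TP + TN) / total
  precision <- safe_div(TP, TP + FP)
  F1 <- if (is.na(precision) || is.na(Sn) || precision + Sn == 0) NA_real_
        else 2 * precision * Sn / (precision + Sn)
  # pair the factors so the denominator is bit-identical under label swap
  # (TP<->TN, FP<->FN); counts are integers, so the products are exact
  mcc_den <- sqrt(((TP + FN) * (TN + FP)) * ((TP + FP) * (TN + FN)))
  MCC <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den

  vals <- c(Sn = Sn, Sp = Sp, Acc = Acc, precision = precision, F1 = F1, MCC = MCC)
  tibble(TP = TP, FP = FP, TN = TN, FN = FN,
         Sn = Sn, Sp = Sp, Acc = Acc, precision = precision, F1 = F1, MCC = MCC,
         undefined = paste(names(vals)[is.na(vals)], collapse = ","))
}

#' Stratified k-fold assignment
#'
#' Partitions sample indices into `k` folds preserving class proportions:
#' fold sizes differ by at most one overall and within each class.
#' Deterministic given the seed.
#'
#' @param labels Integer 0/1 labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1L) {
  if (k < 2) abort("k must be at least 2.", class = "aodeep_config_error")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k))
    abort(sprintf("Each class needs at least k = %d members (have %s).",
                  k, paste(counts, collapse = "/")),
          class = "aodeep_stratification_error")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- sample(which(labels == cls))
      # opposite fill orders so the two classes' remainder folds overlap as
      # little as possible and overall fold sizes differ by at most one
      ord <- if (cls == 0) seq_len(k) else rev(seq_len(k))
      fold[idx] <- rep_len(ord, length(idx))
    }
  })
  fold
}
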