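#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-fold cross-validation metrics
#'
#' @param x An `aodeep_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per fold: confusion counts and
#'   Sn/Sp/Acc/precision/F1/MCC.
#' @export
tidy.aodeep_cv <- function(x, ...) {
  x$per_fold
}

#' One-row summary of a cross-validation run
#'
#' Metrics computed from the confusion counts pooled over all folds, plus
#' the fold count and master seed.
#'
#' @param x An `aodeep_cv` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.aodeep_cv <- function(x, ...) {
  dplyr::mutate(x$pooled, k = x$config$k, seed = x$config$seed)
}

#' Tidy the training history of a feature learner
#'
#' @param x An `aodeep_feature_learner`.
#' @param ... Unused.
#' @return A tibble with columns `phase` (`"pretrain"`/`"finetune"`),
#'   `epoch` and `loss` (weighted reconstruction error, then weighted binary
#'   cross-entropy).
#' @export
tidy.aodeep_feature_learner <- function(x, ...) {
  pre <- if (is.null(x$pretrain_loss)) NULL else
    tibble(phase = "pretrain", epoch = seq_along(x$pretrain_loss),
           loss = as.numeric(x$pretrain_loss))
  fin <- tibble(phase = "finetune", epoch = seq_along(x$finetune_loss),
                loss = x$finetune_loss)
  dplyr::bind_rows(pre, fin)
}

#' @export
print.aodeep_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d), %d samples (%d positive)\n",
              x$config$k, x$config$seed, nrow(x$folds), sum(x$folds$label == 1)))
  cat("Pooled metrics:\n")
  print(as.data.frame(x$pooled[, c("Sn", "Sp", "Acc", "precision", "F1", "MCC")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.aodeep_feature_learner <- function(x, ...) {
  widths <- c(nrow(x$encoder[[1]]$W),
              vapply(c(x$encoder, x$fc), function(l) ncol(l$W), numeric(1)))
  cat("Deep feature learner:", paste(widths, collapse = " - "), "\n")
  cat(sprintf("Final fine-tuning loss: %.6g (%d epochs)\n",
              x$finetune_loss[length(x$finetune_loss)], length(x$finetune_loss)))
  invisible(x)
}
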