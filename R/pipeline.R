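#' Full pipeline configuration
#'
#' Bundles every stage's settings with their published defaults: mixed 0/1-gap
#' features, autoencoder widths 800-650-500-300 with Adadelta, fully connected
#' head 50-25-1 trained at lr 0.0025 / decay 1e-6 / momentum 0.6 / batch 12
#' with dropout 0.2/0.3 and max-norm 3, 6:1 positive sample re-weighting,
#' t-SNE to two dimensions, a linear SVM with C = 2 and 5:1 class weights,
#' and 10-fold cross-validation. Every stage seed is derived from the single
#' master seed.
#'
#' @param gaps Gap values for the feature stage (default `c(0, 1)`).
#' @param ae An [ae_config()].
#' @param ft An [ft_config()].
#' @param tsne A [tsne_config()].
#' @param svm An [svm_config()].
#' @param positive_weight Sample weight of the positive class in both network
#'   losses (default 6; negatives weigh 1).
#' @param k Number of cross-validation folds (default 10).
#' @param seed Master seed.
#' @return A list of class `aodeep_pipeline_config`.
#' @export
pipeline_config <- function(gaps = c(0, 1), ae = ae_config(), ft = ft_config(),
                            tsne = tsne_config(), svm = svm_config(),
                            positive_weight = 6, k = 10, seed = 1L) {
  stopifnot(inherits(ae, "aodeep_ae_config"), inherits(ft, "aodeep_ft_config"),
            inherits(tsne, "aodeep_tsne_config"), inherits(svm, "aodeep_svm_config"))
  if (positive_weight <= 0)
    abort("positive_weight must be positive.", class = "aodeep_config_error")
  if (ae$widths[1] != 400L * length(gaps))
    abort(sprintf("Autoencoder input width %d does not match %d-gap features (%d).",
                  ae$widths[1], length(gaps), 400L * length(gaps)),
          class = "aodeep_config_error")
  structure(list(gaps = as.integer(gaps), ae = ae, ft = ft, tsne = tsne,
                 svm = svm, positive_weight = positive_weight,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "aodeep_pipeline_config")
}

# deterministic sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max, n))
}

train_fold_model <- function(x_train, labels_train, config, ae_seed, ft_seed) {
  w <- sample_weights(labels_train, config$positive_weight)
  ae_cfg <- config$ae; ae_cfg$seed <- ae_seed
  ft_cfg <- config$ft; ft_cfg$seed <- ft_seed
  pre <- pretrain_autoencoder(x_train, w, ae_cfg)
  fine_tune(pre, x_train, labels_train, w, ft_cfg)
}

embed_and_classify <- function(model, x_train, labels_train, x_eval,
                               config, tsne_seed) {
  rep_train <- extract_representation(model, x_train)
  rep_eval <- extract_representation(model, x_eval)
  combined <- rbind(rep_train, rep_eval)
  tags <- rep(c("train", "validation"), c(nrow(rep_train), nrow(rep_eval)))
  ts_cfg <- config$tsne; ts_cfg$seed <- tsne_seed
  emb <- tsne_embed(combined, ts_cfg, partition = tags)
  svm_fit <- train_svm(emb, labels_train, config$svm)
  pred <- predict(svm_fit, emb, rows = "validation")
  list(embedding = emb, svm = svm_fit, predicted = pred)
}

#' Cross-validate the full identification pipeline
#'
#' Runs stratified k-fold cross-validation of the complete pipeline. Within
#' each fold, the autoencoder is pre-trained and the network fine-tuned on
#' the training portion only; 50-dimensional representations of both
#' portions are then embedded jointly with t-SNE (features only — labels of
#' the held-out portion are never touched), the class-weighted linear SVM is
#' trained on the training-tagged points, and the validation points are
#' predicted. Confusion counts are pooled across folds for the headline
#' metrics; per-fold metrics are retained. Fully reproducible from the
#' master seed.
#'
#' @param records Tibble with columns `id`, `sequence`, `label` (1 =
#'   antioxidant).
#' @param config A [pipeline_config()].
#' @return An object of class `aodeep_cv`: `pooled` (one-row metrics tibble),
#'   `per_fold` (k-row metrics tibble), `folds` (tibble id/label/fold),
#'   `embeddings` (list of per-fold embedding tibbles), `predictions`
#'   (tibble id/label/fold/predicted), `config`.
#' @export
run_cv <- function(records, config = pipeline_config()) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "label") %in% names(records)))
  labels <- as.integer(records$label)
  seeds <- derive_seeds(config$seed, 1L + 3L * config$k)
  fold <- stratified_folds(labels, config$k, seeds[1])
  features <- featurize(records, config$gaps)
  x <- feature_matrix(features)$x

  fold_results <- vector("list", config$k)
  for (f in seq_len(config$k)) {
    tr <- fold != f
    va <- !tr
    s <- seeds[1L + (f - 1L) * 3L + 1:3]
    model <- tryCatch(
      train_fold_model(x[tr, , drop = FALSE], labels[tr], config, s[1], s[2]),
      error = function(e) abort(sprintf("Fold %d training failed: %s",
                                        f, conditionMessage(e)),
                                class = "aodeep_fold_error"))
    stage <- embed_and_classify(model, x[tr, , drop = FALSE], labels[tr],
                                x[va, , drop = FALSE], config, s[3])
    truth <- labels[va]
    pred <- stage$predicted$predicted[match(records$id[va], stage$predicted$id)]
    fold_results[[f]] <- list(
      counts = confusion_counts(truth, pred),
      embedding = stage$embedding,
      predictions = tibble(id = records$id[va], label = truth,
                           fold = f, predicted = pred))
  }

  per_fold <- purrr::map_dfr(seq_len(config$k), function(f)
    dplyr::mutate(compute_metrics(fold_results[[f]]$counts), fold = f,
                  .before = 1))
  pooled_counts <- structure(list(
    TP = sum(per_fold$TP), FP = sum(per_fold$FP),
    TN = sum(per_fold$TN), FN = sum(per_fold$FN)), class = "aodeep_confusion")
  structure(list(pooled = compute_metrics(pooled_counts),
                 per_fold = per_fold,
                 folds = tibble(id = records$id, label = labels, fold = fold),
                 embeddings = lapply(fold_results, `[[`, "embedding"),
                 predictions = purrr::map_dfr(fold_results, `[[`, "predictions"),
                 config = config),
            class = "aodeep_cv")
}

#' Train the identification model on a full dataset
#'
#' Featurizes, pre-trains the autoencoder, fine-tunes the network and stores
#' the training representations so new sequences can later be embedded
#' transductively alongside them.
#'
#' @param records Tibble with `id`, `sequence`, `label`.
#' @param config A [pipeline_config()].
#' @return An object of class `aodeep_model`: `learner`, `representation`
#'   (training rows), `labels`, `ids`, `config`.
#' @export
train_model <- function(records, config = pipeline_config()) {
  labels <- as.integer(records$label)
  seeds <- derive_seeds(config$seed, 2L)
  x <- feature_matrix(featurize(records, config$gaps))$x
  learner <- train_fold_model(x, labels, config, seeds[1], seeds[2])
  structure(list(learner = learner,
                 representation = extract_representation(learner, x),
                 labels = labels, ids = records$id, config = config),
            class = "aodeep_model")
}

#' Predict antioxidant labels for new sequences
#'
#' t-SNE has no out-of-sample mapping, so the stored training
#' representations and the new sequences' representations are embedded
#' jointly; the SVM is then trained on the training-tagged points (with the
#' stored labels) and applied to the new points.
#'
#' @param object An [train_model()] result.
#' @param records Tibble of new sequences (`id`, `sequence`).
#' @param seed Seed for the joint embedding (default: derived from the
#'   model's master seed).
#' @param ... Unused.
#' @return Tibble with `id`, `predicted` (1 = antioxidant), `dim1`, `dim2`.
#' @export
predict.aodeep_model <- function(object, records, seed = NULL, ...) {
  config <- object$config
  if (is.null(seed)) seed <- derive_seeds(config$seed, 3L)[3]
  x_new <- feature_matrix(featurize(records, config$gaps))$x
  rep_new <- extract_representation(object$learner, x_new)
  combined <- rbind(object$representation, rep_new)
  tags <- rep(c("train", "validation"),
              c(nrow(object$representation), nrow(rep_new)))
  ts_cfg <- config$tsne; ts_cfg$seed <- as.integer(seed)
  emb <- tsne_embed(combined, ts_cfg, partition = tags)
  svm_fit <- train_svm(emb, object$labels, config$svm)
  pred <- predict(svm_fit, emb, rows = "validation")
  coords <- emb[emb$partition == "validation", c("dim1", "dim2")]
  dplyr::bind_cols(pred, coords)
}
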