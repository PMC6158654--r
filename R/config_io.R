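## YAML configuration handling and run manifests.

config_to_list <- function(config) {
  list(gaps = as.integer(config$gaps),
       ae = unclass(config$ae)[setdiff(names(config$ae), "seed")],
       ft = unclass(config$ft)[setdiff(names(config$ft), "seed")],
       tsne = unclass(config$tsne)[setdiff(names(config$tsne), "seed")],
       svm = list(C = config$svm$C,
                  class_weight = as.list(config$svm$class_weight)),
       positive_weight = config$positive_weight,
       k = config$k, seed = config$seed)
}

#' Load a pipeline configuration from a YAML file
#'
#' Omitted keys take the published defaults; unknown keys are rejected so a
#' typo cannot silently fall back to a default. An empty file yields the
#' default configuration (C = 2, lr = 0.0025, 6:1 sample weights, ...).
#'
#' @param path Path to a YAML file (may be empty).
#' @param seed Optional master-seed override (e.g. from a CLI flag).
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path, seed = NULL) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    abort(sprintf("Config file not found: %s", path), class = "aodeep_io_error")
  if (is.null(raw)) raw <- list()
  known <- c("gaps", "ae", "ft", "tsne", "svm", "positive_weight", "k", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "aodeep_validation_error")
  check_sub <- function(sub, fn, name) {
    sub <- if (is.null(sub)) list() else sub
    bad <- setdiff(names(sub), names(formals(fn)))
    if (length(bad) > 0)
      abort(sprintf("Unknown %s config key(s): %s", name, paste(bad, collapse = ", ")),
            class = "aodeep_validation_error")
    sub
  }
  svm_sub <- check_sub(raw$svm, svm_config, "svm")
  if (!is.null(svm_sub$class_weight)) svm_sub$class_weight <- unlist(svm_sub$class_weight)
  args <- list(
    ae = do.call(ae_config, check_sub(raw$ae, ae_config, "ae")),
    ft = do.call(ft_config, check_sub(raw$ft, ft_config, "ft")),
    tsne = do.call(tsne_config, check_sub(raw$tsne, tsne_config, "tsne")),
    svm = do.call(svm_config, svm_sub))
  if (!is.null(raw$gaps)) args$gaps <- raw$gaps
  if (!is.null(raw$positive_weight)) args$positive_weight <- raw$positive_weight
  if (!is.null(raw$k)) args$k <- raw$k
  if (!is.null(seed)) args$seed <- seed else if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(pipeline_config, args)
}

# FNV-1a over the serialized resolved config; a compact provenance tag for
# output files (not a cryptographic hash)
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(yaml::as.yaml(config_to_list(config))))
  h <- 0x811c9dc5 %% 2^31
  for (b in bytes) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2^31  # products stay exact in doubles (< 2^53)
  }
  sprintf("%08x", as.integer(h))
}

write_tsv_stamped <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d  config: %s", config$seed, config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline end-to-end and write a report directory
#'
#' Executes the four stages in order — feature extraction, autoencoder
#' pre-training + fine-tuning, t-SNE embedding, SVM classification — inside
#' the stratified cross-validation harness, and writes `metrics_pooled.tsv`,
#' `metrics_per_fold.tsv`, `folds.tsv`, `predictions.tsv`, per-fold
#' `embedding_fold<k>.tsv` files and a YAML `manifest.yaml` (resolved config,
#' master seed, config hash, stage order) to `out_dir`. Every tabular output
#' carries the master seed and config hash on a leading comment line.
#'
#' @param records Tibble with `id`, `sequence`, `label` — e.g. from
#'   [read_fasta()] joined with [read_labels()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [run_cv()] result, invisibly.
#' @export
run_end_to_end <- function(records, config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cv <- run_cv(records, config)
  write_tsv_stamped(cv$pooled, file.path(out_dir, "metrics_pooled.tsv"), config)
  write_tsv_stamped(cv$per_fold, file.path(out_dir, "metrics_per_fold.tsv"), config)
  write_tsv_stamped(cv$folds, file.path(out_dir, "folds.tsv"), config)
  write_tsv_stamped(cv$predictions, file.path(out_dir, "predictions.tsv"), config)
  for (f in seq_along(cv$embeddings))
    write_tsv_stamped(as.data.frame(cv$embeddings[[f]]),
                      file.path(out_dir, sprintf("embedding_fold%02d.tsv", f)),
                      config)
  manifest <- list(stages = c("ggap_features", "deep_feature_learning",
                              "tsne_embedding", "svm_classification"),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   config = config_to_list(config),
                   n_records = nrow(records),
                   n_positive = sum(records$label == 1),
                   package_version = as.character(utils::packageVersion("aodeep")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(cv)
}

#' Attach labels to sequence records
#'
#' Joins a record tibble with a label tibble by `id`, failing loudly on any
#' record without a label.
#'
#' @param records Tibble with `id`, `sequence`.
#' @param labels Tibble with `id`, `label` (e.g. [read_labels()]).
#' @return `records` with a `label` column.
#' @export
attach_labels <- function(records, labels) {
  out <- dplyr::left_join(records, labels, by = "id")
  missing <- out$id[is.na(out$label)]
  if (length(missing) > 0)
    abort(sprintf("No label for record(s): %s", paste(missing, collapse = ", ")),
          class = "aodeep_validation_error")
  out
}
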