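# Shared fixtures: everything is generated in code at test time.

# random valid protein sequence of length L
random_sequence <- function(L) {
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

random_records <- function(n, len_range = c(10, 80)) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  tibble::tibble(id = sprintf("r%03d", seq_len(n)),
                 sequence = vapply(lens, random_sequence, character(1)))
}

# naive double-loop g-gap dipeptide counter, independent of the package path
oracle_ggap_counts <- function(sequence, g) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  counts <- integer(400)
  for (p in seq_len(L - g - 1)) {
    i <- match(chars[p], AA_ALPHABET)
    j <- match(chars[p + g + 1], AA_ALPHABET)
    k <- 20L * (i - 1L) + j
    counts[k] <- counts[k] + 1L
  }
  counts
}

# metrics recomputed from reconstructed label vectors, not from the formulas:
# Sn/Sp/Acc as conditional means of indicator vectors, MCC as the Pearson
# correlation of the binary truth/prediction vectors, F1 as 2TP/(2TP+FP+FN)
oracle_metrics <- function(TP, FP, TN, FN) {
  truth <- rep(c(1, 1, 0, 0), c(TP, FN, TN, FP))
  pred <- rep(c(1, 0, 0, 1), c(TP, FN, TN, FP))
  list(Sn = if (TP + FN > 0) mean(pred[truth == 1]) else NA_real_,
       Sp = if (TN + FP > 0) mean(1 - pred[truth == 0]) else NA_real_,
       Acc = mean(truth == pred),
       precision = if (TP + FP > 0) mean(truth[pred == 1]) else NA_real_,
       # harmonic mean is undefined when precision + Sn = 0, i.e. TP = 0
       F1 = if (TP > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_,
       MCC = suppressWarnings(stats::cor(truth, pred)))
}

# small featurized training set with a planted class difference, for network
# tests that need a learnable signal without the full benchmark size
small_training_set <- function(n_pos = 10, n_neg = 40, seed = 42,
                               bias_strength = 8, len = c(40, 120)) {
  sim <- simulate_proteins(sim_config(n_positive = n_pos, n_negative = n_neg,
                                      length_range = len,
                                      bias_strength = bias_strength,
                                      seed = seed))
  x <- feature_matrix(featurize(sim$records))$x
  list(x = x, labels = sim$records$label,
       weights = sample_weights(sim$records$label), records = sim$records)
}
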