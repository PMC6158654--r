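## Exact t-SNE (quadratic in n). Dataset sizes in this pipeline are a few
## hundred points per cross-validation fold, where the exact algorithm is
## both fast and free of the approximation knobs of tree-based variants.

# per-point conditional probabilities at the target perplexity via binary
# search over the Gaussian bandwidth (precision beta = 1/(2 sigma^2))
tsne_input_probabilities <- function(d2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- d2[i, -i]
    for (iter in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p == 0) p <- rep(1 / length(di), length(di)) else p <- p / sum_p
      h <- -sum(p[p > 0] * log(p[p > 0]))  # Shannon entropy
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {           # entropy too high -> narrow the kernel
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

#' Settings for the t-SNE stage
#'
#' @param perplexity Target perplexity of the conditional Gaussian
#'   neighbourhoods (default 30); requires `n > 3 * perplexity`.
#' @param iterations Gradient-descent iterations (default 1000).
#' @param seed Integer seed for the random initial layout.
#' @return A list of class `aodeep_tsne_config`.
#' @export
tsne_config <- function(perplexity = 30, iterations = 1000, seed = 1L) {
  if (perplexity <= 1 || iterations < 1)
    abort("perplexity must exceed 1 and iterations be positive.",
          class = "aodeep_config_error")
  structure(list(perplexity = perplexity, iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "aodeep_tsne_config")
}

#' Embed a representation matrix in two dimensions with t-SNE
#'
#' Standard exact t-SNE: symmetrised input affinities at the configured
#' perplexity, Student-t similarities in the plane, Kullback-Leibler gradient
#' descent with early exaggeration (factor 12 for the first quarter of the
#' iterations), momentum 0.5 switching to 0.8, and per-parameter gain
#' adaptation. Deterministic given the seed. t-SNE has no out-of-sample
#' mapping, so held-out points must be embedded jointly with the training
#' points (see [run_cv()] for the transductive fold workflow).
#'
#' @param x Numeric matrix (rows = points, e.g. the 50-dim learned
#'   representation). Row names, if present, become point ids.
#' @param config A [tsne_config()].
#' @param partition Optional character/factor tag per row (e.g. `"train"` /
#'   `"validation"`), recorded in the result.
#' @return A tibble of class `aodeep_embedding` with columns `id`, `dim1`,
#'   `dim2` and `partition`; the settings used are attached as attribute
#'   `settings`.
#' @export
tsne_embed <- function(x, config = tsne_config(), partition = NULL) {
  stopifnot(inherits(config, "aodeep_tsne_config"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (any(!is.finite(x)))
    abort("Representation contains non-finite values.", class = "aodeep_validation_error")
  if (n <= 3 * config$perplexity)
    abort(sprintf(
      "t-SNE needs n > 3 * perplexity (n = %d, perplexity = %g); use a smaller perplexity.",
      n, config$perplexity), class = "aodeep_feasibility_error")
  if (!is.null(partition)) stopifnot(length(partition) == n)

  d2 <- as.matrix(stats::dist(x))^2
  P <- tsne_input_probabilities(d2, config$perplexity)
  P <- (P + t(P)) / (2 * n)            # symmetrise to joint probabilities
  P <- pmax(P, 1e-12)

  exaggeration <- 12
  exag_iters <- max(1L, config$iterations %/% 4L)
  eta <- 200

  with_seed(config$seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    Pe <- P * exaggeration
    for (it in seq_len(config$iterations)) {
      Pi <- if (it <= exag_iters) Pe else P
      momentum <- if (it <= exag_iters) 0.5 else 0.8
      # Student-t similarities
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pi - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    out <- tibble(id = ids, dim1 = Y[, 1], dim2 = Y[, 2],
                  partition = if (is.null(partition)) "all" else as.character(partition))
    attr(out, "settings") <- config
    class(out) <- c("aodeep_embedding", class(out))
    out
  })
}

#' Configuration for the linear support vector machine stage
#'
#' @param C Soft-margin penalty (default 2).
#' @param class_weight Named penalty multipliers for the two classes;
#'   default `c(positive = 5, negative = 1)` counters the class imbalance.
#' @return A list of class `aodeep_svm_config`.
#' @export
svm_config <- function(C = 2, class_weight = c(positive = 5, negative = 1)) {
  if (C <= 0) abort("C must be positive.", class = "aodeep_config_error")
  if (length(class_weight) != 2 || any(class_weight <= 0))
    abort("class_weight must be two positive values.", class = "aodeep_config_error")
  cw <- stats::setNames(as.numeric(class_weight), names(class_weight))
  structure(list(C = as.numeric(C), class_weight = cw),
            class = "aodeep_svm_config")
}

#' Train the class-weighted linear SVM on a 2-D embedding
#'
#' Fits a linear-kernel support vector machine on the training-tagged rows of
#' the embedding; the decision rule is the sign of an affine function of the
#' two embedding coordinates. Class penalties default to 5:1
#' (positive:negative).
#'
#' @param embedding An `aodeep_embedding` (or any data frame with `dim1`,
#'   `dim2` and `partition`).
#' @param labels Integer 0/1 labels aligned with the training-tagged rows
#'   (or with all rows, in which case the training subset is taken).
#' @param config An [svm_config()].
#' @return A list of class `aodeep_svm` with elements `fit` (the e1071
#'   model) and `config`.
#' @export
train_svm <- function(embedding, labels, config = svm_config()) {
  stopifnot(inherits(config, "aodeep_svm_config"))
  train_rows <- embedding$partition %in% c("train", "all")
  xy <- as.matrix(embedding[train_rows, c("dim1", "dim2")])
  y <- if (length(labels) == nrow(embedding)) labels[train_rows] else labels
  if (length(y) != nrow(xy))
    abort("Label length matches neither the embedding nor its training rows.",
          class = "aodeep_validation_error")
  if (length(unique(y)) < 2)
    abort("SVM training needs both classes.", class = "aodeep_degenerate_error")
  fit <- e1071::svm(xy, factor(y, levels = c(0, 1)),
                    kernel = "linear", cost = config$C, scale = FALSE,
                    class.weights = c("1" = unname(config$class_weight[1]),
                                      "0" = unname(config$class_weight[2])))
  structure(list(fit = fit, config = config), class = "aodeep_svm")
}

#' Predict class labels for embedding points
#'
#' @param object An `aodeep_svm`.
#' @param embedding An embedding tibble; by default only
#'   validation/evaluation-tagged rows are predicted (set `rows = "all"` for
#'   every row).
#' @param rows `"validation"`, `"train"` or `"all"`.
#' @param ... Unused.
#' @return Tibble with columns `id` and `predicted` (integer 0/1).
#' @export
predict.aodeep_svm <- function(object, embedding, rows = c("validation", "train", "all"), ...) {
  rows <- match.arg(rows)
  keep <- switch(rows,
                 all = rep(TRUE, nrow(embedding)),
                 embedding$partition %in% c(rows, "all"))
  xy <- as.matrix(embedding[keep, c("dim1", "dim2")])
  pred <- stats::predict(object$fit, xy)
  tibble(id = embedding$id[keep],
         predicted = as.integer(as.character(pred)))
}
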