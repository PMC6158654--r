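## Dense-network machinery for the autoencoder and the fine-tuned classifier.
## Everything is plain matrices + BLAS: layers are (W: in x out, b: out),
## forward activations row-wise, and the two optimizers the training scheme
## calls for (Adadelta for reconstruction pre-training, mini-batch SGD with
## momentum/decay for supervised fine-tuning).

activate <- function(z, fun) {
  switch(fun,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z,
         abort(sprintf("Unknown activation '%s'", fun)))
}

# derivative wrt pre-activation, expressed through the activation value a
activate_grad <- function(a, fun) {
  switch(fun,
         relu = (a > 0) * 1,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         linear = array(1, dim(a)))
}

new_layer <- function(n_in, n_out, activation, init = c("glorot", "uniform005"),
                      name = "") {
  init <- match.arg(init)
  if (init == "glorot") {
    lim <- sqrt(6 / (n_in + n_out))
    W <- matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  } else {
    W <- matrix(stats::runif(n_in * n_out, -0.05, 0.05), n_in, n_out)
  }
  list(W = W, b = numeric(n_out), activation = activation, name = name)
}

# forward pass through a list of layers; returns activations per layer
# (index 1 = input). dropout_rates, when given, is aligned with `layers` and
# applies inverted dropout to that layer's *output*.
nn_forward <- function(layers, x, dropout_rates = NULL, training = FALSE) {
  acts <- vector("list", length(layers) + 1L)
  masks <- vector("list", length(layers))
  acts[[1]] <- x
  for (l in seq_along(layers)) {
    z <- acts[[l]] %*% layers[[l]]$W
    add_bias(z, layers[[l]]$b)  # in place; z is freshly allocated
    a <- activate(z, layers[[l]]$activation)
    p <- if (is.null(dropout_rates)) 0 else dropout_rates[l]
    if (training && p > 0) {
      m <- matrix(stats::rbinom(length(a), 1L, 1 - p), nrow(a), ncol(a)) / (1 - p)
      a <- a * m
      masks[[l]] <- m
    }
    acts[[l + 1L]] <- a
  }
  list(acts = acts, masks = masks)
}

# backprop given d(loss)/d(output activation) or, when delta_is_dz = TRUE,
# d(loss)/d(pre-activation) of the last layer (the stable sigmoid+BCE path).
nn_backward <- function(layers, fwd, dout, delta_is_dz = FALSE) {
  n <- length(layers)
  grads <- vector("list", n)
  delta <- dout
  for (l in rev(seq_len(n))) {
    a <- fwd$acts[[l + 1L]]
    if (!is.null(fwd$masks[[l]])) delta <- delta * fwd$masks[[l]]
    dz <- if (l == n && delta_is_dz) delta else delta * activate_grad(a, layers[[l]]$activation)
    grads[[l]] <- list(W = crossprod(fwd$acts[[l]], dz), b = colSums(dz))
    if (l > 1L) delta <- tcrossprod(dz, layers[[l]]$W)
  }
  grads
}

# optimizer state buffers, one pair per layer, freshly allocated so the
# in-place C++ steps never touch shared memory
optim_state <- function(layers) {
  lapply(layers, function(ly) list(W = ly$W * 0, b = ly$b * 0))
}

# deep-copy a layer list so in-place updates cannot mutate the caller's object
dup_layers <- function(layers) {
  lapply(layers, function(ly) { ly$W <- ly$W + 0; ly$b <- ly$b + 0; ly })
}

# cap each unit's incoming-weight Euclidean norm (columns of W) at max_norm
apply_max_norm <- function(layer, max_norm) {
  nrm <- sqrt(colSums(layer$W^2))
  over <- nrm > max_norm
  if (any(over))
    layer$W[, over] <- sweep(layer$W[, over, drop = FALSE], 2L,
                             max_norm / nrm[over], "*")
  layer
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Autoencoder pre-training configuration
#'
#' The seven-layer mirrored autoencoder: encoder widths narrow from the
#' 800-dimensional mixed dipeptide vector through 650, 500 and 300 nodes;
#' the decoder mirrors the encoder back to 800. Hidden layers are rectified
#' linear; the reconstruction layer is sigmoid (the inputs are frequencies in
#' \[0, 1\]). Training minimises the sample-weighted squared reconstruction
#' error with Adadelta.
#'
#' @param widths Encoder layer widths, input first; default
#'   `c(800, 650, 500, 300)`, strictly decreasing to the bottleneck.
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 12).
#' @param rho,eps,lr Adadelta decay rate, conditioner and learning-rate
#'   scale (defaults 0.95, 1e-6, 1).
#' @param pretrain `"joint"` (default) trains the full mirrored network
#'   end-to-end; `"layerwise"` trains each encoder/decoder pair greedily.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A list of class `aodeep_ae_config`.
#' @export
ae_config <- function(widths = c(800, 650, 500, 300), epochs = 100,
                      batch_size = 12, rho = 0.95, eps = 1e-6, lr = 1,
                      pretrain = c("joint", "layerwise"), seed = 1L) {
  pretrain <- match.arg(pretrain)
  if (length(widths) < 2 || any(diff(widths) >= 0))
    abort("Encoder widths must strictly decrease to the bottleneck.",
          class = "aodeep_config_error")
  if (epochs < 1 || batch_size < 1)
    abort("epochs and batch_size must be positive.", class = "aodeep_config_error")
  structure(list(widths = as.integer(widths), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), rho = rho, eps = eps,
                 lr = lr, pretrain = pretrain, seed = as.integer(seed)),
            class = "aodeep_ae_config")
}

#' Fine-tuning configuration for the fully connected head
#'
#' Three fully connected layers (50 and 25 tanh hidden nodes, one sigmoid
#' output node) are stacked on the pre-trained encoder and the whole network
#' is trained on weighted binary cross-entropy with mini-batch gradient
#' descent: learning rate 0.0025, decay 1e-6, momentum 0.6, batch size 12.
#' Dropout (0.2 and 0.3) acts on the two hidden layers during training only;
#' after every update each fully connected unit's incoming-weight norm is
#' capped at 3. Fully connected weights initialise uniformly on
#' \[-0.05, 0.05\] with zero biases.
#'
#' @param fc_widths Fully connected widths (default `c(50, 25, 1)`; the last
#'   must be 1).
#' @param dropout Dropout rates for the hidden fully connected layers.
#' @param max_norm Cap on each unit's incoming-weight Euclidean norm.
#' @param lr,decay,momentum,batch_size Optimiser settings.
#' @param epochs Training epochs (default 100).
#' @param seed Integer seed (initialisation, shuffling, dropout).
#' @return A list of class `aodeep_ft_config`.
#' @export
ft_config <- function(fc_widths = c(50, 25, 1), dropout = c(0.2, 0.3),
                      max_norm = 3, lr = 0.0025, decay = 1e-6, momentum = 0.6,
                      batch_size = 12, epochs = 100, seed = 1L) {
  if (fc_widths[length(fc_widths)] != 1)
    abort("The output layer must have a single logistic node.",
          class = "aodeep_config_error")
  if (any(dropout < 0 | dropout >= 1))
    abort("Dropout rates must lie in [0, 1).", class = "aodeep_config_error")
  if (max_norm <= 0 || lr <= 0)
    abort("max_norm and lr must be positive.", class = "aodeep_config_error")
  if (length(dropout) != length(fc_widths) - 1)
    abort("Need one dropout rate per hidden fully connected layer.",
          class = "aodeep_config_error")
  structure(list(fc_widths = as.integer(fc_widths), dropout = dropout,
                 max_norm = max_norm, lr = lr, decay = decay,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "aodeep_ft_config")
}

#' Class-imbalance sample weights
#'
#' The benchmark has roughly six negatives per positive, so positive samples
#' carry weight 6 and negatives weight 1 in both training losses.
#'
#' @param labels Integer 0/1 labels (1 = antioxidant).
#' @param positive_weight Weight for the positive class (default 6).
#' @return Numeric weight vector.
#' @export
sample_weights <- function(labels, positive_weight = 6) {
  ifelse(labels == 1L, positive_weight, 1)
}

weighted_recon_loss <- function(x, xhat, w) {
  sum(w * rowSums((x - xhat)^2)) / sum(w)
}

weighted_bce_loss <- function(t, y, w, eps = 1e-12) {
  y <- pmin(pmax(y, eps), 1 - eps)
  sum(w * (-(t * log(y) + (1 - t) * log(1 - y)))) / sum(w)
}

make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / min(batch_size, n)))
}

build_autoencoder_layers <- function(widths) {
  full <- c(widths, rev(widths)[-1])
  n_lay <- length(full) - 1L
  lapply(seq_len(n_lay), function(l)
    new_layer(full[l], full[l + 1L],
              activation = if (l == n_lay) "sigmoid" else "relu",
              init = "glorot", name = sprintf("ae%d", l)))
}

# start the sigmoid reconstruction layer at the per-feature training mean:
# dipeptide frequencies are tiny (~1/400), and a zero-bias start overshoots
# into the saturated tail of the sigmoid, where gradients vanish
init_output_bias <- function(layer, x) {
  m <- pmin(pmax(colMeans(x), 1e-6), 1 - 1e-6)
  layer$b <- log(m / (1 - m))
  layer
}

train_ae_layers <- function(layers, x, w, config, epochs) {
  n <- nrow(x)
  layers <- dup_layers(layers)
  eg <- optim_state(layers)
  ed <- optim_state(layers)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (batch in make_batches(n, config$batch_size)) {
      xb <- x[batch, , drop = FALSE]
      wb <- w[batch]
      fwd <- nn_forward(layers, xb)
      xhat <- fwd$acts[[length(layers) + 1L]]
      # d/dxhat of the summed weighted batch loss sum_i w_i ||x_i - xhat_i||^2
      dout <- 2 * (xhat - xb) * wb
      grads <- nn_backward(layers, fwd, dout)
      for (l in seq_along(layers)) {
        adadelta_step(layers[[l]]$W, eg[[l]]$W, ed[[l]]$W, grads[[l]]$W,
                      config$rho, config$eps, config$lr)
        adadelta_step(layers[[l]]$b, eg[[l]]$b, ed[[l]]$b, grads[[l]]$b,
                      config$rho, config$eps, config$lr)
      }
    }
    xhat <- nn_forward(layers, x)$acts[[length(layers) + 1L]]
    loss_trace[ep] <- weighted_recon_loss(x, xhat, w)
    if (!is.finite(loss_trace[ep]))
      abort(sprintf("Autoencoder training diverged at epoch %d.", ep),
            class = "aodeep_divergence_error")
  }
  list(layers = layers, loss = loss_trace)
}

#' Pre-train the deep autoencoder
#'
#' Trains the mirrored seven-layer autoencoder with Adadelta to minimise the
#' summed weighted squared reconstruction error
#' `sum(w_i * ||x_i - x'_i||^2)`; the per-epoch loss trace reports its
#' weight-normalised form `sum(w_i * ||x_i - x'_i||^2) / sum(w_i)` so traces
#' are comparable across sample sizes. Positive samples default to weight 6
#' so the minority class is not drowned out of the reconstruction objective.
#' Joint end-to-end training is the default; a greedy layer-wise mode is
#' available for comparison.
#'
#' @param x Numeric feature matrix, one row per sample (default width 800).
#' @param weights Per-sample positive weights (e.g. [sample_weights()]);
#'   default all 1.
#' @param config An [ae_config()].
#' @return A list of class `aodeep_pretrained`: `encoder` (list of layers),
#'   `decoder`, `loss` (per-epoch weighted reconstruction loss on the full
#'   data) and `config`.
#' @export
pretrain_autoencoder <- function(x, weights = rep(1, nrow(x)), config = ae_config()) {
  stopifnot(inherits(config, "aodeep_ae_config"))
  x <- as.matrix(x)
  if (ncol(x) != config$widths[1])
    abort(sprintf("Feature width %d does not match configured input width %d.",
                  ncol(x), config$widths[1]), class = "aodeep_shape_error")
  if (any(weights <= 0)) abort("Sample weights must be positive.",
                               class = "aodeep_config_error")
  if (nrow(x) < config$batch_size)
    warn(sprintf("Only %d samples; batch size clipped from %d.",
                 nrow(x), config$batch_size))
  n_enc <- length(config$widths) - 1L

  with_seed(config$seed, {
    if (config$pretrain == "joint") {
      layers <- build_autoencoder_layers(config$widths)
      layers[[length(layers)]] <- init_output_bias(layers[[length(layers)]], x)
      fit <- train_ae_layers(layers, x, weights, config, config$epochs)
      layers <- fit$layers
      loss <- fit$loss
    } else {
      # greedy: train each (encode, decode) pair on the previous code
      enc <- list(); dec <- list()
      input <- x
      stage_loss <- list()
      for (l in seq_len(n_enc)) {
        din <- ncol(input); dout <- config$widths[l + 1L]
        pair <- list(
          new_layer(din, dout, "relu", "glorot", sprintf("ae%d", l)),
          new_layer(dout, din, if (l == 1L) "sigmoid" else "relu", "glorot",
                    sprintf("ae%d_dec", l)))
        if (l == 1L) pair[[2]] <- init_output_bias(pair[[2]], input)
        fit <- train_ae_layers(pair, input, weights, config, config$epochs)
        enc[[l]] <- fit$layers[[1]]
        dec[[n_enc - l + 1L]] <- fit$layers[[2]]
        stage_loss[[l]] <- fit$loss
        input <- nn_forward(list(enc[[l]]), input)$acts[[2]]
      }
      layers <- c(enc, dec)
      xhat <- nn_forward(layers, x)$acts[[length(layers) + 1L]]
      loss <- vapply(stage_loss, function(s) s[length(s)], numeric(1))
      attr(loss, "final_joint") <- weighted_recon_loss(x, xhat, weights)
    }
    structure(list(encoder = layers[seq_len(n_enc)],
                   decoder = layers[-seq_len(n_enc)],
                   loss = loss, config = config),
              class = "aodeep_pretrained")
  })
}

#' Fine-tune the classifier and feature learner
#'
#' Discards the decoder, stacks the fully connected head (50, 25, 1) on the
#' pre-trained encoder and trains the whole network — encoder included — on
#' weighted binary cross-entropy. Dropout is active only during training;
#' the max-norm cap is re-applied to the fully connected layers after every
#' update. The 50-node first fully connected layer is the learned
#' representation used downstream.
#'
#' @param pretrained An `aodeep_pretrained` object (or a bare list of encoder
#'   layers).
#' @param x Feature matrix (same width the encoder was trained on).
#' @param labels Integer 0/1 labels, 1 = antioxidant.
#' @param weights Per-sample weights; default [sample_weights()] at 6:1.
#' @param config An [ft_config()].
#' @return An object of class `aodeep_feature_learner` with elements
#'   `encoder`, `fc`, `pretrain_loss`, `finetune_loss`, `configs`.
#' @export
fine_tune <- function(pretrained, x, labels,
                      weights = sample_weights(labels), config = ft_config()) {
  stopifnot(inherits(config, "aodeep_ft_config"))
  encoder <- if (inherits(pretrained, "aodeep_pretrained")) pretrained$encoder else pretrained
  x <- as.matrix(x)
  t <- as.numeric(labels)
  if (length(unique(t)) < 2)
    abort("Fine-tuning needs both classes present.", class = "aodeep_degenerate_error")
  if (any(!t %in% c(0, 1)))
    abort("Labels must be 0/1.", class = "aodeep_validation_error")

  bottleneck <- ncol(encoder[[length(encoder)]]$W)
  n_fc <- length(config$fc_widths)

  with_seed(config$seed, {
    fc_in <- c(bottleneck, config$fc_widths[-n_fc])
    fc <- lapply(seq_len(n_fc), function(l)
      new_layer(fc_in[l], config$fc_widths[l],
                activation = if (l == n_fc) "sigmoid" else "tanh",
                init = "uniform005", name = sprintf("fc%d", l)))
    layers <- c(dup_layers(encoder), fc)
    n_enc <- length(encoder)
    dropout <- c(rep(0, n_enc), config$dropout, 0)  # hidden FC outputs only

    n <- nrow(x)
    vel <- optim_state(layers)
    loss_trace <- numeric(config$epochs)
    iter <- 0L
    for (ep in seq_len(config$epochs)) {
      for (batch in make_batches(n, config$batch_size)) {
        xb <- x[batch, , drop = FALSE]
        tb <- t[batch]
        wb <- weights[batch]
        fwd <- nn_forward(layers, xb, dropout_rates = dropout, training = TRUE)
        y <- fwd$acts[[length(layers) + 1L]]
        # sigmoid + BCE, summed weighted batch loss: d/dz = w_i (y_i - t_i)
        dz <- (y - tb) * wb
        grads <- nn_backward(layers, fwd, dz, delta_is_dz = TRUE)
        lr_t <- config$lr / (1 + config$decay * iter)
        for (l in seq_along(layers)) {
          sgd_momentum_step(layers[[l]]$W, vel[[l]]$W, grads[[l]]$W,
                            lr_t, config$momentum)
          sgd_momentum_step(layers[[l]]$b, vel[[l]]$b, grads[[l]]$b,
                            lr_t, config$momentum)
          if (l > n_enc)
            layers[[l]] <- apply_max_norm(layers[[l]], config$max_norm)
        }
        iter <- iter + 1L
      }
      y_full <- nn_forward(layers, x)$acts[[length(layers) + 1L]]
      loss_trace[ep] <- weighted_bce_loss(t, y_full, weights)
      if (!is.finite(loss_trace[ep]))
        abort(sprintf("Fine-tuning diverged at epoch %d.", ep),
              class = "aodeep_divergence_error")
    }

    structure(list(encoder = layers[seq_len(n_enc)],
                   fc = layers[-seq_len(n_enc)],
                   pretrain_loss = if (inherits(pretrained, "aodeep_pretrained"))
                     pretrained$loss else NULL,
                   finetune_loss = loss_trace,
                   configs = list(
                     ae = if (inherits(pretrained, "aodeep_pretrained"))
                       pretrained$config else NULL,
                     ft = config)),
              class = "aodeep_feature_learner")
  })
}

#' Extract the learned 50-dimensional representation
#'
#' Deterministic forward pass (dropout off) through the encoder and the first
#' fully connected layer; its 50 tanh units are the low-dimensional
#' representation of the 800-dimensional input vector.
#'
#' @param model An `aodeep_feature_learner`.
#' @param x Feature matrix with the width the model was trained on.
#' @return Numeric matrix, `nrow(x)` x 50 (first fully connected width).
#' @export
extract_representation <- function(model, x) {
  stopifnot(inherits(model, "aodeep_feature_learner"))
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$encoder[[1]]$W))
    abort(sprintf("Feature width %d does not match model input width %d.",
                  ncol(x), nrow(model$encoder[[1]]$W)), class = "aodeep_shape_error")
  layers <- c(model$encoder, model$fc[1])
  out <- nn_forward(layers, x)$acts[[length(layers) + 1L]]
  rownames(out) <- rownames(x)
  out
}

#' Predicted antioxidant probabilities from the fine-tuned network
#'
#' @param object An `aodeep_feature_learner`.
#' @param x Feature matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.aodeep_feature_learner <- function(object, x, ...) {
  x <- as.matrix(x)
  layers <- c(object$encoder, object$fc)
  as.vector(nn_forward(layers, x)$acts[[length(layers) + 1L]])
}

#' Count trainable parameters of a feature learner
#'
#' @param model An `aodeep_feature_learner` or `aodeep_pretrained` object.
#' @return Named integer vector with per-layer and total parameter counts.
#' @export
n_parameters <- function(model) {
  layers <- if (inherits(model, "aodeep_pretrained"))
    c(model$encoder, model$decoder) else c(model$encoder, model$fc)
  counts <- vapply(layers, function(ly) length(ly$W) + length(ly$b), numeric(1))
  names(counts) <- vapply(layers, function(ly) ly$name, character(1))
  c(counts, total = sum(counts))
}
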