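# Network trainings here run few epochs on small simulated sets: enough to
# exercise the machinery and its invariants without long runtimes.

test_that("backpropagation gradients match central finite differences", {
  set.seed(9)
  layers <- list(aodeep:::new_layer(6, 4, "relu"),
                 aodeep:::new_layer(4, 3, "tanh"),
                 aodeep:::new_layer(3, 1, "sigmoid"))
  x <- matrix(rnorm(5 * 6), 5)
  t <- c(1, 0, 1, 0, 0)
  w <- c(6, 1, 6, 1, 1)
  lossfun <- function(ly) {
    y <- aodeep:::nn_forward(ly, x)$acts[[4]]
    sum(w * -(t * log(y) + (1 - t) * log(1 - y))) / length(t)
  }
  fwd <- aodeep:::nn_forward(layers, x)
  dz <- (fwd$acts[[4]] - t) * (w / 5)
  grads <- aodeep:::nn_backward(layers, fwd, dz, delta_is_dz = TRUE)
  eps <- 1e-6
  for (l in 1:3) for (par in c("W", "b")) {
    for (i in sample(seq_along(layers[[l]][[par]]),
                     min(8, length(layers[[l]][[par]])))) {
      lp <- layers; lp[[l]][[par]][i] <- lp[[l]][[par]][i] + eps
      lm <- layers; lm[[l]][[par]][i] <- lm[[l]][[par]][i] - eps
      num <- (lossfun(lp) - lossfun(lm)) / (2 * eps)
      expect_equal(grads[[l]][[par]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("autoencoder architecture and parameter counts match the widths exactly", {
  d <- small_training_set(n_pos = 6, n_neg = 24, seed = 1)
  pre <- pretrain_autoencoder(d$x, d$weights, ae_config(epochs = 1, seed = 5))
  widths <- c(800, 650, 500, 300, 500, 650, 800)
  expected <- sum(widths[-7] * widths[-1] + widths[-1])
  expect_equal(unname(n_parameters(pre)["total"]), expected)
  # reconstruction layer is as wide as the input
  expect_equal(ncol(pre$decoder[[3]]$W), 800L)

  fl <- fine_tune(pre, d$x, d$labels, d$weights, ft_config(epochs = 1, seed = 6))
  fc_widths <- c(300, 50, 25, 1)
  expected_total <- sum(c(800, 650, 500) * c(650, 500, 300) + c(650, 500, 300)) +
    sum(fc_widths[-4] * fc_widths[-1] + fc_widths[-1])
  expect_equal(unname(n_parameters(fl)["total"]), expected_total)
})

test_that("pre-training reduces the weighted reconstruction loss on a seeded run", {
  d <- small_training_set(n_pos = 8, n_neg = 42, seed = 12)   # 50 samples
  pre <- pretrain_autoencoder(d$x, d$weights, ae_config(epochs = 30, seed = 3))
  expect_length(pre$loss, 30)
  expect_lt(pre$loss[30], pre$loss[1])
  expect_true(all(is.finite(pre$loss)))
})

test_that("reported losses equal independent recomputation from model outputs", {
  d <- small_training_set(n_pos = 8, n_neg = 42, seed = 12)
  pre <- pretrain_autoencoder(d$x, d$weights, ae_config(epochs = 4, seed = 3))
  xhat <- aodeep:::nn_forward(c(pre$encoder, pre$decoder), d$x)$acts[[7]]
  recon <- sum(d$weights * rowSums((d$x - xhat)^2)) / sum(d$weights)
  expect_equal(pre$loss[4], recon, tolerance = 1e-6)

  fl <- fine_tune(pre, d$x, d$labels, d$weights, ft_config(epochs = 4, seed = 8))
  y <- aodeep:::nn_forward(c(fl$encoder, fl$fc), d$x)$acts[[7]]
  bce <- sum(d$weights * -(d$labels * log(y) + (1 - d$labels) * log(1 - y))) /
    sum(d$weights)
  expect_equal(fl$finetune_loss[4], bce, tolerance = 1e-6)
})

test_that("fully connected initialization is uniform in [-0.05, 0.05] with zero biases", {
  set.seed(44)
  ly <- aodeep:::new_layer(300, 50, "tanh", init = "uniform005")
  expect_true(all(ly$W >= -0.05 & ly$W <= 0.05))
  expect_true(all(ly$b == 0))
  expect_gt(max(ly$W), 0.04)   # actually spread over the range
  expect_lt(min(ly$W), -0.04)
})

test_that("max-norm caps every fully connected unit after every epoch", {
  d <- small_training_set(n_pos = 8, n_neg = 42, seed = 12)
  pre <- pretrain_autoencoder(d$x, d$weights, ae_config(epochs = 1, seed = 3))
  for (ep in 1:3) {
    fl <- fine_tune(pre, d$x, d$labels, d$weights,
                    ft_config(epochs = ep, seed = 8, max_norm = 3))
    norms <- unlist(lapply(fl$fc, function(ly) sqrt(colSums(ly$W^2))))
    expect_true(all(norms <= 3 + 1e-9))
  }
  # a deliberately tight cap binds
  fl_tight <- fine_tune(pre, d$x, d$labels, d$weights,
                        ft_config(epochs = 1, seed = 8, max_norm = 0.01))
  norms <- unlist(lapply(fl_tight$fc, function(ly) sqrt(colSums(ly$W^2))))
  expect_true(all(norms <= 0.01 + 1e-9))
})

test_that("fine-tuned predictions are probabilities and training reduces cross-entropy", {
  d <- small_training_set(n_pos = 10, n_neg = 40, seed = 21, bias_strength = 8)
  pre <- pretrain_autoencoder(d$x, d$weights, ae_config(epochs = 3, seed = 3))
  fl <- fine_tune(pre, d$x, d$labels, d$weights, ft_config(epochs = 25, seed = 8))
  p <- predict(fl, d$x)
  expect_true(all(p > 0 & p < 1))
  expect_lt(fl$finetune_loss[25], fl$finetune_loss[1])
})

test_that("the representation is 50-dimensional, deterministic and serializable", {
  d <- small_training_set(n_pos = 6, n_neg = 24, seed = 2)
  pre <- pretrain_autoencoder(d$x, d$weights, ae_config(epochs = 1, seed = 3))
  fl <- fine_tune(pre, d$x, d$labels, d$weights, ft_config(epochs = 1, seed = 8))
  rep1 <- extract_representation(fl, d$x)
  expect_equal(dim(rep1), c(30L, 50L))
  expect_identical(rep1, extract_representation(fl, d$x))
  # identical input rows give identical output rows
  x2 <- d$x[c(1, 1, 5), ]
  r2 <- extract_representation(fl, x2)
  expect_identical(r2[1, ], r2[2, ])
  # round-trip through serialization preserves predictions bit-for-bit
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fl, path)
  expect_identical(predict(readRDS(path), d$x), predict(fl, d$x))
  expect_error(extract_representation(fl, d$x[, 1:100]),
               class = "aodeep_shape_error")
})

test_that("training is reproducible from the seed and refuses degenerate labels", {
  d <- small_training_set(n_pos = 6, n_neg = 24, seed = 2)
  pre1 <- pretrain_autoencoder(d$x, d$weights, ae_config(epochs = 2, seed = 7))
  pre2 <- pretrain_autoencoder(d$x, d$weights, ae_config(epochs = 2, seed = 7))
  expect_identical(pre1$loss, pre2$loss)
  fl1 <- fine_tune(pre1, d$x, d$labels, d$weights, ft_config(epochs = 2, seed = 9))
  fl2 <- fine_tune(pre2, d$x, d$labels, d$weights, ft_config(epochs = 2, seed = 9))
  expect_identical(predict(fl1, d$x), predict(fl2, d$x))
  # fine-tuning must not mutate the pre-trained object it started from
  expect_identical(pre1$encoder, pre2$encoder)
  expect_error(fine_tune(pre1, d$x, rep(1, nrow(d$x)), config = ft_config(epochs = 1)),
               class = "aodeep_degenerate_error")
})

test_that("layer-wise greedy pre-training is available and trains each stage", {
  d <- small_training_set(n_pos = 6, n_neg = 24, seed = 2)
  pre <- pretrain_autoencoder(d$x, d$weights,
                              ae_config(epochs = 2, seed = 3, pretrain = "layerwise"))
  expect_length(pre$encoder, 3)
  expect_true(is.finite(attr(pre$loss, "final_joint")))
})

test_that("learned representations separate planted signal better than permuted labels", {
  accs <- vapply(1:10, function(s) {
    d <- small_training_set(n_pos = 12, n_neg = 48, seed = 300 + s,
                            bias_strength = 8)
    pre <- pretrain_autoencoder(d$x, d$weights,
                                ae_config(epochs = 2, seed = 400 + s))
    fl <- fine_tune(pre, d$x, d$labels, d$weights,
                    ft_config(epochs = 10, seed = 500 + s))
    r <- extract_representation(fl, d$x)
    # held-out nearest-centroid probe: fit on one half, score the other
    set.seed(600 + s)
    half <- sample(nrow(r)) %% 2 == 0
    # balanced accuracy so the majority class offers no shortcut
    probe_acc <- function(lab) {
      if (length(unique(lab[half])) < 2 || length(unique(lab[!half])) < 2)
        return(0.5)
      c1 <- colMeans(r[half & lab == 1, , drop = FALSE])
      c0 <- colMeans(r[half & lab == 0, , drop = FALSE])
      d1 <- rowSums(sweep(r[!half, , drop = FALSE], 2, c1)^2)
      d0 <- rowSums(sweep(r[!half, , drop = FALSE], 2, c0)^2)
      hit <- (d1 < d0) == (lab[!half] == 1)
      (mean(hit[lab[!half] == 1]) + mean(hit[lab[!half] == 0])) / 2
    }
    probe_acc(d$labels) - probe_acc(sample(d$labels))
  }, numeric(1))
  expect_gt(mean(accs), 0)
  expect_gte(sum(accs > 0), 8)
})
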