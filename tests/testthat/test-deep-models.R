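test_that("configs validate and presets bundle the tuned settings", {
  expect_error(network_config("mlp", conv_filters = 4), "convolution")
  expect_error(network_config("mlp", learning_rate = -1), "nonnegative")
  cfg <- network_config("cnn", preset = "sire")
  expect_identical(cfg$conv_filters, 16L)
  expect_equal(cfg$l1, 0.005); expect_equal(cfg$l2, 0.1)
  cfg2 <- network_config("cnn", preset = "dam")
  expect_identical(cfg2$conv_filters, 8L)
  expect_equal(cfg2$l1, 0.003); expect_equal(cfg2$l2, 0.15)
  cfg3 <- network_config("mlp")
  expect_identical(cfg3$hidden_sizes, c(96L, 64L, 32L, 16L))
  expect_equal(cfg3$learning_rate, 1e-5)
  expect_identical(cfg3$batch_size, 32L)
})

test_that("parameter counts follow the architecture arithmetic", {
  # dense stack over 3 markers with one 2-unit hidden layer:
  # 3*2+2 (hidden) + 2*1+1 (output) = 11
  cfg <- network_config("mlp", hidden_sizes = 2)
  expect_identical(build_model(cfg, 3)$n_params, 11L)
  # cnn: valid convolution of length m-k+1 before pooling
  ccfg <- network_config("cnn", conv_filters = 1, kernel_size = 5,
                         pool_size = 3, hidden_sizes = 4)
  mdl <- build_model(ccfg, 10)
  # conv output length 6, pooled to 2, flattened to 2 features
  expect_identical(mdl$n_params,
                   (5L + 1L) + (2L * 4L + 4L) + (4L * 1L + 1L))
  expect_error(build_model(ccfg, 4), "kernel")
})

test_that("initialization and training are reproducible under a fixed seed", {
  cfg <- network_config("mlp", hidden_sizes = c(8, 4), l1 = 0, l2 = 0,
                        learning_rate = 1e-3, max_epochs = 5, seed = 77)
  m1 <- build_model(cfg, 20)
  m2 <- build_model(cfg, 20)
  expect_identical(m1$layers, m2$layers)
  set.seed(1)
  X <- matrix(rbinom(60 * 20, 2, 0.4), 60, 20)
  y <- rnorm(60)
  t1 <- train_model(m1, X[1:40, ], y[1:40], X[41:60, ], y[41:60])
  t2 <- train_model(m2, X[1:40, ], y[1:40], X[41:60, ], y[41:60])
  expect_identical(predict(t1, X), predict(t2, X))
})

test_that("a zero-epoch budget returns the initialized network", {
  cfg <- network_config("mlp", hidden_sizes = 4, seed = 5)
  mdl <- build_model(cfg, 10)
  X <- matrix(1, 6, 10); y <- rnorm(6)
  tr <- train_model(mdl, X, y, X, y, epochs = 0)
  expect_identical(tr$layers, mdl$layers)
  expect_identical(nrow(tr$history), 0L)
})

test_that("early stopping halts within patience of the best epoch and restores its weights", {
  set.seed(3)
  X <- matrix(rbinom(80 * 15, 2, 0.5), 80, 15)
  y <- rnorm(80)  # pure noise: validation loss bottoms out early
  cfg <- network_config("mlp", hidden_sizes = 8, l1 = 0, l2 = 0,
                        learning_rate = 5e-3, max_epochs = 200,
                        early_stop_patience = 5, seed = 11)
  mdl <- train_model(build_model(cfg, 15), X[1:50, ], y[1:50],
                     X[51:80, ], y[51:80])
  h <- mdl$history
  expect_lte(nrow(h), mdl$best_epoch + 5)
  expect_equal(which.min(h$val_mse), mdl$best_epoch)
  # restored weights reproduce the best recorded validation MSE
  expect_equal(mean((predict(mdl, X[51:80, ]) - y[51:80])^2),
               min(h$val_mse), tolerance = 1e-10)
})

test_that("an additive noiseless trait is learnable to low validation error", {
  set.seed(21)
  n <- 400; m <- 40
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  y <- znormalize(drop(X %*% rnorm(m)))
  cfg <- network_config("mlp", hidden_sizes = c(32, 16), l1 = 0, l2 = 0,
                        learning_rate = 3e-3, max_epochs = 120,
                        early_stop_patience = 20, seed = 9)
  mdl <- train_model(build_model(cfg, m), X[1:300, ], y[1:300],
                     X[301:400, ], y[301:400])
  expect_lt(min(mdl$history$val_mse), 0.05 * var(y[301:400]))
})

test_that("forward pass is deterministic, order-invariant and duplicates-consistent", {
  cfg <- network_config("cnn", conv_filters = 3, hidden_sizes = c(8, 4),
                        l1 = 0, l2 = 0, seed = 13)
  mdl <- build_model(cfg, 30)
  X <- matrix(rbinom(20 * 30, 2, 0.5), 20, 30)
  p1 <- predict(mdl, X)
  perm <- sample(20)
  expect_equal(predict(mdl, X[perm, ])[order(perm)], p1, tolerance = 1e-12)
  Xd <- X[c(1, 1, 2), ]
  pd <- predict(mdl, Xd)
  expect_identical(pd[1], pd[2])
  expect_error(predict(mdl, X[, 1:10]), "markers")
})

test_that("a hand-weighted linear network computes x.w + b exactly", {
  cfg <- network_config("mlp", hidden_sizes = 4, activation = "linear",
                        l1 = 0, l2 = 0, seed = 2)
  mdl <- build_model(cfg, 5)
  # collapse to a known affine map: W1 = I-ish, output sums
  mdl$layers[[1]]$W <- rbind(diag(4), 0)
  mdl$layers[[1]]$b <- rep(0, 4)
  mdl$layers[[2]]$W <- matrix(c(1, -1, 2, 0.5), 4, 1)
  mdl$layers[[2]]$b <- 0.25
  w <- drop(rbind(diag(4), 0) %*% c(1, -1, 2, 0.5))
  X <- matrix(rnorm(15), 3, 5)
  expect_equal(predict(mdl, X), drop(X %*% w) + 0.25, tolerance = 1e-12)
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(9)
  n <- 6; m <- 12
  X <- matrix(rnorm(n * m), n, m)
  y <- rnorm(n)
  layers <- list(nn_conv(3, 2, l1 = 0.01, l2 = 0.02), nn_maxpool(2),
                 nn_flatten(), nn_dense(10, 4, l1 = 0.01, l2 = 0.02),
                 nn_dense(4, 1, act = "linear"))
  lossfn <- function(ls) {
    mean((drop(nn_forward(ls, X)) - y)^2) + nn_penalty(ls)
  }
  fw <- nn_forward(layers, X, cache = TRUE)
  bw <- nn_backward(layers, fw$caches,
                    matrix(2 * (drop(fw$out) - y) / n, ncol = 1))
  eps <- 1e-6
  for (li in c(1, 4, 5)) {
    for (t in 1:4) {
      i <- sample(length(layers[[li]]$W), 1)
      lp <- layers; lp[[li]]$W[i] <- lp[[li]]$W[i] + eps
      lm <- layers; lm[[li]]$W[i] <- lm[[li]]$W[i] - eps
      expect_equal(bw$grads[[li]]$dW[i],
                   (lossfn(lp) - lossfn(lm)) / (2 * eps), tolerance = 1e-5)
    }
    bp <- layers; bp[[li]]$b[1] <- bp[[li]]$b[1] + eps
    bm <- layers; bm[[li]]$b[1] <- bm[[li]]$b[1] - eps
    expect_equal(bw$grads[[li]]$db[1],
                 (lossfn(bp) - lossfn(bm)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("an unpenalized linear network converges to ridge-regression predictions", {
  set.seed(31)
  n <- 500; m <- 120
  X <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.5), each = n)), n, m)
  y <- znormalize(drop(X %*% rnorm(m, 0, 0.3)) + rnorm(n, 0, 0.5))
  tr <- 1:350; va <- 351:420; te <- 421:500
  cfg <- network_config("mlp", hidden_sizes = c(16, 8),
                        activation = "linear", l1 = 0, l2 = 0,
                        learning_rate = 2e-3, max_epochs = 150,
                        early_stop_patience = 30, seed = 41)
  mdl <- train_model(build_model(cfg, m), X[tr, ], y[tr], X[va, ], y[va])
  # closed-form ridge with a small penalty as the linear oracle
  Xc <- scale(X[tr, ], scale = FALSE)
  beta <- solve(crossprod(Xc) + diag(1e-4, m), crossprod(Xc, y[tr]))
  ridge <- drop(scale(X[te, ], center = attr(Xc, "scaled:center"),
                      scale = FALSE) %*% beta) + mean(y[tr])
  expect_gt(cor(predict(mdl, X[te, ]), ridge), 0.98)
})
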