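#' Deep-model configuration
#'
#' Architecture and training hyperparameters for the genotype-to-phenotype
#' regressors.  Defaults follow the tuned per-line settings of the study
#' design this package implements: a four-hidden-layer 96:64:32:16 MLP or a
#' one-convolution-layer CNN (kernel 5, pooling 3) feeding a 64:32:16 dense
#' stack, leaky-ReLU hidden activations, linear output, He-normal
#' initialization, Adam with learning rate 1e-5, batch size 32 and MSE loss.
#' The `"sire"` and `"dam"` presets bundle the two tuned regularization
#' columns (sire: MLP l1 0.01 / l2 0.1, CNN 16 filters l1 0.005 / l2 0.1;
#' dam: MLP l1 0.007 / l2 0.15, CNN 8 filters l1 0.003 / l2 0.15).
#'
#' @param arch `"mlp"` or `"cnn"`.
#' @param preset optional `"sire"` or `"dam"` hyperparameter bundle.
#' @param hidden_sizes dense-stack widths (defaults per `arch`).
#' @param conv_filters,kernel_size,pool_size convolution settings (cnn only).
#' @param l1,l2 kernel penalty weights applied to all dense and conv kernels.
#' @param activation hidden activation: `"leaky_relu"` (default) or
#'   `"linear"` (useful for checking against linear baselines).
#' @param leaky_alpha negative slope of the leaky-ReLU.
#' @param learning_rate,batch_size,max_epochs,early_stop_patience training
#'   controls; early stopping monitors validation MSE and restores the best
#'   weights.
#' @param seed integer; fixes initialization and minibatch shuffling.
#' @return list of class `network_config`.
#' @export
network_config <- function(arch = c("mlp", "cnn"), preset = NULL,
                           hidden_sizes = NULL, conv_filters = NULL,
                           kernel_size = 5L, pool_size = 3L,
                           l1 = NULL, l2 = NULL,
                           activation = c("leaky_relu", "linear"),
                           leaky_alpha = 0.3,
                           learning_rate = 1e-5, batch_size = 32L,
                           max_epochs = 500L, early_stop_patience = 20L,
                           seed = 1L) {
  arch <- match.arg(arch)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("sire", "dam"))
    tuned <- list(
      sire = list(mlp = list(l1 = 0.01, l2 = 0.1, conv_filters = NULL),
                  cnn = list(l1 = 0.005, l2 = 0.1, conv_filters = 16L)),
      dam = list(mlp = list(l1 = 0.007, l2 = 0.15, conv_filters = NULL),
                 cnn = list(l1 = 0.003, l2 = 0.15, conv_filters = 8L)))
    tt <- tuned[[preset]][[arch]]
    if (is.null(l1)) l1 <- tt$l1
    if (is.null(l2)) l2 <- tt$l2
    if (is.null(conv_filters)) conv_filters <- tt$conv_filters
  }
  if (is.null(hidden_sizes))
    hidden_sizes <- if (arch == "mlp") c(96, 64, 32, 16) else c(64, 32, 16)
  if (is.null(l1)) l1 <- 0
  if (is.null(l2)) l2 <- 0
  if (arch == "cnn" && is.null(conv_filters)) conv_filters <- 16L
  if (arch == "mlp" && !is.null(conv_filters))
    stop("mlp architecture does not take convolution settings")
  if (any(c(hidden_sizes, kernel_size, pool_size, batch_size) < 1))
    stop("all counts must be positive")
  if (min(l1, l2, learning_rate) < 0)
    stop("l1, l2 and learning_rate must be nonnegative")
  structure(list(arch = arch, hidden_sizes = as.integer(hidden_sizes),
                 conv_filters = if (arch == "cnn") as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 l1 = l1, l2 = l2, activation = match.arg(activation),
                 leaky_alpha = leaky_alpha,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build an untrained genotype-to-phenotype network
#'
#' MLP: a dense stack over the m-length dosage vector.  CNN: one 1-D valid
#' convolution over the marker axis, non-overlapping max pooling, flatten,
#' then the dense stack.  All hidden layers use leaky-ReLU; the single
#' output unit is linear.  Weights are He-normal, drawn deterministically
#' from `config$seed`.
#'
#' @param config a [network_config()].
#' @param n_markers number of input markers m.
#' @return object of class `dl_model` with elements `layers`, `config`,
#'   `n_markers`, `n_params`, `trained`.
#' @export
build_model <- function(config, n_markers) {
  stopifnot(inherits(config, "network_config"), n_markers >= 1)
  set.seed(config$seed)
  layers <- list()
  if (config$arch == "cnn") {
    if (config$kernel_size > n_markers)
      stop("kernel larger than the number of markers")
    conv_len <- n_markers - config$kernel_size + 1
    if (conv_len %/% config$pool_size < 1)
      stop("pool window larger than the convolved axis")
    layers <- c(layers,
                list(nn_conv(config$kernel_size, config$conv_filters,
                             act = config$activation,
                             alpha = config$leaky_alpha,
                             l1 = config$l1, l2 = config$l2)),
                list(nn_maxpool(config$pool_size)),
                list(nn_flatten()))
    p <- (conv_len %/% config$pool_size) * config$conv_filters
  } else {
    p <- n_markers
  }
  for (u in config$hidden_sizes) {
    layers <- c(layers, list(nn_dense(p, u, act = config$activation,
                                      alpha = config$leaky_alpha,
                                      l1 = config$l1, l2 = config$l2)))
    p <- u
  }
  layers <- c(layers, list(nn_dense(p, 1, act = "linear",
                                    l1 = config$l1, l2 = config$l2)))
  structure(list(layers = layers, config = config, n_markers = n_markers,
                 n_params = nn_n_params(layers), trained = FALSE,
                 history = NULL),
            class = "dl_model")
}

#' @export
print.dl_model <- function(x, ...) {
  cat(sprintf("dl_model (%s): %d markers -> %s -> 1; %d parameters; %s\n",
              x$config$arch, x$n_markers,
              paste(x$config$hidden_sizes, collapse = ":"),
              x$n_params, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Train a network with early stopping on a validation split
#'
#' Minimizes MSE plus the configured kernel penalties by minibatch Adam.
#' After each epoch the validation MSE is recorded; training halts when it
#' has not improved for `early_stop_patience` epochs (or at `max_epochs`)
#' and the best-validation weights are restored.
#'
#' @param model an untrained (or previously trained) `dl_model`.
#' @param X_train,y_train training genotypes (n x m dosage matrix) and
#'   phenotypes.
#' @param X_val,y_val validation data monitored for early stopping.
#' @param epochs optional override of `config$max_epochs`.
#' @param learning_rate optional override of the configured rate.
#' @param verbose print per-epoch losses.
#' @return the trained `dl_model`; `$history` is a data.frame with one row
#'   per epoch (`epoch`, `train_loss` incl. penalties, `val_mse`) and
#'   `$best_epoch` marks the restored weights.
#' @export
train_model <- function(model, X_train, y_train, X_val, y_val,
                        epochs = NULL, learning_rate = NULL,
                        verbose = FALSE) {
  cfg <- model$config
  if (ncol(X_train) != model$n_markers) stop("training m mismatch")
  if (ncol(X_val) != model$n_markers) stop("validation m mismatch")
  epochs <- epochs %||% cfg$max_epochs
  lr <- learning_rate %||% cfg$learning_rate
  layers <- model$layers
  state <- adam_init(layers)
  n <- nrow(X_train)
  set.seed(cfg$seed + 1L)
  best_val <- Inf; best_layers <- layers; best_epoch <- 0L
  wait <- 0L; t <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_mse = numeric(0))
  if (epochs < 1) {
    model$history <- hist
    model$best_epoch <- 0L
    model$trained <- TRUE
    return(model)
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      Xb <- X_train[idx, , drop = FALSE]
      yb <- y_train[idx]
      fw <- nn_forward(layers, Xb, cache = TRUE)
      err <- drop(fw$out) - yb
      loss <- mean(err^2) + nn_penalty(layers)
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf loss at epoch %d (lr=%g): try a lower rate",
                     ep, lr))
      dOut <- matrix(2 * err / length(err), ncol = 1)
      bw <- nn_backward(layers, fw$caches, dOut)
      t <- t + 1L
      upd <- adam_step(layers, bw$grads, state, t, lr)
      layers <- upd$layers; state <- upd$state
      tr_loss <- tr_loss + loss; nb <- nb + 1L
    }
    val_mse <- mean((drop(nn_forward(layers, X_val)) - y_val)^2)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss / nb,
                                   val_mse = val_mse))
    if (verbose)
      message(sprintf("epoch %d: train %.5f val %.5f", ep, tr_loss / nb,
                      val_mse))
    if (val_mse < best_val - 1e-12) {
      best_val <- val_mse; best_layers <- layers; best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$layers <- best_layers
  model$history <- hist
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}

#' Predict phenotypes from genotypes
#'
#' Deterministic forward pass of a `dl_model`.
#'
#' @param object a `dl_model`.
#' @param newdata n x m dosage matrix (m must match training).
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.dl_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_markers)
    stop("newdata has wrong number of markers")
  drop(nn_forward(object$layers, newdata))
}
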