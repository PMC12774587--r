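#' VAE augmentation configuration
#'
#' @param latent_dim size of the Gaussian latent space (default 16).
#' @param encoder_sizes hidden widths of the encoder dense stack; the decoder
#'   mirrors them by default.
#' @param decoder_sizes hidden widths of the decoder.
#' @param n_bins number of phenotype bins (default 10).
#' @param per_bin synthetic observations generated per bin (default 100).
#' @param kl_weight weight of the KL term in the loss (default 1).
#' @param output_map how decoder outputs become 0/1/2 codes: `"softmax"`
#'   (default) gives each marker a 3-class categorical head trained by
#'   cross-entropy, and synthetic genotypes are sampled from the class
#'   probabilities, which preserves per-marker genotype frequencies;
#'   `"round"` trains a single mean-squared-error output per marker and
#'   rounds/clips it (simpler, but quantizes marker means).
#' @param learning_rate,batch_size,max_epochs Adam training controls.
#' @param seed RNG seed.
#' @return list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 16L, encoder_sizes = c(256L, 64L),
                       decoder_sizes = rev(encoder_sizes),
                       n_bins = 10L, per_bin = 100L, kl_weight = 1,
                       output_map = c("softmax", "round"),
                       learning_rate = 1e-3, batch_size = 32L,
                       max_epochs = 30L, seed = 1L) {
  if (latent_dim < 1 || n_bins < 2 || per_bin < 1)
    stop("latent_dim >= 1, n_bins >= 2 and per_bin >= 1 required")
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_sizes = as.integer(encoder_sizes),
                 decoder_sizes = as.integer(decoder_sizes),
                 n_bins = as.integer(n_bins), per_bin = as.integer(per_bin),
                 kl_weight = kl_weight,
                 output_map = match.arg(output_map),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "vae_config")
}

# softmax over the 3 genotype classes of each marker; logits are laid out
# class-fastest: column (k-1)*3 + c holds class c-1 of marker k
softmax3 <- function(L, m, n) {
  A <- array(L, c(n, 3, m))
  M <- pmax(A[, 1, , drop = FALSE], A[, 2, , drop = FALSE],
            A[, 3, , drop = FALSE])
  E <- exp(A - array(M[, c(1, 1, 1), , drop = FALSE], c(n, 3, m)))
  S <- E[, 1, , drop = FALSE] + E[, 2, , drop = FALSE] +
    E[, 3, , drop = FALSE]
  P <- E / array(S[, c(1, 1, 1), , drop = FALSE], c(n, 3, m))
  matrix(P, n, 3 * m)
}

class_onehot <- function(Xb, m, n) {
  O <- array(0, c(n, 3, m))
  O[cbind(as.vector(row(Xb)), as.vector(Xb) + 1L, as.vector(col(Xb)))] <- 1
  matrix(O, n, 3 * m)
}

#' Equal-frequency phenotype bins
#'
#' Splits training phenotypes into `n_bins` quantile bins; edges are the
#' empirical quantiles, so bins are (near-)equally populated.  Duplicate
#' quantiles caused by heavy ties collapse the affected bins into their
#' neighbor with a warning.
#'
#' @param y_train training phenotypes (length >= n_bins).
#' @param n_bins number of bins.
#' @return list: `bin` (assignment per animal, 1..n_bins_effective),
#'   `edges` (vector of bin edges, length n_bins_effective + 1),
#'   `midpoints` (average of each bin's edges).
#' @export
bin_phenotypes <- function(y_train, n_bins = 10L) {
  if (length(y_train) < n_bins) stop("need at least n_bins phenotypes")
  edges <- stats::quantile(y_train, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7)
  if (anyDuplicated(edges)) {
    warning("tied quantiles: merging empty bins with their neighbors")
    edges <- unique(edges)
  }
  if (length(edges) < 2) stop("phenotype distribution is degenerate")
  bin <- findInterval(y_train, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  list(bin = bin, edges = edges,
       midpoints = (edges[-length(edges)] + edges[-1]) / 2)
}

#' Train a variational autoencoder on training genotypes
#'
#' Standard Gaussian-latent VAE: the encoder maps a genotype row to
#' per-dimension means and log-variances, a reparameterized sample feeds the
#' decoder, and the loss is the reconstruction term (per-marker 3-class
#' cross-entropy under the default softmax head, or mean squared error under
#' the round head) plus `kl_weight` times the KL divergence to the standard
#' normal (averaged over the batch).
#'
#' @param X_train n x m dosage matrix (QC'd, no missingness).
#' @param config a [vae_config()].
#' @param verbose print per-epoch losses.
#' @return object of class `vae_model` with `encoder`, `mu_head`,
#'   `logvar_head`, `decoder` layer stacks, `config`, `n_markers`,
#'   `history`.
#' @export
train_vae <- function(X_train, config = vae_config(), verbose = FALSE) {
  m <- ncol(X_train)
  n <- nrow(X_train)
  set.seed(config$seed)
  ld <- config$latent_dim
  enc <- list(); p <- m
  for (u in config$encoder_sizes) {
    enc <- c(enc, list(nn_dense(p, u)))
    p <- u
  }
  mu_head <- list(nn_dense(p, ld, act = "linear"))
  lv_head <- list(nn_dense(p, ld, act = "linear"))
  dec <- list(); p <- ld
  for (u in config$decoder_sizes) {
    dec <- c(dec, list(nn_dense(p, u)))
    p <- u
  }
  out_units <- if (config$output_map == "softmax") 3L * m else m
  dec <- c(dec, list(nn_dense(p, out_units, act = "linear")))

  st_enc <- adam_init(enc); st_mu <- adam_init(mu_head)
  st_lv <- adam_init(lv_head); st_dec <- adam_init(dec)
  t <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     recon = numeric(0), kl = numeric(0))
  lr <- config$learning_rate
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tot <- rec_t <- kl_t <- 0; nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      Xb <- X_train[idx, , drop = FALSE]
      nbatch <- nrow(Xb)
      fe <- nn_forward(enc, Xb, cache = TRUE)
      fmu <- nn_forward(mu_head, fe$out, cache = TRUE)
      flv <- nn_forward(lv_head, fe$out, cache = TRUE)
      mu <- fmu$out; lv <- pmin(pmax(flv$out, -10), 10)
      epsm <- matrix(stats::rnorm(nbatch * ld), nbatch, ld)
      z <- mu + exp(lv / 2) * epsm
      fd <- nn_forward(dec, z, cache = TRUE)
      if (config$output_map == "softmax") {
        # per-marker 3-class cross-entropy on logits (n x 3m, classes fastest)
        sm <- softmax3(fd$out, m, nbatch)
        onehot <- class_onehot(Xb, m, nbatch)
        recon <- -sum(log(pmax(sm[onehot > 0], 1e-12))) / (nbatch * m)
        dRecon <- (sm - onehot) / (nbatch * m)
      } else {
        err <- fd$out - Xb
        recon <- mean(err^2)
        dRecon <- 2 * err / (nbatch * m)
      }
      kl <- mean(rowSums(exp(lv) + mu^2 - 1 - lv)) / 2
      loss <- recon + config$kl_weight * kl
      if (!is.finite(loss)) stop("NaN/Inf VAE loss; lower the learning rate")
      bd <- nn_backward(dec, fd$caches, dRecon)
      dz <- bd$dInput
      dmu <- dz + config$kl_weight * mu / nbatch
      dlv <- dz * epsm * exp(lv / 2) / 2 +
        config$kl_weight * (exp(lv) - 1) / (2 * nbatch)
      bmu <- nn_backward(mu_head, fmu$caches, dmu)
      blv <- nn_backward(lv_head, flv$caches, dlv)
      be <- nn_backward(enc, fe$caches, bmu$dInput + blv$dInput)
      t <- t + 1L
      u1 <- adam_step(dec, bd$grads, st_dec, t, lr)
      dec <- u1$layers; st_dec <- u1$state
      u2 <- adam_step(mu_head, bmu$grads, st_mu, t, lr)
      mu_head <- u2$layers; st_mu <- u2$state
      u3 <- adam_step(lv_head, blv$grads, st_lv, t, lr)
      lv_head <- u3$layers; st_lv <- u3$state
      u4 <- adam_step(enc, be$grads, st_enc, t, lr)
      enc <- u4$layers; st_enc <- u4$state
      tot <- tot + loss; rec_t <- rec_t + recon; kl_t <- kl_t + kl
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot / nb,
                                   recon = rec_t / nb, kl = kl_t / nb))
    if (verbose)
      message(sprintf("VAE epoch %d: loss %.4f (recon %.4f, kl %.4f)",
                      ep, tot / nb, rec_t / nb, kl_t / nb))
  }
  structure(list(encoder = enc, mu_head = mu_head, logvar_head = lv_head,
                 decoder = dec, config = config, n_markers = m,
                 history = hist),
            class = "vae_model")
}

#' Encode genotype rows to latent means
#' @param vae a `vae_model`.
#' @param X dosage matrix.
#' @return n x latent_dim matrix of posterior means.
#' @export
vae_encode <- function(vae, X) {
  h <- nn_forward(vae$encoder, as.matrix(X))
  nn_forward(vae$mu_head, h)
}

#' Decode latent vectors to genotype codes
#'
#' Deterministic decode: under the softmax head each marker takes its
#' most probable class; under the round head the regression output is
#' rounded and clipped to \{0,1,2\}.  Set `sample = TRUE` to draw each
#' marker's class from the softmax probabilities instead (used when
#' generating synthetic animals, so genotype frequencies are preserved).
#'
#' @param vae a `vae_model`.
#' @param Z latent matrix.
#' @param sample draw classes stochastically (softmax head only).
#' @return matrix of 0/1/2 genotype codes.
#' @export
vae_decode <- function(vae, Z, sample = FALSE) {
  Z <- as.matrix(Z)
  out <- nn_forward(vae$decoder, Z)
  m <- vae$n_markers
  n <- nrow(Z)
  if (vae$config$output_map == "round")
    return(pmin(pmax(round(out), 0), 2))
  P <- array(softmax3(out, m, n), c(n, 3, m))
  if (!sample) {
    G <- (P[, 2, , drop = FALSE] > P[, 1, , drop = FALSE] &
            P[, 2, , drop = FALSE] >= P[, 3, , drop = FALSE]) * 1 +
      (P[, 3, , drop = FALSE] > P[, 1, , drop = FALSE] &
         P[, 3, , drop = FALSE] > P[, 2, , drop = FALSE]) * 2
    return(matrix(G, n, m))
  }
  u <- matrix(stats::runif(n * m), n, m)
  p0 <- matrix(P[, 1, , drop = FALSE], n, m)
  p1 <- matrix(P[, 2, , drop = FALSE], n, m)
  (u > p0) * 1 + (u > p0 + p1) * 1
}

#' Generate phenotype-binned synthetic animals
#'
#' For each phenotype bin, fits a diagonal Gaussian to the posterior means of
#' that bin's training animals in latent space, samples `per_bin` latent
#' vectors, decodes them to 0/1/2 genotype rows, and assigns every synthetic
#' animal the average of its bin's edges as phenotype.  Bins with a single
#' member are sampled from that member's posterior mean with unit spread.
#'
#' @param vae a trained `vae_model`.
#' @param X_train training genotypes (rows aligned with `bins$bin`).
#' @param bins result of [bin_phenotypes()] on the training phenotypes.
#' @param per_bin synthetic rows per bin (defaults to the VAE config).
#' @return object of class `synthetic_batch`: `genotypes` (matrix of 0/1/2),
#'   `phenotypes` (bin midpoints), `bin_id`, `provenance` (all
#'   `"synthetic"`).
#' @export
generate_synthetic <- function(vae, X_train, bins,
                               per_bin = vae$config$per_bin) {
  stopifnot(nrow(X_train) == length(bins$bin))
  set.seed(vae$config$seed + 1L)
  MU <- vae_encode(vae, X_train)
  n_bins <- length(bins$midpoints)
  ld <- ncol(MU)
  geno <- list(); phen <- numeric(0); bin_id <- integer(0)
  for (b in seq_len(n_bins)) {
    rows <- which(bins$bin == b)
    if (!length(rows)) next
    mu_b <- colMeans(MU[rows, , drop = FALSE])
    sd_b <- if (length(rows) >= 2)
      apply(MU[rows, , drop = FALSE], 2, stats::sd) else rep(1, ld)
    Z <- matrix(stats::rnorm(per_bin * ld, mean = rep(mu_b, each = per_bin),
                             sd = rep(sd_b, each = per_bin)),
                per_bin, ld)
    geno[[length(geno) + 1L]] <- vae_decode(vae, Z, sample = TRUE)
    phen <- c(phen, rep(bins$midpoints[b], per_bin))
    bin_id <- c(bin_id, rep(b, per_bin))
  }
  G <- do.call(rbind, geno)
  rownames(G) <- sprintf("syn%04d", seq_len(nrow(G)))
  structure(list(genotypes = G, phenotypes = phen, bin_id = bin_id,
                 provenance = rep("synthetic", nrow(G))),
            class = "synthetic_batch")
}

#' Append synthetic animals to a training set
#'
#' Row-concatenates the synthetic batch below the real training data.
#' Validation and test sets are untouched by construction (the batch only
#' ever enters the training rows).
#'
#' @param X_train,y_train real training genotypes and phenotypes.
#' @param batch a `synthetic_batch` (or NULL/empty for the identity).
#' @return list `X`, `y`, `provenance` (`"real"`/`"synthetic"` per row).
#' @export
augment <- function(X_train, y_train, batch) {
  if (is.null(batch) || !nrow(batch$genotypes))
    return(list(X = X_train, y = y_train,
                provenance = rep("real", nrow(X_train))))
  if (ncol(batch$genotypes) != ncol(X_train))
    stop("synthetic and real marker columns do not match")
  list(X = rbind(X_train, batch$genotypes),
       y = c(y_train, batch$phenotypes),
       provenance = c(rep("real", nrow(X_train)), batch$provenance))
}
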