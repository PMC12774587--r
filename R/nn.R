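# Minimal feed-forward network engine: dense and 1-D convolution layers,
# leaky-ReLU activations, He-normal initialization, L1/L2 kernel penalties,
# Adam optimization.  Everything is plain R matrix algebra so that training
# is bit-reproducible under a fixed seed in a single-threaded session.

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

nn_dense <- function(p, units, act = "leaky_relu", alpha = 0.3,
                     l1 = 0, l2 = 0) {
  list(type = "dense", W = he_init(p, units, p), b = rep(0, units),
       act = act, alpha = alpha, l1 = l1, l2 = l2)
}

nn_conv <- function(kernel, filters, act = "leaky_relu", alpha = 0.3,
                    l1 = 0, l2 = 0) {
  list(type = "conv", W = he_init(kernel, filters, kernel),
       b = rep(0, filters), kernel = kernel, filters = filters,
       act = act, alpha = alpha, l1 = l1, l2 = l2)
}

nn_maxpool <- function(size) list(type = "maxpool", size = size)
nn_flatten <- function() list(type = "flatten")

act_fwd <- function(z, act, alpha) {
  switch(act,
         linear = z,
         leaky_relu = ifelse(z > 0, z, alpha * z),
         stop("unknown activation"))
}
act_grad <- function(z, act, alpha) {
  switch(act,
         linear = array(1, dim = dim(z) %||% length(z)),
         leaky_relu = ifelse(z > 0, 1, alpha))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# forward pass; input A is n x m.  Returns list(out, cache) when
# cache = TRUE (training) else just the output matrix (n x units_last).
nn_forward <- function(layers, A, cache = FALSE) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    if (L$type == "dense") {
      if (is.array(A) && length(dim(A)) == 3)
        A <- matrix(A, dim(A)[1], dim(A)[2] * dim(A)[3])
      Z <- sweep(A %*% L$W, 2, L$b, "+")
      out <- act_fwd(Z, L$act, L$alpha)
      if (cache) caches[[li]] <- list(A = A, Z = Z)
    } else if (L$type == "conv") {
      n <- nrow(A); m <- ncol(A); k <- L$kernel
      if (k > m) stop("kernel larger than the marker axis")
      len <- m - k + 1
      # patches[i, pos, j] = A[i, pos + j - 1]
      cols <- as.vector(outer(seq_len(len), seq_len(k) - 1L, "+"))
      P <- array(A[, cols], c(n, len, k))
      Z <- matrix(P, n * len, k) %*% L$W
      Z <- sweep(Z, 2, L$b, "+")
      Z <- array(Z, c(n, len, L$filters))
      out <- act_fwd(Z, L$act, L$alpha)
      if (cache) caches[[li]] <- list(P = P, Z = Z, m = m)
    } else if (L$type == "maxpool") {
      d <- dim(A)                      # n x len x f
      npool <- d[2] %/% L$size
      if (npool < 1) stop("pool window larger than the convolved axis")
      Acut <- A[, seq_len(npool * L$size), , drop = FALSE]
      G <- array(Acut, c(d[1], L$size, npool, d[3]))
      M <- G[, 1, , , drop = FALSE]
      am <- array(1L, dim(M))
      for (j in seq_len(L$size)[-1]) {
        Gj <- G[, j, , , drop = FALSE]
        upd <- Gj > M
        M[upd] <- Gj[upd]
        am[upd] <- j
      }
      out <- array(M, c(d[1], npool, d[3]))
      if (cache) caches[[li]] <- list(argmax = array(am, c(d[1], npool, d[3])),
                                      d_in = d, npool = npool)
    } else if (L$type == "flatten") {
      d <- dim(A)
      out <- matrix(A, d[1], prod(d[-1]))
      if (cache) caches[[li]] <- list(d_in = d)
    } else stop("unknown layer type")
    A <- out
  }
  if (cache) list(out = A, caches = caches) else A
}

# backward pass: dOut is the gradient wrt the network output (n x units).
# Returns list(grads = per-layer list(dW, db), ...) including the kernel
# penalty gradients.
nn_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (li in rev(seq_along(layers))) {
    L <- layers[[li]]
    cc <- caches[[li]]
    if (L$type == "dense") {
      dZ <- dA * act_grad(cc$Z, L$act, L$alpha)
      dW <- crossprod(cc$A, dZ) + L$l1 * sign(L$W) + 2 * L$l2 * L$W
      db <- colSums(dZ)
      dA <- dZ %*% t(L$W)
      grads[[li]] <- list(dW = dW, db = db)
    } else if (L$type == "conv") {
      d <- dim(cc$Z)                   # n x len x f
      dZ <- dA * act_grad(cc$Z, L$act, L$alpha)
      dZm <- matrix(dZ, d[1] * d[2], d[3])
      Pm <- matrix(cc$P, d[1] * d[2], L$kernel)
      dW <- crossprod(Pm, dZm) + L$l1 * sign(L$W) + 2 * L$l2 * L$W
      db <- colSums(dZm)
      dP <- array(dZm %*% t(L$W), c(d[1], d[2], L$kernel))
      dX <- matrix(0, d[1], cc$m)
      for (j in seq_len(L$kernel))
        dX[, j:(d[2] + j - 1)] <- dX[, j:(d[2] + j - 1)] + dP[, , j]
      dA <- dX
      grads[[li]] <- list(dW = dW, db = db)
    } else if (L$type == "maxpool") {
      d <- cc$d_in
      npool <- cc$npool
      dG <- array(0, c(d[1], L$size, npool, d[3]))
      # scatter pooled gradients back to the argmax positions
      idx <- cbind(as.vector(slice.index(cc$argmax, 1)),
                   as.vector(cc$argmax),
                   as.vector(slice.index(cc$argmax, 2)),
                   as.vector(slice.index(cc$argmax, 3)))
      dG[idx] <- as.vector(dA)
      dX <- array(0, d)
      dX[, seq_len(npool * L$size), ] <- array(dG, c(d[1], npool * L$size,
                                                     d[3]))
      dA <- dX
      grads[[li]] <- list()
    } else if (L$type == "flatten") {
      dA <- array(dA, cc$d_in)
      grads[[li]] <- list()
    }
  }
  list(grads = grads, dInput = dA)
}

nn_penalty <- function(layers) {
  s <- 0
  for (L in layers)
    if (!is.null(L$W)) s <- s + L$l1 * sum(abs(L$W)) + L$l2 * sum(L$W^2)
  s
}

# Adam state and update ------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(L) {
    if (is.null(L$W)) return(NULL)
    list(mW = L$W * 0, vW = L$W * 0, mb = L$b * 0, vb = L$b * 0)
  })
}

adam_step <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (li in seq_along(layers)) {
    if (is.null(layers[[li]]$W)) next
    s <- state[[li]]; g <- grads[[li]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    layers[[li]]$W <- layers[[li]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    layers[[li]]$b <- layers[[li]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[li]] <- s
  }
  list(layers = layers, state = state)
}

nn_n_params <- function(layers) {
  sum(vapply(layers, function(L)
    if (is.null(L$W)) 0L else length(L$W) + length(L$b), integer(1)))
}
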