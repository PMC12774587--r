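#' Multi-component genomic REML (average information with EM fallback)
#'
#' Fits y = mu + sum of random genetic effects + residual, where each random
#' effect g_i ~ N(0, K_i sigma_i^2) for a supplied relationship matrix K_i
#' and the residual is i.i.d.  Variance components are estimated by
#' restricted maximum likelihood using average-information updates; whenever
#' an AI step leaves the feasible region the offending components fall back
#' to an expectation-maximization step, and all components are floored at
#' `floor_frac * var(y)`.  Standard errors come from the inverse AI matrix
#' at convergence.
#'
#' Model tags follow the usual naming: `"A"` fits \{G\}, `"AD"` \{G, D\},
#' `"AE"` \{G, E_aa\}, `"ADE"` \{G, D, E_aa\}; the matrices must be supplied
#' in that order.
#'
#' @param y numeric phenotype vector (typically pre-corrected and
#'   z-normalized).
#' @param matrices list of `rel_matrix` objects (or plain symmetric
#'   matrices), one per genetic component, matching `model_tag`.
#' @param model_tag one of `"A"`, `"AD"`, `"AE"`, `"ADE"`; used to label the
#'   components and validate the matrix kinds.
#' @param max_iter maximum REML iterations (default 100).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param floor_frac lower bound for each variance component as a fraction
#'   of var(y) (default 1e-6).
#' @param verbose print per-iteration progress.
#' @return object of class `var_components`: `components` (named vector of
#'   variance estimates, one per matrix plus `"eps"`), `se` (from the
#'   inverse AI matrix), `ai_inv` (covariance matrix of the estimates),
#'   `loglik`, `n_iterations`, `converged`, `model_tag`, `floor`.
#' @export
fit_reml <- function(y, matrices, model_tag = c("A", "AD", "AE", "ADE"),
                     max_iter = 100L, tol = 1e-6, floor_frac = 1e-6,
                     verbose = FALSE) {
  model_tag <- match.arg(model_tag)
  expected <- list(A = "additive",
                   AD = c("additive", "dominance"),
                   AE = c("additive", "epistatic"),
                   ADE = c("additive", "dominance", "epistatic"))[[model_tag]]
  if (length(matrices) != length(expected))
    stop(sprintf("model %s needs %d relationship matrices", model_tag,
                 length(expected)))
  Ks <- lapply(matrices, function(K)
    if (inherits(K, "rel_matrix")) K$values else as.matrix(K))
  kinds <- vapply(matrices, function(K)
    if (inherits(K, "rel_matrix")) K$kind else NA_character_, character(1))
  if (!anyNA(kinds) && !identical(unname(kinds), expected))
    stop(sprintf("model %s expects matrices of kind {%s}", model_tag,
                 paste(expected, collapse = ", ")))
  n <- length(y)
  if (any(vapply(Ks, nrow, 1L) != n)) stop("matrix/phenotype size mismatch")

  comp_names <- c(c("a", "d", "eaa")[match(expected,
                                           c("additive", "dominance",
                                             "epistatic"))], "eps")
  q <- length(Ks) + 1L           # genetic components + residual
  vy <- stats::var(y)
  floor_val <- floor_frac * vy
  sigma <- rep(vy / q, q)
  X <- matrix(1, n, 1)

  reml_ll <- function(sigma) {
    V <- diag(sigma[q], n)
    for (i in seq_len(q - 1)) V <- V + sigma[i] * Ks[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    P <- Vi - t(XtVi) %*% solve(XtViX, XtVi)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                    sum(y * Py))
    list(ll = as.numeric(ll), P = P, Py = drop(Py))
  }

  state <- reml_ll(sigma)
  if (!is.finite(state$ll)) stop("initial V not positive definite")
  converged <- FALSE
  AI <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    P <- state$P; Py <- state$Py
    KPy <- vector("list", q)
    for (i in seq_len(q - 1)) KPy[[i]] <- Ks[[i]] %*% Py
    KPy[[q]] <- Py
    # score: dl/dsigma_i = -0.5 (tr(P K_i) - y' P K_i P y);
    # tr(P K_i) via the elementwise product of the symmetric matrices
    score <- numeric(q)
    PKPy <- vector("list", q)
    for (i in seq_len(q)) {
      trPK <- if (i < q) sum(P * Ks[[i]]) else sum(diag(P))
      PKPy[[i]] <- P %*% KPy[[i]]
      score[i] <- -0.5 * (trPK - sum(Py * KPy[[i]]))
    }
    AI <- matrix(0, q, q)
    for (i in seq_len(q)) for (j in i:q) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    }
    # expectation-maximization proposal (guaranteed ascent direction)
    em <- sigma
    for (i in seq_len(q)) {
      trPK <- if (i < q) sum(P * Ks[[i]]) else sum(diag(P))
      em[i] <- sigma[i] + sigma[i]^2 * (sum(Py * KPy[[i]]) - trPK) / n
    }
    em <- pmax(em, floor_val)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    ai_prop <- if (is.null(step)) em else sigma + step
    # components an AI update pushes out of the feasible region fall back
    # to their EM update; a third candidate clamps them to the floor,
    # which handles boundary estimates in one jump
    bad <- !is.finite(ai_prop) | ai_prop < floor_val
    mixed <- ai_prop; mixed[bad] <- em[bad]
    clamped <- ai_prop; clamped[bad] <- floor_val
    candidates <- unique(list(pmax(mixed, floor_val), em,
                              pmax(clamped, floor_val)))
    new_state <- NULL; proposal <- NULL
    for (cand in candidates) {
      st <- reml_ll(cand)
      if (is.finite(st$ll) && (is.null(new_state) || st$ll > new_state$ll)) {
        new_state <- st; proposal <- cand
      }
    }
    # halve toward the current point if every candidate misbehaves
    halvings <- 0L
    while ((is.null(new_state) || new_state$ll < state$ll - 1e-8) &&
           halvings < 20L) {
      proposal <- if (is.null(proposal)) sigma else
        pmax((proposal + sigma) / 2, floor_val)
      st <- reml_ll(proposal)
      if (is.finite(st$ll)) new_state <- st
      halvings <- halvings + 1L
    }
    if (is.null(new_state) || !is.finite(new_state$ll))
      stop("REML iteration produced a non-positive-definite V")
    delta <- abs(new_state$ll - state$ll)
    if (verbose)
      message(sprintf("iter %d: ll=%.6f sigma=%s", iter, new_state$ll,
                      paste(signif(proposal, 4), collapse = " ")))
    sigma <- proposal
    state <- new_state
    if (delta < tol) { converged <- TRUE; break }
  }
  se <- rep(NA_real_, q)
  ai_inv <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(ai_inv)) se <- sqrt(pmax(diag(ai_inv), 0))
  names(sigma) <- names(se) <- comp_names
  if (!is.null(ai_inv)) dimnames(ai_inv) <- list(comp_names, comp_names)
  structure(list(components = sigma, se = se, ai_inv = ai_inv,
                 loglik = state$ll, n_iterations = iter,
                 converged = converged, model_tag = model_tag,
                 floor = floor_val),
            class = "var_components")
}

#' Construct a variance-component record from known values
#'
#' Useful for computing ratios/heritabilities from externally reported
#' component estimates (e.g. a published table) with [ratios()].
#'
#' @param components named numeric vector; genetic components among
#'   `"a"`, `"d"`, `"eaa"` plus residual `"eps"`.
#' @param se optional standard errors (same names).
#' @param model_tag model label.
#' @return a `var_components` object (without likelihood information).
#' @export
variance_components <- function(components, se = NULL,
                                model_tag = c("A", "AD", "AE", "ADE")) {
  model_tag <- match.arg(model_tag)
  if (is.null(names(components)) || !"eps" %in% names(components))
    stop("components must be named and include 'eps'")
  if (any(components < 0)) stop("variances must be nonnegative")
  if (is.null(se)) se <- rep(NA_real_, length(components))
  structure(list(components = components,
                 se = stats::setNames(se, names(components)),
                 ai_inv = NULL, loglik = NA_real_, n_iterations = 0L,
                 converged = NA, model_tag = model_tag, floor = 0),
            class = "var_components")
}

#' @export
print.var_components <- function(x, ...) {
  cat(sprintf("REML fit (%s model), %d iterations, %sconverged\n",
              x$model_tag, x$n_iterations, if (x$converged) "" else "NOT "))
  print(data.frame(component = names(x$components),
                   estimate = round(x$components, 4),
                   se = round(x$se, 4)))
  invisible(x)
}

#' Restricted log-likelihood at fixed variance components
#'
#' Direct dense evaluation, usable as an independent check of [fit_reml()]'s
#' reported likelihood.
#'
#' @param y phenotype vector.
#' @param matrices genetic relationship matrices (list).
#' @param sigma variance components, genetic components first, residual last.
#' @return the restricted log-likelihood (constant terms omitted, matching
#'   [fit_reml()]).
#' @export
reml_loglik <- function(y, matrices, sigma) {
  Ks <- lapply(matrices, function(K)
    if (inherits(K, "rel_matrix")) K$values else as.matrix(K))
  n <- length(y)
  q <- length(sigma)
  stopifnot(length(Ks) == q - 1)
  V <- diag(sigma[q], n)
  for (i in seq_len(q - 1)) V <- V + sigma[i] * Ks[[i]]
  ch <- chol(V)
  Vi <- chol2inv(ch)
  X <- matrix(1, n, 1)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  P <- Vi - t(XtVi) %*% solve(XtViX, XtVi)
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                       determinant(XtViX)$modulus[1] +
                       sum(y * (P %*% y))))
}

#' Variance ratios and heritabilities
#'
#' Phenotypic variance is the sum of all fitted components; narrow-sense
#' heritability h2 = sigma2_a / sigma2_p, dominance ratio d2, epistasis
#' ratio e2_aa, and broad-sense heritability H2 = h2 + d2 + e2_aa (over the
#' components present in the model).  Standard errors use the delta method
#' on the inverse-AI covariance of the component estimates.
#'
#' @param fit a `var_components` from [fit_reml()].
#' @return object of class `herit_ratios`: `sigma2_p`, `ratios` (named
#'   vector: h2 and, when present, d2, e2_aa, plus H2), `se` (delta-method
#'   standard errors, NA when no covariance is available).
#' @export
ratios <- function(fit) {
  sig <- fit$components
  q <- length(sig)
  sp <- sum(sig)
  if (sp <= 0) stop("phenotypic variance is zero")
  gen <- setdiff(names(sig), "eps")
  ratio_names <- c(a = "h2", d = "d2", eaa = "e2_aa")[gen]
  vals <- sig[gen] / sp
  H2 <- sum(vals)
  out <- c(stats::setNames(vals, ratio_names), H2 = H2)
  se <- stats::setNames(rep(NA_real_, length(out)), names(out))
  if (!is.null(fit$ai_inv)) {
    C <- fit$ai_inv
    for (i in seq_along(gen)) {
      g <- rep(-sig[gen[i]] / sp^2, q)
      g[match(gen[i], names(sig))] <- (sp - sig[gen[i]]) / sp^2
      se[i] <- sqrt(max(0, drop(t(g) %*% C %*% g)))
    }
    sg <- sum(sig[gen])
    gH <- rep(-sg / sp^2, q)
    gH[match(gen, names(sig))] <- gH[match(gen, names(sig))] + 1 / sp
    se["H2"] <- sqrt(max(0, drop(t(gH) %*% C %*% gH)))
  }
  structure(list(sigma2_p = sp, ratios = out, se = se,
                 model_tag = fit$model_tag),
            class = "herit_ratios")
}

#' @export
print.herit_ratios <- function(x, ...) {
  cat(sprintf("sigma2_p = %.4f (%s model)\n", x$sigma2_p, x$model_tag))
  print(data.frame(ratio = names(x$ratios),
                   estimate = round(x$ratios, 4), se = round(x$se, 4)))
  invisible(x)
}

#' BLUP prediction of genetic values for test animals
#'
#' Given variance components fitted on the training animals, predicts each
#' genetic component for the test animals as
#' sigma_i^2 K_i\[test, train\] V_train^{-1} (y_train - mu_hat), where
#' V_train is the phenotypic covariance among training animals and mu_hat
#' the GLS intercept.  The additive component is returned as the EBV.
#'
#' @param fit a `var_components` fitted on the training subset.
#' @param matrices relationship matrices spanning train and test animals
#'   (same order as in the fit).
#' @param y_train training phenotypes.
#' @param train_idx,test_idx row indices of training and test animals in
#'   the matrices.
#' @return list: `ebv` (additive prediction for test animals), `components`
#'   (matrix of per-component predictions), `total` (their sum), `mu`.
#' @export
predict_genetic_values <- function(fit, matrices, y_train, train_idx,
                                   test_idx) {
  Ks <- lapply(matrices, function(K)
    if (inherits(K, "rel_matrix")) K$values else as.matrix(K))
  sig <- fit$components
  q <- length(sig)
  stopifnot(length(Ks) == q - 1, length(y_train) == length(train_idx))
  nt <- length(train_idx)
  V <- diag(sig[q], nt)
  for (i in seq_len(q - 1))
    V <- V + sig[i] * Ks[[i]][train_idx, train_idx]
  ch <- tryCatch(chol(V), error = function(e)
    stop("training covariance matrix is singular"))
  Vi <- chol2inv(ch)
  one <- rep(1, nt)
  mu <- sum(Vi %*% y_train) / sum(Vi %*% one)
  w <- drop(Vi %*% (y_train - mu))
  comps <- sapply(seq_len(q - 1), function(i)
    drop(sig[i] * Ks[[i]][test_idx, train_idx, drop = FALSE] %*% w))
  comps <- matrix(comps, nrow = length(test_idx))
  colnames(comps) <- names(sig)[seq_len(q - 1)]
  list(ebv = unname(comps[, 1]), components = comps,
       total = rowSums(comps), mu = mu)
}
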