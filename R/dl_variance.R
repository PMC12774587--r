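#' Probe matrix for black-box linearization
#'
#' An (m+1) x m pseudo-genotype matrix: row 1 is all zeros, rows 2..m+1 the
#' identity (one marker set to code 1, all others 0).  Feeding it to a
#' trained predictor yields the per-marker additive effects as differences
#' from the all-zero prediction.
#'
#' @param m number of markers (>= 1).
#' @return the (m+1) x m probe matrix.
#' @export
build_probe <- function(m) {
  if (m < 1) stop("m must be at least 1")
  rbind(rep(0, m), diag(m))
}

# Call a predictor: either a plain function X -> predictions, or an object
# with a predict method (e.g. a dl_model).
call_model <- function(model, X) {
  p <- if (is.function(model)) model(X) else stats::predict(model, X)
  drop(as.numeric(p))
}

#' Extract per-marker additive effects from any trained predictor
#'
#' a_k = f(e_k) - f(0), where e_k is the probe row with marker k set to 1;
#' one batched forward pass over [build_probe()].  Because probe rows never
#' set two markers simultaneously, interactions are invisible here by
#' design: a measures each marker's 0-to-1 (heterozygote-step) effect.
#'
#' @param model a function of a genotype matrix, or an object with a
#'   `predict` method taking `(object, newdata)`.
#' @param m number of markers the model accepts.
#' @return list: `a` (length-m additive effects), `y0_hat` (prediction of
#'   the all-zero genotype).
#' @export
extract_additive_effects <- function(model, m) {
  preds <- call_model(model, build_probe(m))
  if (length(preds) != m + 1)
    stop("model did not return one prediction per probe row")
  list(a = preds[-1] - preds[1], y0_hat = preds[1])
}

#' Estimated breeding values from linearized effects
#'
#' EBV = X a.
#'
#' @param X_test n x m dosage matrix.
#' @param a per-marker additive effects.
#' @return numeric vector of EBVs.
#' @export
compute_ebv <- function(X_test, a) {
  if (ncol(X_test) != length(a)) stop("marker count mismatch")
  drop(as.matrix(X_test) %*% a)
}

#' Estimated genetic values: the model's own predictions
#'
#' EGV = f(X).
#'
#' @param model predictor (function or object with a `predict` method).
#' @param X_test n x m dosage matrix.
#' @return numeric vector of EGVs.
#' @export
compute_egv <- function(model, X_test) {
  call_model(model, as.matrix(X_test))
}

#' Nonadditive variance summary
#'
#' n2 = 1 - corr(EGV, EBV)^2 is the fraction of the model's predicted
#' genetic variance not explained by its own linear approximation;
#' sigma2_u_dl is the sample variance of the EGVs on the test set, and
#' sigma2_na_dl = n2 * sigma2_u_dl the nonadditive variance.
#'
#' @param ebv,egv aligned numeric vectors (length >= 3, both non-constant).
#' @return list: `n2`, `sigma2_u_dl`, `sigma2_na_dl`, `corr`.
#' @export
nonadditive_summary <- function(ebv, egv) {
  if (length(ebv) != length(egv) || length(ebv) < 3)
    stop("ebv and egv must be aligned vectors of length >= 3")
  if (stats::sd(ebv) == 0 || stats::sd(egv) == 0)
    stop("constant ebv or egv: n2 undefined")
  r <- stats::cor(egv, ebv)
  n2 <- 1 - r^2
  s2u <- stats::var(egv)
  list(n2 = n2, sigma2_u_dl = s2u, sigma2_na_dl = n2 * s2u, corr = r)
}

#' Full linearization of a trained predictor on a test set
#'
#' Convenience wrapper running [extract_additive_effects()],
#' [compute_ebv()], [compute_egv()] and [nonadditive_summary()].
#'
#' @inheritParams compute_egv
#' @return object of class `linearization_result` with `a`, `y0_hat`,
#'   `ebv`, `egv`, `n2`, `sigma2_u_dl`, `sigma2_na_dl`.
#' @export
linearize_model <- function(model, X_test) {
  m <- ncol(X_test)
  ex <- extract_additive_effects(model, m)
  ebv <- compute_ebv(X_test, ex$a)
  egv <- compute_egv(model, X_test)
  s <- nonadditive_summary(ebv, egv)
  structure(list(a = ex$a, y0_hat = ex$y0_hat, ebv = ebv, egv = egv,
                 n2 = s$n2, sigma2_u_dl = s$sigma2_u_dl,
                 sigma2_na_dl = s$sigma2_na_dl),
            class = "linearization_result")
}

#' Pool linearization results across splits
#'
#' Averages EBV and EGV per test animal across splits (default) or
#' concatenates them, then recomputes the nonadditive summary on the pooled
#' vectors and the comparison correlations against the test phenotypes.
#'
#' @param results list of `linearization_result`s with aligned test animals.
#' @param y_test test phenotypes (aligned with each result's vectors).
#' @param mode `"average"` (per-animal mean over splits) or `"concat"`.
#' @return list: `n2`, `sigma2_u_dl`, `sigma2_na_dl`, `cor_avg_ebv`
#'   (corr(avg EBV, y_test)), `cor_avg_egv`, `avg_ebv`, `avg_egv`.
#' @export
pooled_summary <- function(results, y_test, mode = c("average", "concat")) {
  mode <- match.arg(mode)
  if (!length(results)) stop("no split results supplied")
  nt <- length(results[[1]]$ebv)
  if (any(vapply(results, function(r) length(r$ebv), 1L) != nt))
    stop("misaligned test sets across splits")
  EBV <- do.call(rbind, lapply(results, function(r) r$ebv))
  EGV <- do.call(rbind, lapply(results, function(r) r$egv))
  avg_ebv <- colMeans(EBV)
  avg_egv <- colMeans(EGV)
  pooled <- if (mode == "average") nonadditive_summary(avg_ebv, avg_egv)
  else nonadditive_summary(as.vector(t(EBV)), as.vector(t(EGV)))
  out <- list(n2 = pooled$n2, sigma2_u_dl = pooled$sigma2_u_dl,
              sigma2_na_dl = pooled$sigma2_na_dl,
              avg_ebv = avg_ebv, avg_egv = avg_egv)
  if (!is.null(y_test)) {
    stopifnot(length(y_test) == nt)
    out$cor_avg_ebv <- stats::cor(avg_ebv, y_test)
    out$cor_avg_egv <- stats::cor(avg_egv, y_test)
  }
  out
}
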