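#' Relationship matrix container
#'
#' @param values symmetric n x n numeric matrix.
#' @param kind one of `"additive"`, `"dominance"`, `"epistatic"`.
#' @param ids individual identifiers (row/column order).
#' @param n_markers_used number of markers behind the matrix.
#' @param scaling_factor_v trace-based scaling factor (epistatic kind only).
#' @return an object of class `rel_matrix`.
#' @export
rel_matrix <- function(values, kind = c("additive", "dominance", "epistatic"),
                       ids = NULL, n_markers_used = NA_integer_,
                       scaling_factor_v = NA_real_) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, kind = kind, ids = ids,
                 n_markers_used = n_markers_used,
                 scaling_factor_v = scaling_factor_v),
            class = "rel_matrix")
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix (%s): %d individuals, %s markers, mean diag %.3f\n",
              x$kind, nrow(x$values),
              ifelse(is.na(x$n_markers_used), "?", x$n_markers_used),
              mean(diag(x$values))))
  invisible(x)
}

#' Reference-allele frequencies
#'
#' @param genotypes a [geno_matrix()] (or plain dosage matrix) without
#'   missing values.
#' @return per-marker frequency p_k = (sum of dosages)/(2n).
#' @export
allele_frequencies <- function(genotypes) {
  X <- if (inherits(genotypes, "geno_matrix")) genotypes$X else genotypes
  p <- colMeans(X) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic markers present; run QC before computing frequencies")
  p
}

#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' G_ij = sum_k (t_ik - 2 p_k)(t_jk - 2 p_k) / sum_k 2 p_k (1 - p_k),
#' with dosages t in 0/1/2 and a single global denominator.
#'
#' @param genotypes a [geno_matrix()] or dosage matrix.
#' @param frequencies optional externally supplied p_k (e.g. training-set
#'   frequencies); defaults to the analyzed sample's own frequencies.
#' @return a `rel_matrix` of kind `"additive"`.
#' @export
build_G <- function(genotypes, frequencies = NULL) {
  X <- if (inherits(genotypes, "geno_matrix")) genotypes$X else genotypes
  ids <- rownames(X)
  p <- if (is.null(frequencies)) allele_frequencies(X) else frequencies
  if (any(p <= 0 | p >= 1)) stop("frequencies must lie strictly in (0,1)")
  denom <- sum(2 * p * (1 - p))
  if (denom == 0) stop("zero denominator: all markers monomorphic")
  W <- sweep(X, 2, 2 * p)
  G <- tcrossprod(W) / denom
  rel_matrix(G, "additive", ids = ids, n_markers_used = ncol(X))
}

#' Dominance genomic relationship matrix
#'
#' D_ij = (1/m) sum_k (z_ik - 2 p_k q_k)(z_jk - 2 p_k q_k) / (2 p_k^2 q_k^2),
#' where z = 1 for heterozygotes and 0 otherwise and q = 1 - p; the
#' denominator is per marker and the sum is averaged over the m markers.
#'
#' The verbatim formula has an expected diagonal of (1 - 2pq)/(pq) per
#' marker (2 at p = 0.5, larger at low MAF), so variance components
#' estimated against it are not on the phenotypic-variance scale.
#' `normalize = TRUE` divides the matrix by trace/n, giving mean diagonal 1;
#' this scalar reparameterization leaves likelihoods and predictions
#' unchanged but makes the fitted dominance variance directly comparable
#' with the phenotypic variance, and is what the REML pipeline uses.
#'
#' @inheritParams build_G
#' @param normalize divide by trace/n so the mean diagonal is 1
#'   (default FALSE: the formula above, verbatim).
#' @return a `rel_matrix` of kind `"dominance"`.
#' @export
build_D <- function(genotypes, frequencies = NULL, normalize = FALSE) {
  X <- if (inherits(genotypes, "geno_matrix")) genotypes$X else genotypes
  ids <- rownames(X)
  p <- if (is.null(frequencies)) allele_frequencies(X) else frequencies
  if (any(p <= 0 | p >= 1)) stop("frequencies must lie strictly in (0,1)")
  q <- 1 - p
  Z <- (X == 1) * 1
  Zc <- sweep(Z, 2, 2 * p * q)
  Zs <- sweep(Zc, 2, sqrt(2 * p^2 * q^2), "/")
  D <- tcrossprod(Zs) / ncol(X)
  if (normalize) D <- D * nrow(D) / sum(diag(D))
  rel_matrix(D, "dominance", ids = ids, n_markers_used = ncol(X))
}

#' Additive-by-additive epistatic relationship matrix
#'
#' E_aa = (G \eqn{\odot} G) / v with v = tr(G \eqn{\odot} G)/n, so that
#' trace(E_aa) = n by construction.
#'
#' @param G an additive `rel_matrix`.
#' @return a `rel_matrix` of kind `"epistatic"` carrying `scaling_factor_v`.
#' @export
build_Eaa <- function(G) {
  if (!inherits(G, "rel_matrix") || G$kind != "additive")
    stop("build_Eaa expects an additive rel_matrix")
  GG <- G$values * G$values
  v <- sum(diag(GG)) / nrow(GG)
  if (v == 0) stop("scaling factor v is zero (all-zero G)")
  rel_matrix(GG / v, "epistatic", ids = G$ids,
             n_markers_used = G$n_markers_used, scaling_factor_v = v)
}
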