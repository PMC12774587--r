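#' Genotype matrix container
#'
#' Bundles an individuals-by-markers dosage matrix (0/1/2 copies of the
#' reference allele) with per-marker metadata (chromosome) and per-individual
#' metadata (line, birth year).  All downstream stages -- QC, relationship
#' matrices, deep models -- consume this container.
#'
#' @param X integer-valued matrix, individuals in rows, markers in columns.
#'   Values must be 0, 1 or 2; no missingness is allowed.
#' @param chrom character or integer vector of chromosome labels, one per
#'   marker.  Sex chromosomes are labelled `"X"`/`"Y"`.
#' @param samples optional `data.frame` of per-individual metadata with at
#'   least a column `id`; typically also `birth_year` and `line`.
#' @return an object of class `geno_matrix`: a list with elements `X`,
#'   `map` (data.frame with columns `marker`, `chrom`) and `samples`.
#' @export
geno_matrix <- function(X, chrom = NULL, samples = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing genotypes are not supported")
  if (!all(X %in% c(0, 1, 2))) stop("genotype codes must be 0, 1 or 2")
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("snp", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- paste0("ind", seq_len(nrow(X)))
  if (is.null(chrom)) chrom <- rep("1", ncol(X))
  if (length(chrom) != ncol(X)) stop("one chromosome label per marker required")
  if (is.null(samples)) samples <- data.frame(id = rownames(X))
  stopifnot(nrow(samples) == nrow(X))
  structure(list(
    X = X,
    map = data.frame(marker = colnames(X), chrom = as.character(chrom),
                     stringsAsFactors = FALSE),
    samples = samples
  ), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers (%d chromosomes)\n",
              nrow(x$X), ncol(x$X), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$X)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i individual (row) index; missing keeps all.
#' @param j marker (column) index; missing keeps all.
#' @param ... ignored.
#' @return a `geno_matrix` restricted to the selected rows/columns.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  geno_matrix(x$X[i, j, drop = FALSE],
              chrom = x$map$chrom[j],
              samples = x$samples[i, , drop = FALSE])
}
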