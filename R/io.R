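#' Read a PLINK additive-recode (".raw") genotype table
#'
#' Expects the standard header `FID IID PAT MAT SEX PHENOTYPE` followed by
#' one dosage column per marker (marker names carry a `_A`-style allele
#' suffix which is stripped).  Missing dosages are rejected: upstream
#' imputation is assumed.
#'
#' @param file path to the `.raw` file.
#' @param map_file optional CSV with columns `marker`, `chrom`; when absent
#'   all markers are labelled chromosome "1".
#' @return a [geno_matrix()].
#' @export
read_plink_raw <- function(file, map_file = NULL) {
  df <- utils::read.table(file, header = TRUE, check.names = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(need %in% names(df)[1:6]))
    stop("not a PLINK .raw table: missing standard leading columns")
  X <- as.matrix(df[, -(1:6), drop = FALSE])
  colnames(X) <- sub("_[ACGT0-9]+$", "", colnames(X))
  rownames(X) <- as.character(df$IID)
  finish_read(X, df$IID, map_file)
}

#' Read a plain CSV genotype table (id column + one column per marker)
#'
#' @inheritParams read_plink_raw
#' @param file path to the CSV.
#' @return a [geno_matrix()].
#' @export
read_genotype_csv <- function(file, map_file = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (names(df)[1] != "id") stop("first column must be 'id'")
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- as.character(df$id)
  finish_read(X, df$id, map_file)
}

finish_read <- function(X, ids, map_file) {
  if (anyNA(X)) stop("missing genotypes are not supported; impute upstream")
  chrom <- NULL
  if (!is.null(map_file)) {
    map <- utils::read.csv(map_file)
    chrom <- map$chrom[match(colnames(X), map$marker)]
  }
  geno_matrix(X, chrom = chrom, samples = data.frame(id = as.character(ids)))
}

#' Read a phenotype/factor table
#'
#' @param file CSV with at least columns `id` and `y`; factor columns such as
#'   `pen`, `litter`, `MB`, `HYB`, `PD`, `HC`, `birth_year` are carried
#'   through unchanged.
#' @return a data.frame.
#' @export
read_phenotypes <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("id", "y") %in% names(df))) stop("need columns 'id' and 'y'")
  df
}

#' Write a relationship matrix as CSV (ids in the first column)
#' @param K a `rel_matrix`.
#' @param file output path.
#' @export
write_grm_csv <- function(K, file) {
  df <- data.frame(id = K$ids, K$values, check.names = FALSE)
  colnames(df) <- c("id", K$ids)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a relationship matrix written by [write_grm_csv()]
#' @param file CSV path.
#' @param kind matrix kind tag.
#' @return a `rel_matrix`.
#' @export
read_grm_csv <- function(file, kind = "additive") {
  df <- utils::read.csv(file, check.names = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rel_matrix(V, kind = kind, ids = as.character(df$id))
}
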