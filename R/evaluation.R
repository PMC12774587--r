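#' Train/validation/test split scheme
#'
#' Test animals are those born in `test_years`; the remaining pool is split
#' into train/validation partitions either by repeated k-fold cross-validation
#' (default: 10 folds x 5 repeats = 50 splits, each pool animal validating
#' exactly `n_repeats` times) or by repeated random fraction draws (default
#' 20% validation).
#'
#' @param phenotypes data.frame with columns `id` and `birth_year`.
#' @param test_years birth years forming the test set.
#' @param mode `"kfold_repeated"` or `"fraction"`.
#' @param n_folds,n_repeats k-fold settings (mode `"kfold_repeated"`).
#' @param val_fraction,n_splits fraction-mode settings.
#' @param seed RNG seed; the scheme is deterministic given it.
#' @return object of class `split_scheme`: `pool_ids`, `test_ids`, `splits`
#'   (list of lists with `train_ids`, `val_ids`), `mode`, `seed`.
#' @export
make_splits <- function(phenotypes, test_years,
                        mode = c("kfold_repeated", "fraction"),
                        n_folds = 10L, n_repeats = 5L,
                        val_fraction = 0.2, n_splits = 50L, seed = 1L) {
  mode <- match.arg(mode)
  if (!all(c("id", "birth_year") %in% names(phenotypes)))
    stop("phenotype table needs columns 'id' and 'birth_year'")
  test_ids <- as.character(phenotypes$id[phenotypes$birth_year %in% test_years])
  pool_ids <- as.character(phenotypes$id[!phenotypes$birth_year %in% test_years])
  if (!length(test_ids)) stop("no animals in the requested test years")
  set.seed(seed)
  splits <- list()
  if (mode == "kfold_repeated") {
    if (length(pool_ids) < n_folds)
      stop("fewer pool animals than folds")
    for (r in seq_len(n_repeats)) {
      fold <- sample(rep_len(seq_len(n_folds), length(pool_ids)))
      for (f in seq_len(n_folds)) {
        splits[[length(splits) + 1L]] <-
          list(train_ids = pool_ids[fold != f], val_ids = pool_ids[fold == f])
      }
    }
  } else {
    n_val <- round(val_fraction * length(pool_ids))
    if (n_val < 1 || n_val >= length(pool_ids))
      stop("validation fraction leaves an empty train or validation set")
    for (s in seq_len(n_splits)) {
      vi <- sample.int(length(pool_ids), n_val)
      splits[[length(splits) + 1L]] <-
        list(train_ids = pool_ids[-vi], val_ids = pool_ids[vi])
    }
  }
  structure(list(pool_ids = pool_ids, test_ids = test_ids, splits = splits,
                 mode = mode, seed = seed),
            class = "split_scheme")
}

#' @export
print.split_scheme <- function(x, ...) {
  cat(sprintf("split_scheme (%s): %d splits, pool %d, test %d\n",
              x$mode, length(x$splits), length(x$pool_ids),
              length(x$test_ids)))
  invisible(x)
}

check_preds <- function(preds, y_test) {
  preds <- as.matrix(preds)
  if (ncol(preds) != length(y_test))
    stop("prediction columns must align with the test animals")
  if (anyNA(preds)) stop("missing entries in split predictions")
  preds
}

#' Splits-average predictive ability
#'
#' Pearson correlation between predictions and test phenotypes computed per
#' split, then averaged; the spread across splits is the sample SD.  Splits
#' with zero-variance predictions have no defined correlation and are
#' excluded with a warning.
#'
#' @param preds matrix of predictions, one row per split, one column per
#'   test animal.
#' @param y_test test phenotypes.
#' @return list: `mean_r`, `sd_r`, `per_split_r`, `n_excluded`.
#' @export
splits_average <- function(preds, y_test) {
  preds <- check_preds(preds, y_test)
  if (nrow(preds) < 2) stop("need at least 2 splits")
  rs <- apply(preds, 1, function(p) {
    if (stats::sd(p) == 0) NA_real_ else stats::cor(p, y_test)
  })
  n_excl <- sum(is.na(rs))
  if (n_excl > 0)
    warning(sprintf("%d split(s) had zero-variance predictions; excluded",
                    n_excl))
  rs_ok <- rs[!is.na(rs)]
  if (!length(rs_ok)) stop("no split had a defined correlation")
  list(mean_r = mean(rs_ok), sd_r = stats::sd(rs_ok), per_split_r = rs,
       n_excluded = n_excl)
}

#' Averaged-predictions (bagging-style) predictive ability
#'
#' Averages the predicted value of each test animal over all splits first,
#' then computes a single Pearson correlation with the test phenotypes.
#'
#' @inheritParams splits_average
#' @return the correlation r.
#' @export
averaged_predictions <- function(preds, y_test) {
  preds <- check_preds(preds, y_test)
  avg <- colMeans(preds)
  if (stats::sd(avg) == 0)
    stop("averaged prediction vector is constant; r undefined")
  stats::cor(avg, y_test)
}

#' Standard error of a correlation coefficient
#'
#' SE_r = sqrt((1 - r^2) / (n_test - 2)).
#'
#' @param r correlation (|r| < 1).
#' @param n_test number of test animals (> 2).
#' @return the standard error.
#' @export
se_of_r <- function(r, n_test) {
  if (n_test <= 2) stop("n_test must exceed 2")
  if (abs(r) >= 1) stop("|r| must be below 1")
  sqrt((1 - r^2) / (n_test - 2))
}

#' Relative improvement in predictive ability
#'
#' 100 * (r_new / r_base - 1), in percent.
#'
#' @param r_new,r_base correlations; `r_base` must be nonzero.
#' @return the percentage improvement (not rounded; round to 1 decimal in
#'   reports).
#' @export
relative_improvement <- function(r_new, r_base) {
  if (r_base == 0) stop("zero baseline correlation")
  100 * (r_new / r_base - 1)
}
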