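#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on the heterozygote count conditional on the allele
#' counts: the p-value is the summed probability of all heterozygote counts
#' whose conditional probability does not exceed that of the observed count
#' (no mid-p correction).  Probabilities are accumulated in log space so the
#' test stays accurate at the extreme thresholds used for SNP-chip QC
#' (p below 1e-25).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative, total > 0).
#' @return the exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (min(n_AA, n_Aa, n_aa) < 0) stop("counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa      # minor-or-major allele count; symmetric below
  na <- 2 * n_aa + n_Aa
  n_rare <- min(nA, na)
  if (n_rare == 0) return(1)  # monomorphic: single possible configuration
  # feasible heterozygote counts share the parity of the rare allele count
  het <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(n_Aa = h | n, n_rare) up to a constant:
  # P ∝ n_rare! n_common! n! 2^h / ((n_rare-h)/2)! h! ((n_common-h)/2)! (2n)!
  hom_rare <- (n_rare - het) / 2
  hom_common <- n - het - hom_rare
  logp <- het * log(2) - lfactorial(hom_rare) - lfactorial(het) -
    lfactorial(hom_common)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  if (is.na(obs)) stop("observed heterozygote count infeasible for allele counts")
  sum(pr[pr <= obs * (1 + 1e-10)])
}

#' Genotype quality control
#'
#' Removes markers with minor allele frequency at or below `maf_min`, exact
#' Hardy-Weinberg p-value below `hwe_p_min`, or located on a sex chromosome.
#' Markers failing several rules are attributed to a single rule for the
#' report, in the priority order sex chromosome > MAF > HWE; the retained set
#' is independent of rule order.
#'
#' @param genotypes a [geno_matrix()] with chromosome labels and no missing
#'   values.
#' @param maf_min retain markers with MAF strictly greater than this
#'   (default 0.05).
#' @param hwe_p_min retain markers with exact HWE p-value at or above this
#'   (default 1e-25).
#' @param drop_sex_chromosomes remove markers on chromosomes labelled in
#'   `sex_chrom_labels`.
#' @param sex_chrom_labels chromosome labels treated as sex chromosomes.
#' @return list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (class `qc_report`: counts per rule and the retention percentage).
#' @export
apply_qc <- function(genotypes, maf_min = 0.05, hwe_p_min = 1e-25,
                     drop_sex_chromosomes = TRUE,
                     sex_chrom_labels = c("X", "Y", "XY", "MT")) {
  X <- genotypes$X
  m <- ncol(X)
  n <- nrow(X)
  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  n_het <- colSums(X == 1)
  n_aa <- colSums(X == 2)
  n_AA <- n - n_het - n_aa
  hwe_p <- vapply(seq_len(m),
                  function(k) hwe_exact_p(n_AA[k], n_het[k], n_aa[k]),
                  numeric(1))
  fail_sex <- drop_sex_chromosomes &
    genotypes$map$chrom %in% sex_chrom_labels
  fail_maf <- maf <= maf_min
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_sex | fail_maf | fail_hwe)
  if (!any(keep)) stop("QC removed every marker")
  report <- structure(list(
    n_markers_in = m,
    n_removed_sexchr = sum(fail_sex),
    n_removed_maf = sum(fail_maf & !fail_sex),
    n_removed_hwe = sum(fail_hwe & !fail_sex & !fail_maf),
    n_markers_out = sum(keep),
    retention_pct = retention_pct(sum(keep), m)
  ), class = "qc_report")
  list(genotypes = genotypes[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d markers in; removed %d (sex chr), %d (MAF), %d (HWE); %d out (%d%%)\n",
    x$n_markers_in, x$n_removed_sexchr, x$n_removed_maf, x$n_removed_hwe,
    x$n_markers_out, x$retention_pct))
  invisible(x)
}

#' Marker retention percentage
#'
#' Rounded percentage of markers kept by QC, as reported in
#' [apply_qc()]'s report.
#'
#' @param n_out,n_in markers retained / markers supplied.
#' @return `round(100 * n_out / n_in)`.
#' @export
retention_pct <- function(n_out, n_in) {
  if (n_in <= 0) stop("n_in must be positive")
  round(100 * n_out / n_in)
}

#' Pre-correct phenotypes for environmental effects
#'
#' Fits a mixed linear model with fixed birth-month (MB), herd-year (HYB),
#' parity (PD) and compartment (HC) effects and random pen and litter
#' effects by REML, and returns the conditional residuals (phenotype minus
#' fixed-effect fit minus pen and litter BLUPs) as the pre-corrected
#' phenotype.  Fixed factors with a single observed level are dropped with a
#' warning; variance components are constrained nonnegative by the solver.
#'
#' @param phenotypes data.frame with columns `y`, `pen`, `litter`, `MB`,
#'   `HYB`, `PD`, `HC`.
#' @return list of class `precorrection_fit`: `residuals` (the pre-corrected
#'   phenotype, in input order), `fixed_effects` (named coefficient vector),
#'   `pen_variance`, `litter_variance`, `residual_variance`, and `model`
#'   (the fitted lme4 object, or NULL for the degenerate fixed-only case).
#' @export
precorrect <- function(phenotypes) {
  need <- c("y", "pen", "litter", "MB", "HYB", "PD", "HC")
  if (!all(need %in% names(phenotypes)))
    stop("phenotype table must carry columns ", paste(need, collapse = ", "))
  df <- phenotypes
  for (v in c("pen", "litter", "MB", "HYB", "PD", "HC"))
    df[[v]] <- factor(df[[v]])
  fixed <- c("MB", "HYB", "PD", "HC")
  usable <- fixed[vapply(fixed, function(v) nlevels(df[[v]]) > 1, logical(1))]
  if (length(usable) < length(fixed))
    warning("dropping constant fixed factors: ",
            paste(setdiff(fixed, usable), collapse = ", "))
  rand <- c("pen", "litter")
  rand_usable <- rand[vapply(rand, function(v) nlevels(df[[v]]) > 1,
                             logical(1))]
  rhs <- c(if (length(usable)) usable else "1",
           sprintf("(1 | %s)", rand_usable))
  if (!length(rand_usable)) {
    # degenerate: ordinary least squares on the fixed part
    fml <- stats::reformulate(if (length(usable)) usable else "1",
                              response = "y")
    fit <- stats::lm(fml, data = df)
    return(structure(list(residuals = unname(stats::residuals(fit)),
                          fixed_effects = stats::coef(fit),
                          pen_variance = 0, litter_variance = 0,
                          residual_variance = stats::sigma(fit)^2,
                          model = NULL),
                     class = "precorrection_fit"))
  }
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- lme4::lmer(fml, data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  structure(list(
    residuals = unname(stats::residuals(fit)),
    fixed_effects = lme4::fixef(fit),
    pen_variance = getv("pen"),
    litter_variance = getv("litter"),
    residual_variance = getv("Residual"),
    model = fit
  ), class = "precorrection_fit")
}

#' Z-score normalization
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n-1
#' denominator).
#'
#' @param values numeric vector with at least two distinct values.
#' @return the normalized vector.
#' @export
znormalize <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("cannot z-normalize a constant vector")
  (values - mean(values)) / s
}
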