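#' Simulation configuration
#'
#' Parameters of the synthetic boar-like dataset generator.  Defaults emulate
#' the structure of a purebred boar testing population: two-digit thousands of
#' animals, a moderately heritable trait (narrow-sense heritability around
#' 0.25, a small dominance fraction, essentially no additive-by-additive
#' epistasis), pen/litter/birth-month environmental structure and a
#' birth-year-based holdout of the youngest animals.
#'
#' @param n_individuals number of animals.
#' @param n_markers number of SNP markers.
#' @param maf_range length-2 vector; reference-allele frequencies are drawn
#'   uniformly from this interval (must lie inside (0, 0.5]).
#' @param ld_decay probability in \[0, 1) that a haplotype allele is copied
#'   from the adjacent previous marker (first-order Markov linkage
#'   disequilibrium); 0 gives independent markers.
#' @param target_h2,target_d2,target_e2 target variance fractions of the
#'   additive, dominance and additive-by-additive epistatic components
#'   relative to total phenotypic variance.  Their sum must be < 1.
#' @param n_pens,n_litters number of pen and litter groups.
#' @param pen_var,litter_var variances of the pen and litter random effects.
#' @param n_birth_years number of birth-year cohorts, assigned uniformly.
#' @param test_years which birth years (counted from the first) form the
#'   holdout test set; defaults to the last two cohorts, mirroring a design
#'   where the youngest animals are predicted.
#' @param n_epi_pairs number of marker pairs carrying epistatic effects.
#' @param seed integer seed; fixes every downstream array.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000, n_markers = 1000,
                       maf_range = c(0.05, 0.5), ld_decay = 0.5,
                       target_h2 = 0.25, target_d2 = 0.02, target_e2 = 0,
                       n_pens = 150, n_litters = 400,
                       pen_var = 0.10, litter_var = 0.15,
                       n_birth_years = 6,
                       test_years = NULL,
                       n_epi_pairs = max(5L, round(n_markers / 10)),
                       seed = 1L) {
  if (is.null(test_years)) test_years <- c(n_birth_years - 1L, n_birth_years)
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_markers = as.integer(n_markers),
              maf_range = maf_range, ld_decay = ld_decay,
              target_h2 = target_h2, target_d2 = target_d2,
              target_e2 = target_e2,
              n_pens = as.integer(n_pens), n_litters = as.integer(n_litters),
              pen_var = pen_var, litter_var = litter_var,
              n_birth_years = as.integer(n_birth_years),
              test_years = as.integer(test_years),
              n_epi_pairs = as.integer(n_epi_pairs),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_individuals < 1 || n_markers < 1 || n_pens < 1 || n_litters < 1 ||
        n_birth_years < 1)
      stop("all counts must be positive")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("maf_range must lie within (0, 0.5]")
    if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must be in [0, 1)")
    if (min(target_h2, target_d2, target_e2) < 0)
      stop("target variance fractions must be nonnegative")
    if (target_h2 + target_d2 + target_e2 >= 1)
      stop("target_h2 + target_d2 + target_e2 must be < 1")
  })
  invisible(cfg)
}

#' Simulate SNP genotypes with first-order Markov linkage disequilibrium
#'
#' Each individual carries two haplotypes.  Along a haplotype the allele at
#' marker k is copied from marker k-1 with probability `ld_decay`, otherwise
#' drawn fresh as Bernoulli(p_k) with p_k uniform on `maf_range`.  Dosage is
#' the sum of the two haplotype alleles, giving 0/1/2 codes in
#' Hardy-Weinberg proportions when `ld_decay = 0`.  Markers are spread evenly
#' over 18 autosomes.
#'
#' @param config a [sim_config()].
#' @return a [geno_matrix()] whose `samples` table carries `id`, `birth_year`,
#'   `pen`, `litter` and the fixed-factor columns used by the phenotype
#'   generator.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_markers
  p <- runif(m, config$maf_range[1], config$maf_range[2])

  sim_hap <- function() {
    H <- matrix(0L, n, m)
    H[, 1] <- rbinom(n, 1, p[1])
    if (m > 1) {
      fresh <- matrix(rbinom(n * (m - 1), 1, rep(p[-1], each = n)), n)
      copy <- matrix(runif(n * (m - 1)) < config$ld_decay, n)
      for (k in 2:m) {
        H[, k] <- ifelse(copy[, k - 1], H[, k - 1], fresh[, k - 1])
      }
    }
    H
  }
  X <- sim_hap() + sim_hap()

  chrom <- as.character(rep_len(rep(1:18, each = ceiling(m / 18)), m))
  samples <- data.frame(
    id = sprintf("ind%04d", seq_len(n)),
    birth_year = sample.int(config$n_birth_years, n, replace = TRUE),
    pen = sample.int(config$n_pens, n, replace = TRUE),
    litter = sample.int(config$n_litters, n, replace = TRUE),
    MB = sample.int(12, n, replace = TRUE),
    HYB = sample.int(8, n, replace = TRUE),
    PD = sample.int(5, n, replace = TRUE),
    HC = sample.int(4, n, replace = TRUE)
  )
  rownames(X) <- samples$id
  geno_matrix(X, chrom = chrom, samples = samples)
}

# Project v onto the orthogonal complement of the columns of B (which are
# assumed mutually orthogonal and centered), then rescale to standard
# deviation `sd_target`.  Zero-variance targets return the zero vector.
orthoscale <- function(v, B, sd_target) {
  v <- v - mean(v)
  if (sd_target <= 1e-10) return(rep(0, length(v)))
  if (length(B)) {
    for (j in seq_along(B)) {
      b <- B[[j]]
      ss <- sum(b * b)
      if (ss > 0) v <- v - b * (sum(v * b) / ss)
    }
  }
  s <- stats::sd(v)
  if (s < 1e-12) stop("degenerate component: zero empirical variance")
  v * (sd_target / s)
}

#' Simulate phenotypes with known additive, dominance and epistatic variance
#'
#' The phenotype is built as additive value (dosage times additive effects)
#' + dominance value (heterozygosity indicator times dominance effects)
#' + epistatic value (sum over marker pairs of centered-dosage products)
#' + pen + litter + fixed environmental factors (birth month MB, herd-year
#' HYB, parity PD, compartment HC) + residual.  Components are empirically
#' centered, sequentially orthogonalized and rescaled so the realized
#' variance fractions equal the targets exactly and the component variances
#' sum to the phenotypic variance.
#'
#' @param genotypes a [geno_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return a list with `phenotypes` (data.frame: id, y, birth_year, pen,
#'   litter, MB, HYB, PD, HC) and `truth` (class `truth_set`): per-marker
#'   effects, epistatic pairs, realized fractions, and the component vectors.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  X <- genotypes$X
  n <- nrow(X); m <- ncol(X)
  s <- genotypes$samples

  total_env_var <- config$pen_var + config$litter_var + 0.04
  g <- config$target_h2 + config$target_d2 + config$target_e2
  # total phenotypic variance: large enough that the residual fraction
  # (1 - g) can absorb the environmental variance
  sigma_p2 <- max(total_env_var + 1, 1.05 * total_env_var / (1 - g))

  fixed_eff <- list(MB = stats::rnorm(12, 0, 0.1),
                    HYB = stats::rnorm(8, 0, 0.1),
                    PD = stats::rnorm(5, 0, 0.1),
                    HC = stats::rnorm(4, 0, 0.1))
  fixedv <- fixed_eff$MB[s$MB] + fixed_eff$HYB[s$HYB] +
    fixed_eff$PD[s$PD] + fixed_eff$HC[s$HC]
  penv <- stats::rnorm(config$n_pens, 0, sqrt(config$pen_var))[s$pen]
  litv <- stats::rnorm(config$n_litters, 0, sqrt(config$litter_var))[s$litter]

  a_eff <- stats::rnorm(m) / sqrt(m)
  # dominance effect variance scales with 1/(2 p^2 q^2) so the dominance
  # covariance is proportional to the heterozygosity-based dominance
  # relationship matrix (standardized-effect convention)
  p_hat <- pmin(pmax(colMeans(X) / 2, 1e-3), 1 - 1e-3)
  d_eff <- stats::rnorm(m) / (sqrt(2) * p_hat * (1 - p_hat)) / sqrt(m)
  H <- (X == 1) * 1
  raw_add <- drop(X %*% a_eff)
  raw_dom <- drop(H %*% d_eff)

  n_pairs <- min(config$n_epi_pairs, m * (m - 1) / 2)
  pair_idx <- cbind(sample.int(m, n_pairs, replace = TRUE),
                    sample.int(m, n_pairs, replace = TRUE))
  bad <- pair_idx[, 1] == pair_idx[, 2]
  pair_idx[bad, 2] <- (pair_idx[bad, 1] %% m) + 1L
  pair_eff <- stats::rnorm(n_pairs) / sqrt(n_pairs)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  raw_epi <- drop((Xc[, pair_idx[, 1], drop = FALSE] *
                     Xc[, pair_idx[, 2], drop = FALSE]) %*% pair_eff)
  resid_raw <- stats::rnorm(n)

  # sequential orthogonalization keeps component variances exactly additive
  env_sd <- function(v) stats::sd(v)
  fixedv <- fixedv - mean(fixedv)
  basis <- list(fixedv)
  penv <- orthoscale(penv, basis, env_sd(penv)); basis <- c(basis, list(penv))
  litv <- orthoscale(litv, basis, env_sd(litv)); basis <- c(basis, list(litv))
  add <- orthoscale(raw_add, basis, sqrt(config$target_h2 * sigma_p2))
  basis <- c(basis, list(add))
  dom <- orthoscale(raw_dom, basis, sqrt(config$target_d2 * sigma_p2))
  basis <- c(basis, list(dom))
  epi <- orthoscale(raw_epi, basis, sqrt(config$target_e2 * sigma_p2))
  basis <- c(basis, list(epi))
  env <- fixedv + penv + litv
  resid_var <- sigma_p2 * (1 - g) - stats::var(env)
  if (resid_var <= 0) stop("environmental variance exceeds the residual budget")
  resid <- orthoscale(resid_raw, basis, sqrt(resid_var))

  y <- add + dom + epi + env + resid
  vp <- stats::var(y)

  # scale per-marker effects consistently with the realized components
  sc_a <- if (stats::sd(raw_add) > 0 && config$target_h2 > 0)
    sqrt(config$target_h2 * sigma_p2) / stats::sd(raw_add - mean(raw_add)) else 0
  sc_d <- if (stats::sd(raw_dom) > 0 && config$target_d2 > 0)
    sqrt(config$target_d2 * sigma_p2) / stats::sd(raw_dom - mean(raw_dom)) else 0
  sc_e <- if (stats::sd(raw_epi) > 0 && config$target_e2 > 0)
    sqrt(config$target_e2 * sigma_p2) / stats::sd(raw_epi - mean(raw_epi)) else 0

  truth <- structure(list(
    additive_effects = a_eff * sc_a,
    dominance_effects = d_eff * sc_d,
    epistatic_pairs = data.frame(i = pair_idx[, 1], j = pair_idx[, 2],
                                 effect = pair_eff * sc_e),
    genetic_values = data.frame(additive = add, dominance = dom,
                                epistatic = epi),
    env_values = data.frame(fixed = fixedv, pen = penv, litter = litv),
    residuals = resid,
    realized_h2 = stats::var(add) / vp,
    realized_d2 = stats::var(dom) / vp,
    realized_e2 = stats::var(epi) / vp,
    sigma_p2 = vp
  ), class = "truth_set")

  phen <- data.frame(id = s$id, y = y, birth_year = s$birth_year,
                     pen = s$pen, litter = s$litter,
                     MB = s$MB, HYB = s$HYB, PD = s$PD, HC = s$HC)
  list(phenotypes = phen, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Genotypes are written either as a PLINK additive-recode text table
#' (".raw" dialect: FID IID PAT MAT SEX PHENOTYPE then one dosage column per
#' marker, names suffixed `_A`) or as a plain CSV (id column + one column per
#' marker); the phenotype/factor table is always a CSV.  Both round-trip
#' losslessly through [read_plink_raw()] / [read_genotype_csv()].
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes phenotype data.frame (or NULL to skip).
#' @param path output prefix; files `<path>.raw` or `<path>_geno.csv`,
#'   `<path>_pheno.csv` and `<path>_map.csv` are created.
#' @param format `"plink_raw"` or `"csv"`.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(genotypes, phenotypes = NULL, path,
                          format = c("plink_raw", "csv")) {
  format <- match.arg(format)
  paths <- character(0)
  if (format == "plink_raw") {
    f <- paste0(path, ".raw")
    hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
             paste0(colnames(genotypes$X), "_A"))
    df <- data.frame(FID = genotypes$samples$id, IID = genotypes$samples$id,
                     PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9)
    df <- cbind(df, as.data.frame(genotypes$X))
    names(df) <- hdr
    utils::write.table(df, f, quote = FALSE, row.names = FALSE, sep = " ")
    paths <- c(paths, f)
  } else {
    f <- paste0(path, "_geno.csv")
    df <- data.frame(id = genotypes$samples$id, genotypes$X,
                     check.names = FALSE)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  fm <- paste0(path, "_map.csv")
  utils::write.csv(genotypes$map, fm, row.names = FALSE, quote = FALSE)
  paths <- c(paths, fm)
  if (!is.null(phenotypes)) {
    fp <- paste0(path, "_pheno.csv")
    utils::write.csv(phenotypes, fp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, fp)
  }
  invisible(paths)
}
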