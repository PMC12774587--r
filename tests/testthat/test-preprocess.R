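test_that("HWE exact test matches direct enumeration", {
  # oracle: enumerate the conditional heterozygote-count distribution and
  # sum probabilities no larger than the observed one
  oracle_p <- function(nAA, nAb, nbb) {
    n <- nAA + nAb + nbb
    n_rare <- min(2 * nAA + nAb, 2 * nbb + nAb)
    if (n_rare == 0) return(1)
    d <- hwe_het_distribution(n, n_rare)
    obs <- d$p[d$het == nAb]
    sum(d$p[d$p <= obs * (1 + 1e-10)])
  }
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(100, 0, 0), c(3, 5, 2),
                c(10, 1, 10), c(0, 7, 13), c(40, 20, 40))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle_p(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10,
                 info = paste(cs, collapse = ","))
  }
  # modal heterozygote count: p-value includes most of the mass
  expect_gte(hwe_exact_p(25, 50, 25), 0.5)
  # extreme disequilibrium at n = 100 is far below the QC threshold
  expect_lt(hwe_exact_p(50, 0, 50), 1e-25)
  # monomorphic marker: only one configuration exists
  expect_identical(hwe_exact_p(100, 0, 0), 1)
  expect_error(hwe_exact_p(0, 0, 0), "zero")
  expect_error(hwe_exact_p(-1, 2, 3), "nonnegative")
})

test_that("QC applies MAF, HWE and sex-chromosome rules with consistent counts", {
  # 4 markers with sample MAFs {0, 0.04, 0.06, 0.5}: the first is
  # monomorphic, the second fails MAF <= 0.05, markers 3 and 4 survive
  n <- 50
  X <- cbind(rep(0, n),
             c(rep(1, 4), rep(0, n - 4)),
             c(rep(1, 6), rep(0, n - 6)),
             c(rep(0, 12), rep(1, 26), rep(2, 12)))
  colnames(X) <- paste0("m", 1:4)
  g <- geno_matrix(X, chrom = rep("1", 4))
  res <- apply_qc(g)
  expect_identical(colnames(res$genotypes$X), c("m3", "m4"))
  rep <- res$report
  expect_identical(rep$n_markers_in, 4L)
  expect_identical(rep$n_markers_out, 2L)
  expect_identical(rep$n_markers_out,
                   rep$n_markers_in - rep$n_removed_maf -
                     rep$n_removed_hwe - rep$n_removed_sexchr)
  expect_identical(rep$retention_pct, 50)

  # sex-chromosome markers are removed regardless of frequencies
  g2 <- geno_matrix(X, chrom = c("1", "1", "X", "1"))
  res2 <- apply_qc(g2)
  expect_identical(colnames(res2$genotypes$X), "m4")
  expect_identical(res2$report$n_removed_sexchr, 1L)

  # HWE rule: perfect heterozygote excess at decent n
  X3 <- cbind(rep(1, 200), c(rep(0, 50), rep(1, 100), rep(2, 50)))
  g3 <- geno_matrix(X3, chrom = c("2", "2"))
  res3 <- apply_qc(g3)
  expect_identical(res3$report$n_removed_hwe, 1L)
  expect_identical(ncol(res3$genotypes$X), 1L)

  expect_error(apply_qc(geno_matrix(X[, 1, drop = FALSE], chrom = "1")),
               "every marker")
})

test_that("QC retained set is order-independent across rules", {
  d <- small_dataset(n = 200, m = 60, seed = 31)
  g <- d$geno
  g$map$chrom[1:5] <- "X"
  full <- apply_qc(g)
  # apply rules one at a time in a different order
  s1 <- apply_qc(g, maf_min = 0, hwe_p_min = 0)          # sex only
  s2 <- apply_qc(s1$genotypes, hwe_p_min = 0)            # then MAF
  s3 <- apply_qc(s2$genotypes, maf_min = 0)              # then HWE
  expect_identical(colnames(s3$genotypes$X), colnames(full$genotypes$X))
})

test_that("retention percentages follow the rounded-ratio definition", {
  expect_identical(retention_pct(36313, 49478), 73)
  expect_identical(retention_pct(35977, 48617), 74)
  expect_identical(retention_pct(1, 3), 33)
})

test_that("pre-correction reduces to centering in the degenerate design", {
  n <- 40
  ph <- data.frame(y = rnorm(n), pen = 1, litter = 1, MB = 1, HYB = 1,
                   PD = 1, HC = 1)
  fit <- suppressWarnings(precorrect(ph))
  expect_equal(fit$residuals, ph$y - mean(ph$y), tolerance = 1e-10)
  expect_identical(fit$pen_variance, 0)
  expect_identical(fit$litter_variance, 0)
})

test_that("pre-correction recovers pen and litter variances and the residuals behave", {
  cfg <- sim_config(n_individuals = 2000, n_markers = 20, target_h2 = 0,
                    target_d2 = 0, target_e2 = 0, pen_var = 0.3,
                    litter_var = 0.2, n_pens = 120, n_litters = 250,
                    seed = 41)
  g <- simulate_genotypes(cfg)
  s <- simulate_phenotypes(g, cfg)
  fit <- precorrect(s$phenotypes)
  # REML variance estimates near truth (loose bands ~2 SE at this size)
  expect_lt(abs(fit$pen_variance - 0.3), 0.08)
  expect_lt(abs(fit$litter_variance - 0.2), 0.06)
  # residual mean zero and orthogonality to every fixed-effect column
  expect_lt(abs(mean(fit$residuals)), 1e-8)
  mm <- model.matrix(~ factor(MB) + factor(HYB) + factor(PD) + factor(HC),
                     data = s$phenotypes)
  expect_lt(max(abs(crossprod(mm, fit$residuals))), 1e-6)
})

test_that("pre-corrected values track the genetic signal better than raw phenotypes", {
  cfg <- sim_config(n_individuals = 1500, n_markers = 150, target_h2 = 0.3,
                    target_d2 = 0, target_e2 = 0, pen_var = 0.5,
                    litter_var = 0.4, n_pens = 80, n_litters = 200,
                    seed = 43)
  g <- simulate_genotypes(cfg)
  s <- simulate_phenotypes(g, cfg)
  fit <- precorrect(s$phenotypes)
  gv <- s$truth$genetic_values$additive
  expect_gt(cor(fit$residuals, gv), cor(s$phenotypes$y, gv))
})

test_that("z-normalization has exact moments and is idempotent", {
  expect_equal(znormalize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(100, 5, 3)
  z <- znormalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(znormalize(z), z, tolerance = 1e-12)
  expect_error(znormalize(rep(2, 5)), "constant")
})
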