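test_that("reported REML log-likelihood matches a direct dense evaluation and is a local optimum", {
  d <- small_dataset(n = 300, m = 400, h2 = 0.3, d2 = 0, e2 = 0,
                     pen_var = 0, litter_var = 0, seed = 51)
  y <- znormalize(d$phen$y)
  G <- build_G(d$geno)
  fit <- fit_reml(y, list(G), "A")
  expect_true(fit$converged)
  ll_direct <- reml_loglik(y, list(G), fit$components)
  expect_equal(fit$loglik, ll_direct, tolerance = 1e-6)
  # +/-10% perturbations of the solution do not increase the likelihood
  for (i in 1:2) for (f in c(0.9, 1.1)) {
    sig <- fit$components
    sig[i] <- sig[i] * f
    expect_lte(reml_loglik(y, list(G), sig), fit$loglik + 1e-8)
  }
})

test_that("additive heritability is recovered within 2 SE on a moderate simulation", {
  d <- small_dataset(n = 800, m = 1000, h2 = 0.25, d2 = 0, e2 = 0,
                     pen_var = 0, litter_var = 0, seed = 53)
  y <- znormalize(d$phen$y)
  fit <- fit_reml(y, list(build_G(d$geno)), "A")
  r <- ratios(fit)
  expect_lt(abs(r$ratios["h2"] - 0.25), 2 * r$se["h2"])
  expect_equal(r$sigma2_p, sum(fit$components), tolerance = 1e-10)
})

test_that("a pure-noise trait drives the genetic component to the floor", {
  d <- small_dataset(n = 400, m = 300, h2 = 0, d2 = 0, e2 = 0,
                     pen_var = 0, litter_var = 0, seed = 57)
  y <- znormalize(d$phen$y)
  G <- build_G(d$geno)
  fit <- fit_reml(y, list(G), "A")
  # estimate collapses toward zero (sampling spread is ~0.05 here)
  expect_lt(fit$components["a"], 0.1)
  # the likelihood surface is flat at zero: clamping the genetic component
  # to the floor matches the intercept-only optimum almost exactly
  ll0 <- reml_loglik(y, list(), sigma = var(y))
  ll_floor <- reml_loglik(y, list(G), c(fit$floor, var(y)))
  expect_lt(abs(ll_floor - ll0), 1e-3)
  expect_gte(fit$loglik, ll0 - 1e-3)
})

test_that("epistatic component at the floor leaves the additive estimate unchanged", {
  d <- small_dataset(n = 500, m = 600, h2 = 0.3, d2 = 0, e2 = 0,
                     pen_var = 0, litter_var = 0, seed = 59)
  y <- znormalize(d$phen$y)
  G <- build_G(d$geno)
  E <- build_Eaa(G)
  fA <- fit_reml(y, list(G), "A")
  fAE <- fit_reml(y, list(G, E), "AE")
  hA <- ratios(fA)$ratios["h2"]
  hAE <- ratios(fAE)$ratios["h2"]
  expect_lt(abs(hA - hAE), 0.005)
})

test_that("model tags validate their relationship matrices", {
  d <- small_dataset(n = 50, m = 60, seed = 61)
  y <- znormalize(d$phen$y)
  G <- build_G(d$geno)
  D <- build_D(d$geno, normalize = TRUE)
  expect_error(fit_reml(y, list(G, D), "A"), "needs 1")
  expect_error(fit_reml(y, list(D, G), "AD"), "expects matrices of kind")
  fit <- fit_reml(y, list(G, D), "AD")
  expect_named(fit$components, c("a", "d", "eps"))
})

test_that("variance ratios reproduce published-style arithmetic", {
  # dam-line additive-dominance fit: h2 + d2 = H2
  vc <- variance_components(c(a = 0.266, d = 0.023, eps = 0.737), model_tag = "AD")
  r <- ratios(vc)
  expect_equal(round(unname(r$ratios["h2"] + r$ratios["d2"]), 3),
               round(unname(r$ratios["H2"]), 3))
  expect_equal(unname(round(r$ratios["H2"], 3)), 0.282)
  # dominance share of the total genetic variance, nearest percent
  share_genetic <- 100 * 0.023 / (0.266 + 0.023)
  expect_equal(round(share_genetic), 8)
  # dominance as a percentage of phenotypic variance
  expect_equal(round(100 * unname(r$ratios["d2"]), 2), 2.24)
  expect_error(ratios(variance_components(c(a = 0, eps = 0))), "zero")
})

test_that("ratio standard errors follow the delta method on the AI covariance", {
  d <- small_dataset(n = 300, m = 300, h2 = 0.3, d2 = 0, e2 = 0,
                     pen_var = 0, litter_var = 0, seed = 63)
  y <- znormalize(d$phen$y)
  fit <- fit_reml(y, list(build_G(d$geno)), "A")
  r <- ratios(fit)
  sp <- sum(fit$components)
  g <- c((sp - fit$components["a"]) / sp^2, -fit$components["a"] / sp^2)
  manual <- sqrt(drop(t(g) %*% fit$ai_inv %*% g))
  expect_equal(unname(r$se["h2"]), manual, tolerance = 1e-10)
})

test_that("BLUP predictions follow the closed form in the single-animal case", {
  # one training animal, G = I on {train, test} except g between them
  g <- 0.6; s2a <- 0.4; s2e <- 0.6
  K <- rbind(c(1, g), c(g, 1))
  fit <- variance_components(c(a = s2a, eps = s2e), model_tag = "A")
  y_tr <- 1.3
  pr <- predict_genetic_values(fit, list(K), y_tr, train_idx = 1,
                               test_idx = 2)
  # GLS intercept with one record equals the record itself, so shrinkage
  # leaves zero signal; instead check against two training animals
  K3 <- diag(3); K3[1, 3] <- K3[3, 1] <- g
  y2 <- c(1.0, -1.0)
  pr2 <- predict_genetic_values(fit, list(K3), y2, train_idx = 1:2,
                                test_idx = 3)
  mu <- 0  # symmetric records, equal weights
  expect_equal(pr2$ebv, g * s2a / (s2a + s2e) * (y2[1] - mu),
               tolerance = 1e-10)
  expect_equal(pr$ebv, 0, tolerance = 1e-10)  # y - mu is zero with n=1
})

test_that("vanishing additive variance shrinks every prediction to zero", {
  d <- small_dataset(n = 80, m = 100, seed = 67)
  y <- znormalize(d$phen$y)
  G <- build_G(d$geno)
  fit <- variance_components(c(a = 1e-12, eps = 1), model_tag = "A")
  pr <- predict_genetic_values(fit, list(G), y[1:60], 1:60, 61:80)
  expect_lt(max(abs(pr$ebv)), 1e-9)
})

test_that("BLUP agrees with a Henderson mixed-model-equation solve", {
  d <- small_dataset(n = 150, m = 500, h2 = 0.3, d2 = 0, e2 = 0,
                     pen_var = 0, litter_var = 0, seed = 71)
  y <- znormalize(d$phen$y)
  G <- build_G(d$geno)$values
  tr <- 1:110; te <- 111:150
  s2a <- 0.3; s2e <- 0.7
  fit <- variance_components(c(a = s2a, eps = s2e), model_tag = "A")
  pr <- predict_genetic_values(fit, list(G), y[tr], tr, te)
  # MME: [X'X  X'Z; Z'X  Z'Z + G^{-1} s2e/s2a] [b; u] = [X'y; Z'y]
  n <- length(y)
  Z <- matrix(0, length(tr), n); Z[cbind(seq_along(tr), tr)] <- 1
  Xd <- matrix(1, length(tr), 1)
  Ginv <- solve(G + diag(1e-8, n))
  C <- rbind(cbind(crossprod(Xd), crossprod(Xd, Z)),
             cbind(crossprod(Z, Xd), crossprod(Z) + Ginv * s2e / s2a))
  rhs <- rbind(crossprod(Xd, y[tr]), crossprod(Z, y[tr]))
  sol <- solve(C, rhs)
  u_hat <- sol[-1][te]
  expect_equal(unname(pr$ebv), unname(u_hat), tolerance = 1e-6)
})

test_that("prediction beats the mean baseline and approaches the direct-solve accuracy", {
  d <- small_dataset(n = 700, m = 700, h2 = 0.35, d2 = 0, e2 = 0,
                     pen_var = 0, litter_var = 0, seed = 73)
  y <- znormalize(d$phen$y)
  G <- build_G(d$geno)
  tr <- 1:550; te <- 551:700
  fit <- fit_reml(y[tr], list(rel_matrix(G$values[tr, tr], "additive")), "A")
  pr <- predict_genetic_values(fit, list(G), y[tr], tr, te)
  truth <- d$truth$genetic_values$additive[te]
  expect_gt(cor(pr$ebv, truth), 0.2)  # mean baseline has correlation 0
})
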