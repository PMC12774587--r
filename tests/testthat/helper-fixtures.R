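# Shared small fixtures, built in code at test time.

# a small simulated dataset reused by several files
small_dataset <- function(n = 400, m = 200, h2 = 0.25, d2 = 0.02, e2 = 0,
                          pen_var = 0.1, litter_var = 0.15, seed = 11,
                          ld = 0.5) {
  cfg <- sim_config(n_individuals = n, n_markers = m, target_h2 = h2,
                    target_d2 = d2, target_e2 = e2, pen_var = pen_var,
                    litter_var = litter_var, ld_decay = ld, seed = seed)
  g <- simulate_genotypes(cfg)
  s <- simulate_phenotypes(g, cfg)
  list(config = cfg, geno = g, phen = s$phenotypes, truth = s$truth)
}

# brute-force two-loop evaluation of the additive relationship formula
bruteforce_G <- function(X, p) {
  n <- nrow(X); m <- ncol(X)
  denom <- sum(2 * p * (1 - p))
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (k in 1:m) s <- s + (X[i, k] - 2 * p[k]) * (X[j, k] - 2 * p[k])
    G[i, j] <- s / denom
  }
  G
}

# brute-force two-loop evaluation of the dominance relationship formula
bruteforce_D <- function(X, p) {
  n <- nrow(X); m <- ncol(X)
  q <- 1 - p
  Z <- (X == 1) * 1
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (k in 1:m)
      s <- s + (Z[i, k] - 2 * p[k] * q[k]) * (Z[j, k] - 2 * p[k] * q[k]) /
        (2 * p[k]^2 * q[k]^2)
    D[i, j] <- s / m
  }
  D
}

# exact conditional distribution of the heterozygote count given allele
# counts, by direct enumeration of genotype configurations (independent of
# the package's log-space implementation)
hwe_het_distribution <- function(n, n_rare) {
  het <- seq(n_rare %% 2, n_rare, by = 2)
  pr <- vapply(het, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    exp(lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
          h * log(2))
  }, numeric(1))
  data.frame(het = het, p = pr / sum(pr))
}
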