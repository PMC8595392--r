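test_that("forward-backward equals brute-force path enumeration", {
  set.seed(23)
  for (cfg in list(c(K = 2, m = 3, n = 2), c(K = 3, m = 4, n = 2),
                   c(K = 2, m = 5, n = 3), c(K = 3, m = 5, n = 1))) {
    K <- cfg["K"]; m <- cfg["m"]; n <- cfg["n"]
    pi <- matrix(runif(K * m, 0.05, 0.95), K, m)
    rho <- 0.1
    tot <- matrix(rpois(n * m, 2), n, m)
    alt <- matrix(rbinom(n * m, as.vector(tot), 0.4), n, m)
    lik <- lik_from_counts(tot - alt, alt, error_rate = 0.05)
    bf <- brute_force_posteriors(lik, pi, rho)
    L0 <- matrix(lik[, , 1], n, m); L1 <- matrix(lik[, , 2], n, m)
    L2 <- matrix(lik[, , 3], n, m)
    T1 <- lcgblup:::hap_transition(K, rho)
    fb <- lcgblup:::forward_backward_all(L0, L1, L2, pi, T1 %x% T1)
    expect_equal(fb$gamma, bf$gamma, tolerance = 1e-10)
    ## and the assembled genotype posteriors agree too
    model <- structure(list(pi = pi, K = K, rho = rho), class = "founder_hmm")
    post <- impute_posteriors(model, lik)
    expect_equal(post$prob, bf$gpost, tolerance = 1e-10)
  }
})

test_that("single-site pair-state posterior matches hand enumeration", {
  ## K = 2, hand-set pi, one alternate read
  pi <- matrix(c(0.1, 0.9), 2, 1)
  eps <- 0.01
  lik <- lik_from_counts(matrix(0L, 1, 1), matrix(1L, 1, 1), error_rate = eps)
  model <- structure(list(pi = pi, K = 2, rho = 0), class = "founder_hmm")
  post <- impute_posteriors(model, lik)
  ## enumerate the 4 ordered pair states by hand
  pg_read <- c(eps, 0.5, 1 - eps)   # P(read = alt | g)
  states <- expand.grid(k1 = 1:2, k2 = 1:2)
  joint <- numeric(3)
  for (s in 1:4) {
    p1 <- pi[states$k1[s], 1]; p2 <- pi[states$k2[s], 1]
    pg <- c((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)
    joint <- joint + 0.25 * pg * pg_read
  }
  expect_equal(as.vector(post$prob[1, 1, ]), joint / sum(joint),
               tolerance = 1e-12)
})

test_that("zero-read individual gets the model-implied marginal dosage", {
  set.seed(29)
  K <- 3; m <- 4
  pi <- matrix(runif(K * m, 0.1, 0.9), K, m)
  lik <- lik_from_counts(matrix(0L, 1, m), matrix(0L, 1, m), error_rate = 0.01)
  model <- structure(list(pi = pi, K = K, rho = 0.05), class = "founder_hmm")
  post <- impute_posteriors(model, lik)
  ## oracle: exhaustive summation over all K^2 states under the uniform
  ## stationary distribution
  for (j in 1:m) {
    dos <- 0
    for (k1 in 1:K) for (k2 in 1:K)
      dos <- dos + (pi[k1, j] + pi[k2, j]) / K^2
    expect_equal(post$dosage[1, j], dos, tolerance = 1e-10)
    expect_equal(post$dosage[1, j], 2 * mean(pi[, j]), tolerance = 1e-10)
  }
})

test_that("EM log-likelihood is non-decreasing", {
  sim <- simulate_population(K = 4, n_sites = 100, n_ind = 100,
                             switch_rate = 0.02, seed = 33)
  reads <- simulate_reads(sim$truth, mean_depth = 1, error_rate = 0.01, seed = 34)
  lik <- genotype_likelihoods(reads)
  hmm <- fit_haplotype_hmm(lik, K = 4, rho = 0.02, n_iter = 30, seed = 35)
  expect_gte(min(diff(hmm$loglik)), -1e-8)
})

test_that("fitted founders recover a K=2 panel at high depth", {
  sim <- simulate_population(K = 2, n_sites = 100, n_ind = 100,
                             switch_rate = 0, seed = 37)
  reads <- simulate_reads(sim$truth, mean_depth = 30, error_rate = 0.01, seed = 38)
  lik <- genotype_likelihoods(reads)
  hmm <- fit_haplotype_hmm(lik, K = 2, rho = 0.001, n_iter = 40, seed = 39)
  truth <- sim$panel$haplotypes
  mae <- function(a, b) mean(abs(a - b))
  direct <- (mae(hmm$pi[1, ], truth[1, ]) + mae(hmm$pi[2, ], truth[2, ])) / 2
  swapped <- (mae(hmm$pi[1, ], truth[2, ]) + mae(hmm$pi[2, ], truth[1, ])) / 2
  expect_lt(min(direct, swapped), 0.05)
})

test_that("high-depth imputation reproduces the truth almost exactly", {
  sim <- simulate_population(K = 4, n_sites = 100, n_ind = 80, seed = 41)
  reads <- simulate_reads(sim$truth, mean_depth = 30, error_rate = 0.001, seed = 42)
  lik <- genotype_likelihoods(reads)
  hmm <- fit_haplotype_hmm(lik, K = 4, rho = 0.002, n_iter = 25, seed = 43)
  post <- impute_posteriors(hmm, lik)
  expect_gt(genotypic_concordance(post$hard, sim$truth$genotypes), 0.999)
})

test_that("posteriors normalize and dosages stay in range on random input", {
  set.seed(47)
  n <- 20; m <- 15; K <- 3
  tot <- matrix(rpois(n * m, 1.5), n, m)
  alt <- matrix(rbinom(n * m, as.vector(tot), 0.5), n, m)
  lik <- lik_from_counts(tot - alt, alt, error_rate = 0.02)
  hmm <- fit_haplotype_hmm(lik, K = K, rho = 0.05, n_iter = 10, seed = 48)
  post <- impute_posteriors(hmm, lik)
  sums <- post$prob[, , 1] + post$prob[, , 2] + post$prob[, , 3]
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-8)
  expect_true(all(post$dosage >= 0 & post$dosage <= 2))
  flat <- matrix(post$prob, n * m, 3)
  expect_true(all(flat[cbind(seq_len(n * m), as.vector(post$hard) + 1L)] >=
                  apply(flat, 1, max) - 1e-12))
})

test_that("model/likelihood shape mismatch is caught", {
  lik <- lik_from_counts(matrix(0L, 2, 4), matrix(0L, 2, 4))
  model <- structure(list(pi = matrix(0.5, 2, 3), K = 2, rho = 0.01),
                     class = "founder_hmm")
  expect_error(impute_posteriors(model, lik), "site-count mismatch")
  expect_error(fit_haplotype_hmm(lik, K = 1), "K")
})

test_that("HMM imputation beats the LD-free baseline at the working point", {
  ## paired comparison on the headline configuration over 5 seeds
  runs <- lapply(1:5, headline_run)
  hmm_r2 <- vapply(runs, `[[`, 0, "hmm_r2")
  base_r2 <- vapply(runs, `[[`, 0, "base_r2")
  expect_true(all(hmm_r2 > base_r2))
})

test_that("dosage accuracy is non-decreasing in sequencing depth", {
  ## reduced same-shape configuration; 3 seeds x 4 depths
  depths <- c(0.5, 1, 2, 20)
  means <- sapply(1:3, function(s) {
    sim <- simulate_population(K = 4, n_sites = 120, n_ind = 150,
                               switch_rate = 0.002, seed = child_seed(s, 81))
    full <- simulate_reads(sim$truth, mean_depth = 20, error_rate = 0.01,
                           seed = child_seed(s, 82))
    vapply(depths, function(d) {
      reads <- if (d < 20) downsample_reads(full, d, seed = child_seed(s, 83))
               else full
      lik <- genotype_likelihoods(reads)
      hmm <- fit_haplotype_hmm(lik, K = 4, rho = 0.002, n_iter = 30,
                               seed = child_seed(s, 84))
      post <- impute_posteriors(hmm, lik)
      as.numeric(dosage_r2(post$dosage, sim$truth$genotypes))
    }, 0)
  })
  avg <- rowMeans(means)
  expect_true(all(diff(avg) > -0.005))
})
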