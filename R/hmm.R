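## Founder-haplotype hidden Markov model for reference-free imputation.
##
## Each individual's two chromosomes are modelled as mosaics of K unobserved
## founder haplotypes. The hidden state at a site is the ordered founder pair
## (k1, k2); each haplotype independently re-draws its founder with
## probability rho between adjacent sites (uniform destination). Founder k
## carries the alternate allele at site j with probability pi[k, j]; the
## emission at a site marginalizes the binomial read likelihood over the two
## founder alleles. pi is estimated by EM; rho is a fixed user parameter.
##
## All chain passes are scaled per site (log accumulators), and the
## recursions are vectorized across individuals: the K^2-state transition is
## a single (K^2 x K^2) matrix product applied to an n x K^2 slab.

## single-haplotype transition: stay with prob 1-rho, else uniform over K
hap_transition <- function(K, rho) {
  (1 - rho) * diag(K) + rho / K * matrix(1, K, K)
}

## state-space helpers: states are (k1, k2) pairs, column-major (k1 fastest)
pair_emission_weights <- function(pi_j) {
  ## 3 x K^2 matrix: P(g | k1, k2) for g = 0, 1, 2
  q <- 1 - pi_j
  rbind(as.vector(outer(q, q)),
        as.vector(outer(pi_j, q) + outer(q, pi_j)),
        as.vector(outer(pi_j, pi_j)))
}

## emissions for all individuals at site j: n x K^2
site_emission <- function(L0j, L1j, L2j, Bw) {
  cbind(L0j, L1j, L2j) %*% Bw
}

#' Fit the founder-haplotype HMM by EM
#'
#' Estimates the founder allele-probability table `pi` (K x n_sites) from
#' genotype likelihoods by expectation-maximization over the K^2
#' founder-pair chain. The switch probability `rho` is held fixed.
#'
#' Initialization matters: the EM surface has a near-symmetric saddle where
#' all founders sit at the population frequency, and small perturbations of
#' it converge slowly. The default `init = "kmeans"` therefore seeds the
#' founders from the centers of a seeded k-means clustering of the LD-free
#' baseline dosages (individuals cluster by founder-pair at strong LD, so
#' the centers straddle the founder space); `init = "jitter"` is the naive
#' alternative, the baseline frequency plus per-founder uniform jitter of
#' +-0.1. With `n_restarts > 1` additional independently seeded starts are
#' run and the best final log-likelihood wins.
#'
#' @param lik a `lik_tensor` from [genotype_likelihoods()]
#' @param K number of founder haplotypes (>= 2)
#' @param rho per-interval founder switch probability in `[0, 1)`
#' @param n_iter maximum EM iterations
#' @param tol stop when the log-likelihood improves by less than this
#' @param seed RNG seed for the initialization
#' @param init `"kmeans"` (default) or `"jitter"`
#' @param n_restarts number of independently seeded EM runs; the best final
#'   log-likelihood wins
#' @return an object of class `founder_hmm`: `pi`, `K`, `rho`, `loglik`
#'   (trace of the kept run), `converged`, `baseline_freq`
#' @export
fit_haplotype_hmm <- function(lik, K = 8, rho = 0.002, n_iter = 60,
                              tol = 1e-4, seed = 1,
                              init = c("kmeans", "jitter"), n_restarts = 1) {
  stopifnot(inherits(lik, "lik_tensor"))
  init <- match.arg(init)
  if (K < 2) stop("K must be >= 2 (a single founder collapses to the LD-free baseline)")
  K <- check_count(K, "K", min = 2L)
  check_scalar(rho, "rho", 0, 1, upper_open = TRUE)
  base <- baseline_dosages(lik)
  m <- dim(lik)[2]
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(child_seed(seed, r - 1), {
      km <- if (init == "kmeans" && nrow(base$dosage) >= 2 * K)
        tryCatch(stats::kmeans(base$dosage, centers = K, nstart = 5,
                               iter.max = 30),
                 error = function(e) NULL)
      else NULL
      pi0 <- if (!is.null(km)) {
        km$centers / 2
      } else {
        matrix(rep(base$freq, each = K), K, m) +
          matrix(stats::runif(K * m, -0.1, 0.1), K, m)
      }
      pi0 <- pmin(pmax(pi0, 1e-4), 1 - 1e-4)
      em_haplotype_hmm(lik, pi0, rho, n_iter, tol)
    })
    if (is.null(best) || utils::tail(fit$loglik, 1) > utils::tail(best$loglik, 1))
      best <- fit
  }
  structure(list(pi = best$pi, K = K, rho = rho, loglik = best$loglik,
                 converged = best$converged, baseline_freq = base$freq),
            class = "founder_hmm")
}

## One EM run from a given pi start.
em_haplotype_hmm <- function(lik, pi, rho, n_iter, tol) {
  n <- dim(lik)[1]; m <- dim(lik)[2]; K <- nrow(pi)
  L0 <- lik[, , 1, drop = FALSE]; dim(L0) <- c(n, m)
  L1 <- lik[, , 2, drop = FALSE]; dim(L1) <- c(n, m)
  L2 <- lik[, , 3, drop = FALSE]; dim(L2) <- c(n, m)
  T1 <- hap_transition(K, rho)
  Tp <- T1 %x% T1
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    fb <- forward_backward_all(L0, L1, L2, pi, Tp)
    ll_trace <- c(ll_trace, fb$loglik)
    ## M-step: expected alternate-allele dosage carried by each founder
    num <- matrix(0, K, m); den <- matrix(0, K, m)
    for (j in seq_len(m)) {
      pj <- pi[, j]; qj <- 1 - pj
      G <- matrix(fb$gamma[, , j], n, K * K)
      E <- matrix(fb$emission[, , j], n, K * K)
      ## E[a1 | state, reads] numerator: pi_k1 ((1-pi_k2) L1 + pi_k2 L2)
      N1 <- outer(L1[, j], as.vector(outer(pj, qj))) +
            outer(L2[, j], as.vector(outer(pj, pj)))
      N2 <- outer(L1[, j], as.vector(outer(qj, pj))) +
            outer(L2[, j], as.vector(outer(pj, pj)))
      W1 <- colSums(G * N1 / E)   # expected alt count via haplotype 1
      W2 <- colSums(G * N2 / E)
      Wt <- colSums(G)
      M1 <- matrix(W1, K, K); M2 <- matrix(W2, K, K); Mt <- matrix(Wt, K, K)
      num[, j] <- rowSums(M1) + colSums(M2)
      den[, j] <- rowSums(Mt) + colSums(Mt)
    }
    pi_new <- pmin(pmax(num / den, 1e-4), 1 - 1e-4)
    if (it > 1 && ll_trace[it] - ll_trace[it - 1] < tol) {
      converged <- TRUE
      break
    }
    pi <- pi_new
  }
  list(pi = pi, loglik = ll_trace, converged = converged)
}

## Scaled forward-backward for all individuals at once.
## Returns per-site state posteriors gamma [n, K^2, m], the emission slabs
## [n, K^2, m], and the total log-likelihood (sum over individuals).
forward_backward_all <- function(L0, L1, L2, pi, Tp) {
  n <- nrow(L0); m <- ncol(L0); K <- nrow(pi); S <- K * K
  slab <- function(arr, j) matrix(arr[, , j], n, S)
  emission <- array(NA_real_, c(n, S, m))
  for (j in seq_len(m))
    emission[, , j] <- site_emission(L0[, j], L1[, j], L2[, j],
                                     pair_emission_weights(pi[, j]))
  alpha <- array(NA_real_, c(n, S, m))
  logc <- matrix(NA_real_, n, m)
  a <- slab(emission, 1) / S
  cs <- rowSums(a)
  alpha[, , 1] <- a / cs
  logc[, 1] <- log(cs)
  if (m > 1) for (j in 2:m) {
    a <- (slab(alpha, j - 1) %*% Tp) * slab(emission, j)
    cs <- rowSums(a)
    alpha[, , j] <- a / cs
    logc[, j] <- log(cs)
  }
  beta <- array(NA_real_, c(n, S, m))
  beta[, , m] <- 1
  if (m > 1) for (j in (m - 1):1) {
    b <- (slab(beta, j + 1) * slab(emission, j + 1)) %*% t(Tp)
    beta[, , j] <- b / rowSums(b)
  }
  gamma <- alpha * beta
  for (j in seq_len(m)) {
    g <- slab(gamma, j)
    gamma[, , j] <- g / rowSums(g)
  }
  list(gamma = gamma, emission = emission, loglik = sum(logc))
}

#' Posterior genotypes from a fitted founder HMM
#'
#' Runs forward-backward under the fitted model and combines the state
#' posteriors with the per-state genotype distribution conditioned on the
#' site's reads:
#' `P(g | reads) = sum_s gamma_s P(g | s) L_g / sum_g' P(g' | s) L_g'`.
#' Hard calls are the posterior argmax with ties broken toward the smaller
#' genotype.
#'
#' @param model a `founder_hmm` from [fit_haplotype_hmm()]
#' @param lik the `lik_tensor` to impute (site count must match the model)
#' @return a `posterior_genotypes` object (probabilities, expected dosages,
#'   hard calls); `freq` holds the model-implied mean founder frequency
#' @export
impute_posteriors <- function(model, lik) {
  stopifnot(inherits(model, "founder_hmm"), inherits(lik, "lik_tensor"))
  n <- dim(lik)[1]; m <- dim(lik)[2]
  if (m != ncol(model$pi))
    stop(sprintf("site-count mismatch: model has %d sites, likelihoods have %d",
                 ncol(model$pi), m))
  L0 <- lik[, , 1, drop = FALSE]; dim(L0) <- c(n, m)
  L1 <- lik[, , 2, drop = FALSE]; dim(L1) <- c(n, m)
  L2 <- lik[, , 3, drop = FALSE]; dim(L2) <- c(n, m)
  K <- model$K
  T1 <- hap_transition(K, model$rho)
  fb <- forward_backward_all(L0, L1, L2, model$pi, T1 %x% T1)
  prob <- array(NA_real_, c(n, m, 3))
  for (j in seq_len(m)) {
    Bw <- pair_emission_weights(model$pi[, j])
    GE <- matrix(fb$gamma[, , j], n, K * K) /
          matrix(fb$emission[, , j], n, K * K)
    for (g in 1:3)
      prob[, j, g] <- (GE %*% Bw[g, ]) *
        switch(g, L0[, j], L1[, j], L2[, j])
  }
  s <- matrix(prob[, , 1], n, m) + matrix(prob[, , 2], n, m) +
       matrix(prob[, , 3], n, m)
  for (g in 1:3) prob[, , g] <- prob[, , g] / s
  new_posteriors(prob, freq = colMeans(model$pi), ids = attr(lik, "ids"))
}

#' @export
print.founder_hmm <- function(x, ...) {
  cat(sprintf("Founder-haplotype HMM: K = %d founders, %d sites, rho = %.4g\n",
              x$K, ncol(x$pi), x$rho))
  cat(sprintf("  EM iterations: %d (%sconverged), final log-likelihood %.3f\n",
              length(x$loglik), if (x$converged) "" else "not ",
              utils::tail(x$loglik, 1)))
  invisible(x)
}

#' @export
predict.founder_hmm <- function(object, lik, ...) impute_posteriors(object, lik)
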