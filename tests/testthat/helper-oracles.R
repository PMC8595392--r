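## Independent oracles used across test files.

## Brute-force posterior genotype probabilities for the founder-pair HMM:
## enumerate all (K^2)^m state paths, accumulate joint probabilities, and
## marginalize. Exponential in m; for chains of <= 5 sites and K <= 3 only.
brute_force_posteriors <- function(lik, pi, rho) {
  n <- dim(lik)[1]; m <- dim(lik)[2]; K <- nrow(pi); S <- K * K
  T1 <- (1 - rho) * diag(K) + rho / K * matrix(1, K, K)
  states <- expand.grid(k1 = 1:K, k2 = 1:K)   # k1 fastest: matches package order
  trans <- matrix(0, S, S)
  for (a in 1:S) for (b in 1:S)
    trans[a, b] <- T1[states$k1[a], states$k1[b]] * T1[states$k2[a], states$k2[b]]
  emis <- function(i, j, s) {
    p1 <- pi[states$k1[s], j]; p2 <- pi[states$k2[s], j]
    pg <- c((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)
    sum(pg * lik[i, j, ])
  }
  paths <- as.matrix(expand.grid(rep(list(1:S), m)))
  gamma <- array(0, c(n, S, m))
  gpost <- array(0, c(n, m, 3))
  for (i in 1:n) {
    pr <- numeric(nrow(paths))
    for (r in seq_len(nrow(paths))) {
      s <- paths[r, ]
      p <- 1 / S * emis(i, 1, s[1])
      if (m > 1) for (j in 2:m)
        p <- p * trans[s[j - 1], s[j]] * emis(i, j, s[j])
      pr[r] <- p
    }
    pr <- pr / sum(pr)
    for (j in 1:m) for (s in 1:S)
      gamma[i, s, j] <- sum(pr[paths[, j] == s])
    ## genotype posterior at each site: state posterior x genotype given reads
    for (j in 1:m) for (s in 1:S) {
      p1 <- pi[states$k1[s], j]; p2 <- pi[states$k2[s], j]
      pg <- c((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)
      w <- pg * lik[i, j, ]
      gpost[i, j, ] <- gpost[i, j, ] + gamma[i, s, j] * w / sum(w)
    }
  }
  list(gamma = gamma, gpost = gpost)
}

## likelihood tensor from explicit read counts (bypasses simulate_reads)
lik_from_counts <- function(ref, alt, error_rate = 0.01) {
  genotype_likelihoods(
    structure(list(ref = ref, alt = alt, error_rate = error_rate,
                   mean_depth = mean(ref + alt), ids = rownames(ref)),
              class = "read_counts"))
}

## 1-D grid-search REML oracle for a balanced repeated-records design:
## y_ij = mu + a_i + e_ij with a ~ N(0, va), unrelated individuals. For a
## grid of heritability ratios, profile the scale analytically and evaluate
## the restricted likelihood; returns the grid maximizer of h2 = va/(va+ve).
grid_reml_h2 <- function(y, ind, grid = seq(0.002, 0.998, by = 0.002)) {
  n <- length(y)
  Z <- outer(ind, sort(unique(ind)), "==") * 1
  X <- matrix(1, n, 1)
  best <- c(h2 = NA, ll = -Inf)
  for (h2 in grid) {
    V0 <- tcrossprod(Z) * h2 + diag(1 - h2, n)   # V = s2 * V0
    cV <- chol(V0)
    V0i <- chol2inv(cV)
    B <- crossprod(X, V0i %*% X)
    bhat <- solve(B, crossprod(X, V0i %*% y))
    r <- y - X %*% bhat
    quad <- sum(r * (V0i %*% r))
    s2 <- quad / (n - 1)
    ll <- -0.5 * (2 * sum(log(diag(cV))) + (n - 1) * log(s2) +
                  log(det(B)) + quad / s2)
    if (ll > best["ll"]) best <- c(h2 = h2, ll = ll)
  }
  best[["h2"]]
}
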