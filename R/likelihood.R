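## Read-level genotype likelihoods and the LD-free frequency baseline.

#' Biallelic genotype likelihoods from read counts
#'
#' For genotype g in {0, 1, 2} a read reports the alternate allele with
#' probability `error_rate`, 0.5, or `1 - error_rate` respectively, so with
#' `a` alternate reads out of `n`:
#' `P(reads | g) = C(n, a) p_g^a (1 - p_g)^(n - a)`.
#' Likelihoods are rescaled per individual-site to a maximum of 1 (the
#' constant cancels in every downstream posterior); sites with zero reads get
#' the uninformative triplet (1, 1, 1).
#'
#' @param reads a `read_counts` object
#' @param error_rate per-base error probability in (0, 0.5); defaults to the
#'   rate stored in `reads`
#' @return an object of class `lik_tensor`: a numeric array
#'   `[n_ind, n_sites, 3]` with slices for g = 0, 1, 2, with attribute `ids`
#' @export
genotype_likelihoods <- function(reads, error_rate = reads$error_rate) {
  stopifnot(inherits(reads, "read_counts"))
  check_scalar(error_rate, "error_rate", 0, 0.5, lower_open = TRUE, upper_open = TRUE)
  a <- reads$alt; n <- reads$alt + reads$ref
  p <- c(error_rate, 0.5, 1 - error_rate)
  L <- array(NA_real_, c(nrow(a), ncol(a), 3))
  for (g in 1:3)
    L[, , g] <- stats::dbinom(a, n, p[g])
  mx <- pmax(L[, , 1], L[, , 2], L[, , 3])
  for (g in 1:3) L[, , g] <- L[, , g] / mx
  structure(L, class = "lik_tensor", ids = reads$ids)
}

#' LD-free posterior dosages under Hardy-Weinberg priors
#'
#' Site-by-site EM for the alternate-allele frequency: given the current
#' frequency p, each individual's genotype posterior is the Hardy-Weinberg
#' prior `((1-p)^2, 2p(1-p), p^2)` times its read likelihood, normalized; the
#' new p is the mean posterior dosage / 2. This is the single-site
#' (linkage-free) baseline against which the haplotype HMM is compared.
#'
#' @param lik a `lik_tensor` from [genotype_likelihoods()]
#' @param tol convergence tolerance on the frequency (default 1e-6)
#' @param max_iter maximum EM iterations per site (default 100)
#' @return an object of class `posterior_genotypes` (list): `prob` array
#'   `[n, m, 3]` of genotype posteriors, `dosage` n x m matrix in `[0, 2]`,
#'   `hard` n x m hard calls in {0,1,2} (ties toward the smaller genotype),
#'   and `freq`, the estimated alternate-allele frequencies
#' @export
baseline_dosages <- function(lik, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(lik, "lik_tensor"))
  n <- dim(lik)[1]; m <- dim(lik)[2]
  L0 <- lik[, , 1, drop = FALSE]; dim(L0) <- c(n, m)
  L1 <- lik[, , 2, drop = FALSE]; dim(L1) <- c(n, m)
  L2 <- lik[, , 3, drop = FALSE]; dim(L2) <- c(n, m)
  if (any(L0 + L1 + L2 == 0))
    stop("degenerate site: all three genotype likelihoods are zero")
  ## moment start: mean of the per-individual ML dosage, mildly shrunk
  p <- pmin(pmax((colSums(L2 > pmax(L0, L1)) * 2 +
                  colSums(L1 > pmax(L0, L2))) / (2 * n), 0.01), 0.99)
  for (it in seq_len(max_iter)) {
    w0 <- t((1 - p)^2 * t(L0))
    w1 <- t(2 * p * (1 - p) * t(L1))
    w2 <- t(p^2 * t(L2))
    s <- w0 + w1 + w2
    p_new <- colMeans((w1 + 2 * w2) / s) / 2
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  w0 <- t((1 - p)^2 * t(L0))
  w1 <- t(2 * p * (1 - p) * t(L1))
  w2 <- t(p^2 * t(L2))
  s <- w0 + w1 + w2
  prob <- array(c(w0 / s, w1 / s, w2 / s), c(n, m, 3))
  new_posteriors(prob, freq = p, ids = attr(lik, "ids"))
}

## Assemble a posterior_genotypes object from a probability array.
new_posteriors <- function(prob, freq = NULL, ids = NULL) {
  n <- dim(prob)[1]; m <- dim(prob)[2]
  p1 <- prob[, , 2, drop = FALSE]; dim(p1) <- c(n, m)
  p2 <- prob[, , 3, drop = FALSE]; dim(p2) <- c(n, m)
  dosage <- p1 + 2 * p2
  flat <- matrix(aperm(prob, c(1, 2, 3)), n * m, 3)
  hard <- matrix(max.col(flat, ties.method = "first") - 1L, n, m)
  if (!is.null(ids)) { rownames(dosage) <- ids; rownames(hard) <- ids }
  structure(list(prob = prob, dosage = dosage, hard = hard, freq = freq,
                 ids = ids),
            class = "posterior_genotypes")
}

#' @export
print.posterior_genotypes <- function(x, ...) {
  cat(sprintf("Posterior genotypes: %d individuals x %d sites (mean dosage %.3f)\n",
              nrow(x$dosage), ncol(x$dosage), mean(x$dosage)))
  invisible(x)
}
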