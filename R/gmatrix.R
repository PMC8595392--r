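## Site QC, LD pruning, and relationship matrices (genomic and pedigree).

#' MAF / Hardy-Weinberg site filters
#'
#' Keeps sites with minor-allele frequency >= `maf_min` AND a 1-df chi-square
#' Hardy-Weinberg test p-value strictly > `hwe_p_min` (the boundary rules of
#' the standard QC convention: >= for MAF, strict > for HWE). Dosage input is
#' rounded to the nearest genotype for the HWE genotype counts.
#'
#' @param geno n x m genotype (0/1/2) or dosage matrix
#' @param maf_min minimum minor-allele frequency (default 0.01)
#' @param hwe_p_min HWE p-value threshold (default 1e-6)
#' @return an object of class `site_filter_result`: `kept` (indices), `maf`,
#'   `hwe_p` (per site), and `removed` counts per rule
#' @export
site_filters <- function(geno, maf_min = 0.01, hwe_p_min = 1e-6) {
  g <- round(geno)
  g[g < 0] <- 0; g[g > 2] <- 2
  n <- nrow(g)
  p <- colMeans(g) / 2
  maf <- pmin(p, 1 - p)
  n2 <- colSums(g == 2); n1 <- colSums(g == 1); n0 <- n - n1 - n2
  e2 <- n * p^2; e1 <- n * 2 * p * (1 - p); e0 <- n * (1 - p)^2
  chi2 <- rep(0, ncol(g))
  poly <- p > 0 & p < 1
  chi2[poly] <- (n0[poly] - e0[poly])^2 / e0[poly] +
                (n1[poly] - e1[poly])^2 / e1[poly] +
                (n2[poly] - e2[poly])^2 / e2[poly]
  hwe_p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p <= hwe_p_min
  kept <- which(!fail_maf & !fail_hwe)
  if (!length(kept)) stop("no sites survive the MAF/HWE filters")
  structure(list(kept = kept, maf = maf, hwe_p = hwe_p,
                 removed = c(maf = sum(fail_maf),
                             hwe = sum(fail_hwe & !fail_maf))),
            class = "site_filter_result")
}

#' Windowed greedy LD pruning
#'
#' Slides a window of `window_size` sites advancing by `step`; within each
#' window, while any pair of retained sites has squared genotype correlation
#' above `r2_max`, the member of the currently worst (highest-r2) pair with
#' the smaller MAF is removed (ties: the larger index). Deterministic given
#' the input order.
#'
#' @param geno n x m genotype or dosage matrix
#' @param r2_max maximum allowed pairwise r2, in (0, 1]
#' @param window_size,step window geometry in sites
#' @return integer vector of kept (column) indices
#' @export
ld_prune <- function(geno, r2_max, window_size = 50, step = 5) {
  check_scalar(r2_max, "r2_max", 0, 1, lower_open = TRUE)
  m <- ncol(geno)
  p <- colMeans(geno) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  starts <- if (m <= window_size) 1L else
    unique(c(seq(1L, m - window_size + 1L, by = step), m - window_size + 1L))
  for (s in starts) {
    win <- s:min(s + window_size - 1L, m)
    repeat {
      idx <- win[keep[win]]
      if (length(idx) < 2L) break
      cc <- suppressWarnings(stats::cor(geno[, idx, drop = FALSE]))
      r2 <- cc^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      mx <- max(r2)
      if (mx <= r2_max) break
      w <- which(r2 == mx, arr.ind = TRUE)[1, ]
      a <- idx[w[1]]; b <- idx[w[2]]
      drop_site <- if (maf[a] < maf[b]) a
        else if (maf[b] < maf[a]) b
        else max(a, b)
      keep[drop_site] <- FALSE
    }
  }
  which(keep)
}

#' Genotype-based genomic relationship matrix
#'
#' VanRaden's first method: `G = W W' / sum_j 2 p_j (1 - p_j)` with
#' `w_ij = m_ij - 2 p_j`, where `p_j` is the alternate-allele frequency
#' (in-sample unless supplied).
#'
#' @param geno n x m genotype matrix (0/1/2)
#' @param freqs optional per-site allele frequencies used for centering
#' @return an object of class `grm`: the n x n matrix plus `source`,
#'   `n_markers`, `denom`
#' @export
grm_genotype <- function(geno, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(geno) / 2
  denom <- sum(2 * freqs * (1 - freqs))
  if (denom <= 0) stop("zero denominator: all sites monomorphic")
  W <- sweep(geno, 2, 2 * freqs)
  G <- tcrossprod(W) / denom
  new_grm((G + t(G)) / 2, "genotype", ncol(geno), denom, rownames(geno))
}

#' Dosage-based genomic relationship matrix
#'
#' `G = D D' / s_d` with `D` the column-centered dosage matrix and
#' `s_d = sum_j var(D_j)` using the population (denominator n) variance, so
#' `trace(G) = n` exactly.
#'
#' @param dosage n x m expected-dosage matrix in `[0, 2]`
#' @return a `grm` object with source `"dosage"`
#' @export
grm_dosage <- function(dosage) {
  s_d <- sum(col_pvar(dosage))
  if (s_d <= 0) stop("zero denominator: all dosage columns constant")
  D <- sweep(dosage, 2, colMeans(dosage))
  G <- tcrossprod(D) / s_d
  new_grm((G + t(G)) / 2, "dosage", ncol(dosage), s_d, rownames(dosage))
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' `a_ii = 1 + 0.5 a(sire, dam)`; `a_ij = 0.5 (a(j, sire_i) + a(j, dam_i))`,
#' with unknown parents contributing 0. The pedigree is topologically sorted
#' first; a cycle is an error.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (0, "", or NA for
#'   unknown parents)
#' @return a `grm` object with source `"pedigree"`, rows/columns in the
#'   input id order
#' @export
pedigree_a_matrix <- function(ped) {
  ped <- as.data.frame(ped)
  if (!all(c("id", "sire", "dam") %in% names(ped)))
    stop("pedigree needs columns id, sire, dam")
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA
    x
  }
  sire <- clean(ped$sire); dam <- clean(ped$dam)
  unknown_parent <- c(sire, dam)[!is.na(c(sire, dam)) & !(c(sire, dam) %in% id)]
  if (length(unknown_parent))
    stop("parents absent from pedigree: ",
         paste(unique(unknown_parent), collapse = ", "))
  n <- length(id)
  pos <- stats::setNames(seq_len(n), id)
  ## topological order (Kahn); detects cycles
  parents <- cbind(ifelse(is.na(sire), 0L, pos[sire]),
                   ifelse(is.na(dam), 0L, pos[dam]))
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[i, ]) if (p > 0L) {
    indeg[i] <- indeg[i] + 1L
    children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L); order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) stop("pedigree contains a cycle")
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in order) {
    s <- parents[i, 1]; d <- parents[i, 2]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    done <- order[seq_len(match(i, order) - 1L)]
    for (jj in done) {
      aij <- 0.5 * ((if (s > 0L) A[jj, s] else 0) +
                    (if (d > 0L) A[jj, d] else 0))
      A[i, jj] <- A[jj, i] <- aij
    }
  }
  new_grm(A, "pedigree", NA_integer_, NA_real_, id)
}

new_grm <- function(G, source, n_markers, denom, ids = NULL) {
  if (!is.null(ids)) dimnames(G) <- list(ids, ids)
  structure(list(G = G, source = source, n_markers = n_markers,
                 denom = denom),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d x %d (mean diag %.3f)\n",
              x$source, nrow(x$G), ncol(x$G), mean(diag(x$G))))
  invisible(x)
}

#' Stabilize a relationship matrix for mixed-model solves
#'
#' Adds `jitter` to the diagonal if the smallest eigenvalue is at or below
#' zero (near-duplicate individuals), with a message.
#' @param grm a `grm` object (or plain matrix)
#' @param jitter diagonal increment (default 1e-6)
#' @return the (possibly jittered) `grm`/matrix, same type as the input
#' @export
stabilize_grm <- function(grm, jitter = 1e-6) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    message(sprintf("relationship matrix not positive definite (min eig %.3g); adding %.1g to diagonal",
                    ev_min, jitter))
    G <- G + diag(jitter, nrow(G))
  }
  if (inherits(grm, "grm")) { grm$G <- G; grm } else G
}

#' Write a relationship matrix as tab-delimited text with id headers
#' @param grm a `grm` object or matrix
#' @param path output path
#' @export
write_grm <- function(grm, path) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  utils::write.table(G, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a relationship matrix written by [write_grm()]
#' @param path input path
#' @return a numeric matrix with id dimnames
#' @export
read_grm <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}
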