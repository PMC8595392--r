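## Single- and two-trait GBLUP: AI-REML variance components, mixed-model
## breeding-value prediction, and derived genetic parameters.
##
## The model is y = Xb + Zu + e with u ~ N(0, G * sigma_a^2) for one trait,
## and for two traits [u1; u2] ~ N(0, G (x) M), [e1; e2] ~ N(0, I (x) R),
## where M and R are the 2x2 genetic and residual (co)variance matrices.
## REML maximization uses average-information (AI) updates with step halving
## and an exact EM-REML fallback, so the restricted log-likelihood never
## decreases across accepted iterations.
##
## Two computational paths: when every phenotyped individual has a record on
## every modelled trait, the likelihood factorizes over the eigenvectors of
## G into n independent t x t blocks (lam_i M + R) and all REML quantities
## are O(n) per iteration ("eigen" path). Arbitrary missing-record patterns
## use a dense-V path ("direct"), quadratic in the record count.

#' Specify a GBLUP model
#'
#' @param fixed a formula (single trait) or named list of per-trait formulas,
#'   e.g. `list(t1 = ~ sex + year_season, t2 = ~ sex + year_season + age)`.
#'   Formulas are right-hand-side only; the response is always the `value`
#'   column of the phenotype table.
#' @param traits trait names, matching levels of the phenotype `trait`
#'   column; defaults to the names of `fixed`
#' @return an object of class `gblup_spec`
#' @export
model_spec <- function(fixed, traits = NULL) {
  if (inherits(fixed, "formula")) fixed <- list(t1 = fixed)
  if (is.null(traits)) traits <- names(fixed)
  if (is.null(traits) || any(!nzchar(traits)))
    stop("trait names required (name the elements of 'fixed')")
  if (length(fixed) != length(traits) || !length(traits) %in% 1:2)
    stop("1 or 2 traits supported")
  names(fixed) <- traits
  structure(list(traits = traits, fixed = fixed), class = "gblup_spec")
}

## Per-trait design matrices and response vectors from a long phenotype table.
## Returns records split by trait, with the individual index into `ids`.
build_design <- function(spec, pheno, ids) {
  out <- vector("list", length(spec$traits))
  names(out) <- spec$traits
  for (t in seq_along(spec$traits)) {
    tr <- spec$traits[t]
    sub <- pheno[pheno$trait == tr & !is.na(pheno$value), , drop = FALSE]
    if (!nrow(sub)) {
      if (length(spec$traits) == 1L) stop("no records for trait ", tr)
      ## trait entirely unobserved: no records, no estimable fixed effects
      out[[t]] <- list(y = numeric(0), X = matrix(0, 0, 0), ind = integer(0))
      next
    }
    miss <- setdiff(as.character(sub$id), ids)
    if (length(miss))
      stop("phenotyped individuals absent from the relationship matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
    X <- stats::model.matrix(spec$fixed[[tr]], data = sub)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("fixed-effect design for trait ", tr,
           " is rank deficient; confounded columns: ",
           paste(bad, collapse = ", "))
    }
    out[[t]] <- list(y = sub$value, X = X,
                     ind = match(as.character(sub$id), ids))
  }
  out
}

## parameter bookkeeping: theta layout per trait count ----------------------
theta_names <- function(nt) {
  if (nt == 1L) c("var_a", "var_e")
  else c("var_a1", "cov_a", "var_a2", "var_e1", "cov_e", "var_e2")
}

theta_to_MR <- function(theta, nt) {
  if (nt == 1L) list(M = matrix(theta[1], 1, 1), R = matrix(theta[2], 1, 1))
  else list(M = matrix(theta[c(1, 2, 2, 3)], 2, 2),
            R = matrix(theta[c(4, 5, 5, 6)], 2, 2))
}

## parameter list: for each theta element, which matrix (M genetic weighted
## by lam, R residual) and which symmetric structure element it moves
param_table <- function(nt) {
  if (nt == 1L)
    list(list(mat = "M", r = 1, c = 1), list(mat = "R", r = 1, c = 1))
  else
    list(list(mat = "M", r = 1, c = 1), list(mat = "M", r = 1, c = 2),
         list(mat = "M", r = 2, c = 2), list(mat = "R", r = 1, c = 1),
         list(mat = "R", r = 1, c = 2), list(mat = "R", r = 2, c = 2))
}

theta_valid <- function(theta, nt, floor_v) {
  mr <- theta_to_MR(theta, nt)
  if (nt == 1L)
    return(theta[1] >= floor_v[1] && theta[2] >= floor_v[2])
  va <- theta[c(1, 3)]; ve <- theta[c(4, 6)]
  all(va >= floor_v[1:2]) && all(ve >= floor_v[3:4]) &&
    theta[2]^2 <= prod(va) && theta[5]^2 < prod(ve)
}

#' Precompute the eigendecomposition of a relationship matrix
#'
#' The eigen REML path spends most of its time decomposing G; when many
#' models are fitted against the same matrix (replicated simulations,
#' single- and multi-trait fits), decompose once and pass the result to
#' [reml_fit()] in place of `G`. The decomposition is used only when the
#' phenotyped individuals cover all of G; otherwise the needed submatrix is
#' re-decomposed.
#'
#' @param G a `grm` object or relationship matrix with id dimnames
#' @return an object of class `grm_eigen` (fields `G`, `U`, `lam`)
#' @export
grm_eigen <- function(G) {
  Gm <- if (inherits(G, "grm")) G$G else G
  if (is.null(rownames(Gm)))
    dimnames(Gm) <- list(as.character(seq_len(nrow(Gm))),
                         as.character(seq_len(nrow(Gm))))
  eg <- eigen(Gm, symmetric = TRUE)
  structure(list(G = Gm, U = eg$vectors, lam = pmax(eg$values, 1e-10)),
            class = "grm_eigen")
}

#' Fit a GBLUP mixed model by AI-REML
#'
#' Estimates the additive and residual (co)variance components of a single-
#' or two-trait GBLUP model by restricted maximum likelihood with
#' average-information updates (EM-REML fallback when an AI step leaves the
#' parameter space or decreases the likelihood), then solves for fixed
#' effects and genomic breeding values at the estimates.
#'
#' @param spec a [model_spec()]
#' @param pheno long phenotype table: columns `id`, `trait`, `value`, plus
#'   any covariates the fixed-effect formulas use
#' @param G a `grm` object or an n x n relationship matrix with id dimnames
#' @param init optional named numeric vector of starting values (see
#'   `theta_names`); defaults to half the phenotypic variance for each
#'   variance and half the maximal magnitude, signed by the sample trait
#'   correlation, for covariances
#' @param tol convergence tolerance on the REML log-likelihood change
#' @param max_iter maximum iterations
#' @param method `"auto"` (eigen path when records are complete across
#'   traits, else direct), `"eigen"`, or `"direct"`
#' @param verbose print the likelihood trace
#' @return an object of class `gblup_fit` with components `theta`, `se`,
#'   `M`, `R`, `bhat` (per-trait fixed effects), `gebv` (n x t matrix over
#'   all individuals in G), `loglik` (trace), `converged`, `ai` (the final
#'   average-information matrix), and the inputs needed by `predict`
#' @export
reml_fit <- function(spec, pheno, G, init = NULL, tol = 1e-8, max_iter = 200,
                     method = c("auto", "eigen", "direct"), verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "gblup_spec"))
  pre_eigen <- NULL
  if (inherits(G, "grm_eigen")) { pre_eigen <- G; G <- G$G }
  Gm <- if (inherits(G, "grm")) G$G else G
  ids <- rownames(Gm)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(Gm)))
    dimnames(Gm) <- list(ids, ids)
  }
  pheno$trait <- as.character(pheno$trait)
  des <- build_design(spec, pheno, ids)
  nt <- length(des)

  complete <- TRUE
  if (nt >= 1L) {
    ref <- sort(des[[1]]$ind)
    for (t in seq_len(nt)) {
      it <- des[[t]]$ind
      if (anyDuplicated(it) || !identical(sort(it), ref)) complete <- FALSE
    }
  }
  if (method == "eigen" && !complete)
    stop("eigen path requires one record per trait per individual; use method = 'direct'")
  use_eigen <- method == "eigen" || (method == "auto" && complete)

  ## default initialization
  vy <- vapply(des, function(d) if (length(d$y) > 1) stats::var(d$y) else NA_real_, 0)
  vy[!is.finite(vy) | vy <= 0] <- 1
  if (is.null(init)) {
    theta <- if (nt == 1L) c(vy / 2, vy / 2) else {
      sgn <- {
        i1 <- des[[1]]$ind; i2 <- des[[2]]$ind
        common <- intersect(i1, i2)
        if (length(common) > 2)
          sign(stats::cor(des[[1]]$y[match(common, i1)],
                          des[[2]]$y[match(common, i2)]))
        else 1
      }
      if (sgn == 0) sgn <- 1
      c(vy[1] / 2, sgn * 0.5 * sqrt(prod(vy)) / 2, vy[2] / 2,
        vy[1] / 2, sgn * 0.5 * sqrt(prod(vy)) / 2, vy[2] / 2)
    }
  } else {
    theta <- init[theta_names(nt)]
    if (anyNA(theta)) stop("init must be named with: ",
                           paste(theta_names(nt), collapse = ", "))
  }
  names(theta) <- theta_names(nt)
  floor_v <- if (nt == 1L) 1e-8 * c(vy, vy) else 1e-8 * vy[c(1, 2, 1, 2)]
  theta <- pmax(theta, if (nt == 1L) floor_v else
    c(floor_v[1], -Inf, floor_v[2], floor_v[3], -Inf, floor_v[4]))

  eng <- if (use_eigen) eigen_engine(des, Gm, nt, pre_eigen)
         else direct_engine(des, Gm, nt)
  fit <- reml_iterate(eng, theta, nt, floor_v, tol, max_iter, verbose)

  mr <- theta_to_MR(fit$theta, nt)
  gebv <- gebv_solve(fit$theta, des, Gm, nt, masked = integer(0))
  colnames(gebv$u) <- spec$traits
  rownames(gebv$u) <- ids
  bhat <- gebv$bhat
  names(bhat) <- NULL
  structure(list(theta = fit$theta, se = fit$se, M = mr$M, R = mr$R,
                 bhat = stats::setNames(gebv$bhat, spec$traits),
                 gebv = gebv$u, loglik = fit$loglik,
                 converged = fit$converged, n_iter = fit$n_iter,
                 ai = fit$ai, spec = spec, ids = ids, G = Gm,
                 pheno = pheno, method = if (use_eigen) "eigen" else "direct",
                 n_records = vapply(des, function(d) length(d$y), 0L)),
            class = "gblup_fit")
}

## Shared REML driver: engines expose loglik(theta) and stats(theta)
## (loglik, gradient, AI matrix, EM proposal).
reml_iterate <- function(eng, theta, nt, floor_v, tol, max_iter, verbose) {
  ll_trace <- numeric(0)
  st <- eng$stats(theta)
  ll <- st$ll
  converged <- FALSE
  ai <- st$ai
  for (it in seq_len(max_iter)) {
    ll_trace <- c(ll_trace, ll)
    if (verbose) message(sprintf("iter %d logL %.6f", it, ll))
    ## AI (quasi-Newton) proposal with step halving
    delta <- tryCatch(solve(st$ai, st$grad), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:30) {
        cand <- theta + step * delta
        if (theta_valid(cand, nt, floor_v)) {
          llc <- eng$loglik(cand)
          if (is.finite(llc) && llc >= ll - 1e-12) {
            theta <- cand; ll_new <- llc; accepted <- TRUE
            break
          }
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      ## exact EM-REML step (guaranteed ascent, stays in the parameter space)
      cand <- eng$em(theta)
      cand <- pmax(cand, if (nt == 1L) floor_v else
        c(floor_v[1], -Inf, floor_v[2], floor_v[3], -Inf, floor_v[4]))
      llc <- eng$loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-10) {
        theta <- cand; ll_new <- llc; accepted <- TRUE
      }
    }
    if (!accepted) { converged <- TRUE; break }  # no direction improves
    st <- eng$stats(theta)
    ai <- st$ai
    if (abs(ll_new - ll) < tol) { ll <- st$ll; converged <- TRUE; break }
    ll <- st$ll
  }
  ll_trace <- c(ll_trace, ll)
  se <- tryCatch(sqrt(diag(solve(ai))), error = function(e) rep(NA_real_, length(theta)))
  names(se) <- names(theta)
  list(theta = theta, se = se, loglik = ll_trace, converged = converged,
       n_iter = length(ll_trace) - 1L, ai = ai)
}

## ---------------------------------------------------------------------------
## Eigen path: complete records, G = U diag(lam) U'
eigen_engine <- function(des, Gm, nt, pre_eigen = NULL) {
  ids <- rownames(Gm)
  ord <- sort(des[[1]]$ind)
  if (!is.null(pre_eigen) && length(ord) == nrow(Gm) &&
      identical(ord, seq_len(nrow(Gm)))) {
    lam <- pre_eigen$lam
    U <- pre_eigen$U
  } else {
    eg <- eigen(Gm[ord, ord, drop = FALSE], symmetric = TRUE)
    lam <- pmax(eg$values, 1e-10)
    U <- eg$vectors
  }
  n <- length(ord)
  Y <- matrix(0, n, nt)
  Xr <- vector("list", nt)
  for (t in seq_len(nt)) {
    perm <- match(ord, des[[t]]$ind)
    Y[, t] <- crossprod(U, des[[t]]$y[perm])
    Xr[[t]] <- crossprod(U, des[[t]]$X[perm, , drop = FALSE])
  }
  pt <- vapply(Xr, ncol, 0L)
  p <- sum(pt)
  blk <- split(seq_len(p), rep(seq_len(nt), pt))
  ptab <- param_table(nt)

  dinv_arr <- function(D) {
    ## D: array (n, t, t) -> inverse entries + log-determinant sum
    if (nt == 1L) {
      list(inv = array(1 / D, dim(D)), ldet = sum(log(D[, 1, 1])))
    } else {
      a <- D[, 1, 1]; b <- D[, 1, 2]; d <- D[, 2, 2]
      det <- a * d - b * b
      inv <- array(0, dim(D))
      inv[, 1, 1] <- d / det; inv[, 2, 2] <- a / det
      inv[, 1, 2] <- inv[, 2, 1] <- -b / det
      list(inv = inv, ldet = sum(log(det)))
    }
  }
  make_D <- function(theta) {
    mr <- theta_to_MR(theta, nt)
    D <- array(0, c(n, nt, nt))
    for (r in seq_len(nt)) for (c in seq_len(nt))
      D[, r, c] <- lam * mr$M[r, c] + mr$R[r, c]
    D
  }
  xtwx <- function(W) {
    B <- matrix(0, p, p)
    for (r in seq_len(nt)) for (c in seq_len(nt))
      B[blk[[r]], blk[[c]]] <- crossprod(Xr[[r]] * W[, r, c], Xr[[c]])
    (B + t(B)) / 2
  }
  xtwv <- function(W, V) {
    out <- numeric(p)
    for (r in seq_len(nt)) {
      acc <- numeric(n)
      for (c in seq_len(nt)) acc <- acc + W[, r, c] * V[, c]
      out[blk[[r]]] <- crossprod(Xr[[r]], acc)
    }
    out
  }
  xc <- function(cv) {
    V <- matrix(0, n, nt)
    for (r in seq_len(nt)) V[, r] <- Xr[[r]] %*% cv[blk[[r]]]
    V
  }
  bmul <- function(W, V) {
    out <- matrix(0, n, nt)
    for (r in seq_len(nt)) for (c in seq_len(nt))
      out[, r] <- out[, r] + W[, r, c] * V[, c]
    out
  }

  core <- function(theta) {
    D <- make_D(theta)
    di <- dinv_arr(D)
    B <- xtwx(di$inv)
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cB)) return(NULL)
    ldetB <- 2 * sum(log(diag(cB)))
    Binv <- chol2inv(cB)
    bhat <- Binv %*% xtwv(di$inv, Y)
    E <- Y - xc(bhat)
    Q <- bmul(di$inv, E)
    ll <- -0.5 * (di$ldet + ldetB + sum(E * Q))
    list(D = D, Dinv = di$inv, B = B, Binv = Binv, bhat = bhat,
         E = E, Q = Q, ll = ll)
  }

  loglik <- function(theta) {
    cr <- core(theta)
    if (is.null(cr)) -Inf else cr$ll
  }

  stats <- function(theta) {
    cr <- core(theta)
    if (is.null(cr)) stop("non-finite likelihood at current parameters")
    Dinv <- cr$Dinv; Q <- cr$Q
    np <- length(ptab)
    grad <- numeric(np)
    Svecs <- vector("list", np)
    for (k in seq_len(np)) {
      pk <- ptab[[k]]
      w <- if (pk$mat == "M") lam else rep(1, n)
      r <- pk$r; c <- pk$c
      sym <- if (r == c) 1 else 2
      ypvpy <- if (r == c) sum(w * Q[, r] * Q[, c]) else 2 * sum(w * Q[, r] * Q[, c])
      trvv <- if (r == c) sum(w * Dinv[, r, c]) else 2 * sum(w * Dinv[, r, c])
      ## H_k = X' (w * Dinv S Dinv) X
      DSD <- array(0, c(n, nt, nt))
      for (rr in seq_len(nt)) for (cc in seq_len(nt)) {
        v <- Dinv[, rr, r] * Dinv[, c, cc]
        if (r != c) v <- v + Dinv[, rr, c] * Dinv[, r, cc]
        DSD[, rr, cc] <- w * v
      }
      Hk <- xtwx(DSD)
      trPV <- trvv - sum(cr$Binv * Hk)
      grad[k] <- -0.5 * (trPV - ypvpy)
      ## s_k = V_k P y (blocks w * S Q)
      s <- matrix(0, n, nt)
      s[, r] <- s[, r] + w * Q[, c]
      if (r != c) s[, c] <- s[, c] + w * Q[, r]
      Svecs[[k]] <- s
    }
    Ps <- vector("list", np)
    for (k in seq_len(np)) {
      u <- bmul(Dinv, Svecs[[k]])
      cv <- cr$Binv %*% xtwv_plain(u)
      Ps[[k]] <- u - bmul(Dinv, xc(cv))
    }
    ai <- matrix(0, np, np)
    for (k in seq_len(np)) for (l in k:np) {
      ai[k, l] <- ai[l, k] <- 0.5 * sum(Svecs[[k]] * Ps[[l]])
    }
    list(ll = cr$ll, grad = grad, ai = ai)
  }
  xtwv_plain <- function(V) {
    out <- numeric(p)
    for (r in seq_len(nt)) out[blk[[r]]] <- crossprod(Xr[[r]], V[, r])
    out
  }

  em <- function(theta) {
    cr <- core(theta)
    if (is.null(cr)) return(theta)
    mr <- theta_to_MR(theta, nt)
    Dinv <- cr$Dinv; Binv <- cr$Binv; Q <- cr$Q
    ## diagonal t x t blocks of P = Dinv - Dinv X Binv X' Dinv
    Z <- vector("list", nt)  # rows of Dinv X per output trait
    for (r in seq_len(nt)) {
      Zr <- matrix(0, n, p)
      for (c in seq_len(nt)) Zr[, blk[[c]]] <- Xr[[c]] * Dinv[, r, c]
      Z[[r]] <- Zr
    }
    Pb <- array(0, c(n, nt, nt))
    for (r in seq_len(nt)) for (c in r:nt) {
      v <- Dinv[, r, c] - rowSums((Z[[r]] %*% Binv) * Z[[c]])
      Pb[, r, c] <- Pb[, c, r] <- v
    }
    SM <- matrix(0, nt, nt); SR <- matrix(0, nt, nt)
    for (r in seq_len(nt)) for (c in seq_len(nt)) {
      SM[r, c] <- sum(lam * (Pb[, r, c] - Q[, r] * Q[, c]))
      SR[r, c] <- sum(Pb[, r, c] - Q[, r] * Q[, c])
    }
    Mn <- mr$M - mr$M %*% SM %*% mr$M / n
    Rn <- mr$R - mr$R %*% SR %*% mr$R / n
    if (nt == 1L) c(Mn[1, 1], Rn[1, 1])
    else c(Mn[1, 1], Mn[1, 2], Mn[2, 2], Rn[1, 1], Rn[1, 2], Rn[2, 2])
  }

  list(loglik = loglik, stats = stats, em = em)
}

## ---------------------------------------------------------------------------
## Direct path: dense V over the observed records; handles missing traits.
direct_engine <- function(des, Gm, nt) {
  recs <- do.call(rbind, lapply(seq_len(nt), function(t)
    if (length(des[[t]]$y))
      data.frame(trait = t, ind = des[[t]]$ind, y = des[[t]]$y)))
  nrec <- nrow(recs)
  pt <- vapply(des, function(d) ncol(d$X), 0L)
  p <- sum(pt)
  X <- matrix(0, nrec, p)
  off <- c(0, cumsum(pt))
  row0 <- 0
  for (t in seq_len(nt)) {
    nr <- length(des[[t]]$y)
    if (nr) X[row0 + seq_len(nr), off[t] + seq_len(pt[t])] <- des[[t]]$X
    row0 <- row0 + nr
  }
  y <- recs$y
  ptab <- param_table(nt)
  np <- length(ptab)
  ## component matrices V_k
  Vk <- vector("list", np)
  same_ind <- outer(recs$ind, recs$ind, "==")
  Gpair <- Gm[recs$ind, recs$ind]
  for (k in seq_len(np)) {
    pk <- ptab[[k]]
    sel <- (outer(recs$trait, recs$trait, function(a, b)
      (a == pk$r & b == pk$c) | (a == pk$c & b == pk$r)))
    Vk[[k]] <- if (pk$mat == "M") Gpair * sel
    else if (pk$r == pk$c) diag(as.numeric(recs$trait == pk$r))
    else same_ind * sel   # residual covariance pairs trait records per individual
  }
  ## parameters whose component matrix is identically zero (e.g. the second
  ## trait has no records) do not enter the likelihood; freeze them
  active <- vapply(Vk, function(v) any(v != 0), TRUE)
  build_V <- function(theta) {
    V <- matrix(0, nrec, nrec)
    for (k in which(active)) V <- V + theta[k] * Vk[[k]]
    V
  }
  core <- function(theta) {
    V <- build_V(theta)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vinv <- chol2inv(cV)
    B <- crossprod(X, Vinv %*% X)
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cB)) return(NULL)
    Binv <- chol2inv(cB)
    P <- Vinv - Vinv %*% X %*% Binv %*% t(X) %*% Vinv
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cB))) +
                  sum(y * Py))
    list(P = P, Py = Py, ll = ll)
  }
  loglik <- function(theta) {
    cr <- core(theta)
    if (is.null(cr)) -Inf else cr$ll
  }
  stats <- function(theta) {
    cr <- core(theta)
    if (is.null(cr)) stop("non-finite likelihood at current parameters")
    grad <- numeric(np)
    svecs <- vector("list", np)
    for (k in which(active)) {
      VkPy <- Vk[[k]] %*% cr$Py
      grad[k] <- -0.5 * (sum(cr$P * Vk[[k]]) - sum(cr$Py * VkPy))
      svecs[[k]] <- VkPy
    }
    ai <- diag(1, np)   # frozen parameters: unit diagonal, zero gradient
    for (k in which(active)) {
      Psk <- cr$P %*% svecs[[k]]
      for (l in which(active)) if (l >= k)
        ai[k, l] <- ai[l, k] <- 0.5 * sum(svecs[[l]] * Psk)
    }
    list(ll = cr$ll, grad = grad, ai = ai)
  }
  em <- function(theta) {
    ## generic damped gradient fallback: scaled to the parameter magnitudes
    st <- tryCatch(stats(theta), error = function(e) NULL)
    if (is.null(st)) return(theta)
    sc <- pmax(abs(theta), 1e-6 * max(abs(theta)))
    theta + sc^2 * st$grad / nrec
  }
  list(loglik = loglik, stats = stats, em = em)
}

## ---------------------------------------------------------------------------
## BLUP solve at fixed variance components, with optional masking.
## Returns GEBVs for every individual in G and per-trait fixed effects.
gebv_solve <- function(theta, des, Gm, nt, masked) {
  mr <- theta_to_MR(theta, nt)
  keep <- lapply(seq_len(nt), function(t) !(des[[t]]$ind %in% masked))
  if (!any(unlist(keep))) stop("all individuals masked: no data to predict from")
  recs <- do.call(rbind, lapply(seq_len(nt), function(t)
    if (sum(keep[[t]]))
      data.frame(trait = t, ind = des[[t]]$ind[keep[[t]]],
                 y = des[[t]]$y[keep[[t]]])))
  nrec <- nrow(recs)
  pt <- vapply(des, function(d) ncol(d$X), 0L)
  p <- sum(pt); off <- c(0, cumsum(pt))
  X <- matrix(0, nrec, p)
  row0 <- 0
  for (t in seq_len(nt)) {
    nr <- sum(keep[[t]])
    if (nr) X[row0 + seq_len(nr), off[t] + seq_len(pt[t])] <-
        des[[t]]$X[keep[[t]], , drop = FALSE]
    row0 <- row0 + nr
  }
  Gpair <- Gm[recs$ind, recs$ind, drop = FALSE]
  same_ind <- outer(recs$ind, recs$ind, "==")
  V <- matrix(0, nrec, nrec)
  for (r in seq_len(nt)) for (c in seq_len(nt)) {
    sel <- outer(recs$trait == r, recs$trait == c)
    V <- V + mr$M[r, c] * (Gpair * sel)
    ## residual: per-record within a trait, per-individual across traits
    V <- V + mr$R[r, c] *
      (if (r == c) diag(as.numeric(recs$trait == r)) else same_ind * sel)
  }
  cV <- chol(V + diag(1e-10 * mean(diag(V)), nrec))
  Vinv <- chol2inv(cV)
  B <- crossprod(X, Vinv %*% X)
  bhat <- solve(B, crossprod(X, Vinv %*% recs$y))
  w <- Vinv %*% (recs$y - X %*% bhat)
  n_all <- nrow(Gm)
  u <- matrix(0, n_all, nt)
  for (t in seq_len(nt)) {
    wt <- as.vector(w) * mr$M[t, recs$trait]
    u[, t] <- Gm[, recs$ind, drop = FALSE] %*% wt
  }
  bl <- lapply(seq_len(nt), function(t) {
    b <- bhat[off[t] + seq_len(pt[t])]
    names(b) <- colnames(des[[t]]$X)
    b
  })
  list(u = u, bhat = bl)
}

#' Predict genomic breeding values, optionally masking individuals
#'
#' Re-solves the mixed-model (BLUP) equations at the fitted variance
#' components with the phenotypes of `masked_ids` removed (they stay in G),
#' the validation device of cross-validation. With no masking this returns
#' the fitted GEBVs.
#'
#' @param fit a `gblup_fit`
#' @param masked_ids character ids whose phenotype records are withheld
#' @return matrix of GEBVs (individuals in G x traits)
#' @export
predict_gebv <- function(fit, masked_ids = NULL) {
  stopifnot(inherits(fit, "gblup_fit"))
  if (is.null(masked_ids) || !length(masked_ids)) return(fit$gebv)
  des <- build_design(fit$spec, fit$pheno, fit$ids)
  masked <- match(as.character(masked_ids), fit$ids)
  masked <- masked[!is.na(masked)]
  out <- gebv_solve(fit$theta, des, fit$G, length(fit$spec$traits), masked)
  colnames(out$u) <- fit$spec$traits
  rownames(out$u) <- fit$ids
  out$u
}

#' @export
predict.gblup_fit <- function(object, masked_ids = NULL, ...)
  predict_gebv(object, masked_ids)

#' Heritabilities and genetic/phenotypic correlations
#'
#' From variance components: `h2 = var_a / (var_a + var_e)` per trait; for
#' two traits additionally the genetic correlation
#' `rg = cov_a / (sd_a1 sd_a2)` and the phenotypic correlation
#' `rp = (cov_a + cov_e) / sqrt((var_a1 + var_e1)(var_a2 + var_e2))`.
#'
#' @param x a `gblup_fit`, or a named list/vector with elements `var_a`,
#'   `var_e` (length 1 or 2) and, for two traits, `cov_a` and `cov_e`
#' @return named list: `h2` (per trait), and for two traits `rg`, `rp`
#' @export
genetic_parameters <- function(x) {
  if (inherits(x, "gblup_fit")) {
    nt <- length(x$spec$traits)
    if (nt == 1L) x <- list(var_a = x$theta[["var_a"]], var_e = x$theta[["var_e"]])
    else x <- list(var_a = x$theta[c("var_a1", "var_a2")],
                   var_e = x$theta[c("var_e1", "var_e2")],
                   cov_a = x$theta[["cov_a"]], cov_e = x$theta[["cov_e"]])
  }
  var_a <- as.numeric(x$var_a); var_e <- as.numeric(x$var_e)
  tot <- var_a + var_e
  if (any(tot <= 0)) stop("zero total variance: parameters undefined")
  out <- list(h2 = var_a / tot)
  if (length(var_a) == 2L) {
    if (any(var_a <= 0)) stop("genetic correlation undefined with zero additive variance")
    out$rg <- x$cov_a / sqrt(prod(var_a))
    out$rp <- (x$cov_a + x$cov_e) / sqrt(prod(tot))
  }
  out
}

## ---------------------------------------------------------------------------
## S3 methods

#' @export
print.gblup_fit <- function(x, ...) {
  nt <- length(x$spec$traits)
  cat(sprintf("GBLUP fit (%d trait%s, %s REML path): %s after %d iterations\n",
              nt, if (nt > 1) "s" else "", x$method,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  est <- rbind(estimate = x$theta, se = x$se)
  print(round(est, 4))
  invisible(x)
}

#' @export
summary.gblup_fit <- function(object, ...) {
  gp <- genetic_parameters(object)
  structure(list(fit = object, gp = gp), class = "summary.gblup_fit")
}

#' @export
print.summary.gblup_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("h2: %s\n", paste(sprintf("%.3f", x$gp$h2), collapse = ", ")))
  if (!is.null(x$gp$rg))
    cat(sprintf("rg: %.3f   rp: %.3f\n", x$gp$rg, x$gp$rp))
  invisible(x)
}

#' @export
coef.gblup_fit <- function(object, ...) object$bhat

#' @export
logLik.gblup_fit <- function(object, ...) {
  structure(utils::tail(object$loglik, 1), df = length(object$theta),
            class = "logLik")
}
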