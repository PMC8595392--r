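## Synthetic populations, traits and shallow sequencing reads.
##
## The generative model mirrors the assumptions of the downstream analysis:
## every individual's two chromosomes are mosaics of a small panel of founder
## haplotypes (switching founder between adjacent sites with a fixed
## probability), traits are additive with optional fixed effects, and reads
## are per-site Poisson with symmetric base-calling error.

#' Simulate a founder-mosaic population
#'
#' Draws `K` founder haplotypes over `n_sites` biallelic sites, then builds
#' `n_ind` diploid individuals whose two haplotypes are mosaics of the founder
#' rows: each haplotype starts from a uniformly chosen founder and, between
#' adjacent sites, re-draws its founder uniformly with probability
#' `switch_rate` (the destination may equal the source). Low `switch_rate`
#' with few founders yields the strong local linkage disequilibrium on which
#' reference-free imputation relies.
#'
#' Founder alleles are sampled per site with target alternate-allele
#' frequencies given by `freq_spec`; optional along-genome correlation is
#' imposed by copying the previous allele with probability `ld_copy`.
#'
#' @param K number of founder haplotypes (>= 2)
#' @param n_sites number of biallelic sites
#' @param n_ind number of diploid individuals
#' @param freq_spec either a length-2 numeric range from which per-site
#'   alternate-allele frequencies are drawn uniformly, or a numeric vector of
#'   length `n_sites` of frequencies; all values must lie in (0, 0.5]
#' @param switch_rate per-interval probability that a haplotype re-draws its
#'   founder, in `[0, 1)`
#' @param ld_copy probability that a founder allele copies the previous site's
#'   allele instead of being drawn fresh (within-founder LD), in `[0, 1)`
#' @param seed RNG seed
#' @return a list with components `panel` (class `founder_panel`: `K`,
#'   `n_sites`, `haplotypes` K x n_sites 0/1 matrix, `site_freqs`) and
#'   `truth` (class `true_genotypes`: `genotypes` n_ind x n_sites matrix with
#'   entries 0/1/2, and `mosaic_paths`, a list of two n_ind x n_sites founder
#'   index matrices, one per haplotype)
#' @export
simulate_population <- function(K = 8, n_sites = 200, n_ind = 400,
                                freq_spec = c(0.05, 0.5),
                                switch_rate = 0.002, ld_copy = 0.3,
                                seed = 1) {
  K <- check_count(K, "K", min = 2L)
  n_sites <- check_count(n_sites, "n_sites", min = 1L)
  n_ind <- check_count(n_ind, "n_ind", min = 1L)
  check_scalar(switch_rate, "switch_rate", 0, 1, upper_open = TRUE)
  check_scalar(ld_copy, "ld_copy", 0, 1, upper_open = TRUE)
  with_seed(seed, {
    if (length(freq_spec) == 2L && n_sites != 2L) {
      check_scalar(freq_spec[1], "freq_spec[1]", 0, 0.5, lower_open = TRUE)
      check_scalar(freq_spec[2], "freq_spec[2]", freq_spec[1], 0.5)
      site_freqs <- stats::runif(n_sites, freq_spec[1], freq_spec[2])
    } else {
      if (length(freq_spec) != n_sites)
        stop("'freq_spec' must be a range of length 2 or per-site frequencies of length n_sites")
      if (any(freq_spec <= 0) || any(freq_spec > 0.5))
        stop("per-site frequencies must lie in (0, 0.5]")
      site_freqs <- as.numeric(freq_spec)
    }

    hap <- matrix(0L, K, n_sites)
    hap[, 1] <- stats::rbinom(K, 1L, site_freqs[1])
    if (n_sites > 1L) for (j in 2:n_sites) {
      copy <- stats::runif(K) < ld_copy
      fresh <- stats::rbinom(K, 1L, site_freqs[j])
      hap[, j] <- ifelse(copy, hap[, j - 1L], fresh)
    }

    paths <- lapply(1:2, function(h) {
      p <- matrix(0L, n_ind, n_sites)
      p[, 1] <- sample.int(K, n_ind, replace = TRUE)
      if (n_sites > 1L) for (j in 2:n_sites) {
        sw <- stats::runif(n_ind) < switch_rate
        p[, j] <- ifelse(sw, sample.int(K, n_ind, replace = TRUE), p[, j - 1L])
      }
      p
    })

    geno <- matrix(0L, n_ind, n_sites)
    for (h in 1:2) {
      idx <- cbind(as.vector(paths[[h]]),
                   rep(1:n_sites, each = n_ind))
      geno <- geno + matrix(hap[idx], n_ind, n_sites)
    }
    ids <- sprintf("ind%04d", seq_len(n_ind))
    rownames(geno) <- ids
    panel <- structure(list(K = K, n_sites = n_sites, haplotypes = hap,
                            site_freqs = site_freqs),
                       class = "founder_panel")
    truth <- structure(list(genotypes = geno, mosaic_paths = paths, ids = ids),
                       class = "true_genotypes")
    list(panel = panel, truth = truth)
  })
}

#' Trait architecture parameters
#'
#' Container for the additive (co)variance targets and fixed-effect layout
#' used by [simulate_phenotypes()]. For two traits the genetic and residual
#' 2x2 (co)variance matrices must be positive definite.
#'
#' @param var_a additive genetic variance per trait (length 1 or 2)
#' @param var_e residual variance per trait (length 1 or 2)
#' @param cov_a additive covariance between the two traits (ignored for one)
#' @param cov_e residual covariance between the two traits
#' @param n_qtl number of causal sites
#' @param sex_levels,ys_levels numbers of sex and year-season classes (0 for
#'   no such fixed effect)
#' @param age_slope slope of the age covariate on the second trait (trait
#'   units per day); `NULL` for no age effect
#' @param effect_sd magnitude of the simulated fixed-effect contrasts,
#'   expressed in residual standard deviations
#' @return an object of class `trait_params`
#' @export
trait_params <- function(var_a, var_e, cov_a = 0, cov_e = 0, n_qtl = 100,
                         sex_levels = 2, ys_levels = 4, age_slope = NULL,
                         effect_sd = 0.5) {
  n_traits <- length(var_a)
  if (!n_traits %in% 1:2 || length(var_e) != n_traits)
    stop("var_a and var_e must both have length 1 or 2")
  if (n_traits == 2L) {
    M <- matrix(c(var_a[1], cov_a, cov_a, var_a[2]), 2)
    R <- matrix(c(var_e[1], cov_e, cov_e, var_e[2]), 2)
    if (!is_pd2(M) || !is_pd2(R))
      stop("genetic and residual (co)variance matrices must be positive definite")
  } else {
    if (var_a[1] < 0 || var_e[1] <= 0) stop("variances must be non-negative (var_e > 0)")
  }
  structure(list(n_traits = n_traits, var_a = var_a, var_e = var_e,
                 cov_a = cov_a, cov_e = cov_e, n_qtl = n_qtl,
                 sex_levels = sex_levels, ys_levels = ys_levels,
                 age_slope = age_slope, effect_sd = effect_sd),
            class = "trait_params")
}

#' Simulate phenotypes with additive genetics and fixed effects
#'
#' Samples `n_qtl` causal sites from the segregating sites, draws correlated
#' QTL effects, and calibrates the resulting breeding values in-sample so the
#' realized additive variance of each trait equals `var_a` exactly and (for
#' two traits) the realized genetic correlation equals the target exactly.
#' Residuals are drawn with the requested residual (co)variance; fixed
#' effects (sex, year-season, age covariate for the second trait) are added
#' with contrasts of about `effect_sd` residual SDs.
#'
#' @param truth a `true_genotypes` object from [simulate_population()]
#' @param params a [trait_params()] object
#' @param seed RNG seed
#' @return a `data.frame` in long format with columns `id`, `trait` (factor
#'   `t1`/`t2`), `value`, `sex`, `year_season`, `age` (NA where the trait has
#'   no age covariate), and `tbv` (true breeding value, simulation truth)
#' @export
simulate_phenotypes <- function(truth, params, seed = 1) {
  stopifnot(inherits(truth, "true_genotypes"), inherits(params, "trait_params"))
  geno <- truth$genotypes
  n <- nrow(geno); m <- ncol(geno)
  if (params$n_qtl > m) stop("n_qtl exceeds the number of sites")
  with_seed(seed, {
    seg <- which(col_pvar(geno) > 0)
    if (length(seg) < params$n_qtl)
      stop("not enough segregating sites for the requested n_qtl")
    qtl <- sort(sample(seg, params$n_qtl))
    W <- scale(geno[, qtl, drop = FALSE], center = TRUE, scale = FALSE)

    nt <- params$n_traits
    ## raw genetic scores, one per trait, from independent effect draws
    g_raw <- W %*% matrix(stats::rnorm(params$n_qtl * nt), params$n_qtl, nt)
    std <- function(v) {
      s <- stats::sd(v)
      if (s == 0) stop("degenerate genetic score (all QTL monomorphic?)")
      (v - mean(v)) / s
    }
    u <- matrix(0, n, nt)
    if (params$var_a[1] > 0) {
      z1 <- std(g_raw[, 1])
      u[, 1] <- z1 * sqrt(params$var_a[1])
      if (nt == 2L) {
        ## exact in-sample genetic correlation: orthogonalize the second
        ## score against the first, then recombine at the target correlation
        r <- params$cov_a / sqrt(params$var_a[1] * params$var_a[2])
        z2r <- std(stats::resid(stats::lm(g_raw[, 2] ~ z1)))
        z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * z2r
        u[, 2] <- z2 * sqrt(params$var_a[2])
      }
    }

    ## residuals with target (co)variance
    if (nt == 2L) {
      R <- matrix(c(params$var_e[1], params$cov_e, params$cov_e,
                    params$var_e[2]), 2)
      e <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(R)
    } else {
      e <- matrix(stats::rnorm(n, sd = sqrt(params$var_e[1])), n, 1)
    }

    ## fixed-effect covariates shared across traits
    sex <- if (params$sex_levels > 0)
      factor(sample(paste0("s", seq_len(params$sex_levels)), n, replace = TRUE))
    else factor(rep("s1", n))
    ys <- if (params$ys_levels > 0)
      factor(sample(paste0("ys", seq_len(params$ys_levels)), n, replace = TRUE))
    else factor(rep("ys1", n))
    age <- stats::rnorm(n, 180, 15)

    out <- vector("list", nt)
    for (t in seq_len(nt)) {
      sde <- sqrt(params$var_e[t])
      b_sex <- (as.integer(sex) - 1) * params$effect_sd * sde
      b_ys <- (as.integer(ys) - 1) * params$effect_sd * sde / 2
      fx <- b_sex + b_ys
      has_age <- t == 2L && !is.null(params$age_slope)
      if (has_age) fx <- fx + params$age_slope * (age - mean(age))
      out[[t]] <- data.frame(
        id = truth$ids, trait = paste0("t", t),
        value = fx + u[, t] + e[, t],
        sex = sex, year_season = ys,
        age = if (has_age) age else NA_real_,
        tbv = u[, t], stringsAsFactors = FALSE)
    }
    ph <- do.call(rbind, out)
    ph$trait <- factor(ph$trait, levels = paste0("t", seq_len(nt)))
    attr(ph, "qtl") <- qtl
    ph
  })
}

#' Simulate low-coverage sequencing read counts
#'
#' Per individual and site the total read count is Poisson(`mean_depth`);
#' each read reports the alternate allele with probability
#' `g/2 * (1 - error_rate) + (1 - g/2) * error_rate` for true genotype `g`.
#'
#' @param truth a `true_genotypes` object (or a plain 0/1/2 genotype matrix)
#' @param mean_depth mean reads per site per individual (> 0)
#' @param error_rate per-base error probability in (0, 0.5)
#' @param seed RNG seed
#' @return an object of class `read_counts`: list with integer matrices
#'   `ref` and `alt`, plus `error_rate` and `mean_depth`
#' @export
simulate_reads <- function(truth, mean_depth = 1, error_rate = 0.01, seed = 1) {
  geno <- if (inherits(truth, "true_genotypes")) truth$genotypes else truth
  check_scalar(mean_depth, "mean_depth", 0, Inf, lower_open = TRUE)
  check_scalar(error_rate, "error_rate", 0, 0.5, lower_open = TRUE, upper_open = TRUE)
  with_seed(seed, {
    n <- nrow(geno); m <- ncol(geno)
    tot <- matrix(stats::rpois(n * m, mean_depth), n, m)
    p_alt <- geno / 2 * (1 - error_rate) + (1 - geno / 2) * error_rate
    alt <- matrix(stats::rbinom(n * m, as.vector(tot), as.vector(p_alt)), n, m)
    structure(list(ref = tot - alt, alt = alt,
                   error_rate = error_rate, mean_depth = mean_depth,
                   ids = rownames(geno)),
              class = "read_counts")
  })
}

#' Thin read counts to a lower target depth
#'
#' Retains each read independently with probability
#' `target_depth / mean_depth` (binomial thinning), emulating random read
#' downsampling of sequence data to a shallower depth.
#'
#' @param reads a `read_counts` object
#' @param target_depth desired mean depth, `<=` the current `mean_depth`
#' @param seed RNG seed
#' @return a `read_counts` object at the new depth
#' @export
downsample_reads <- function(reads, target_depth, seed = 1) {
  stopifnot(inherits(reads, "read_counts"))
  check_scalar(target_depth, "target_depth", 0, reads$mean_depth,
               lower_open = TRUE)
  p <- target_depth / reads$mean_depth
  with_seed(seed, {
    thin <- function(m) {
      out <- m
      out[] <- stats::rbinom(length(m), as.vector(m), p)
      out
    }
    structure(list(ref = thin(reads$ref), alt = thin(reads$alt),
                   error_rate = reads$error_rate, mean_depth = target_depth,
                   ids = reads$ids),
              class = "read_counts")
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("Founder panel: %d haplotypes x %d sites (mean target freq %.3f)\n",
              x$K, x$n_sites, mean(x$site_freqs)))
  invisible(x)
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("Read counts: %d individuals x %d sites, mean depth %.3g, error %.3g\n",
              nrow(x$ref), ncol(x$ref), mean(x$ref + x$alt), x$error_rate))
  invisible(x)
}
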