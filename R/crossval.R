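## k-fold cross-validation of genomic prediction: corrected phenotypes,
## per-fold accuracy r(y_c, GEBV) and dispersion bias 1 - slope(y_c on GEBV).

#' Random fold assignment
#'
#' Partitions `ids` into `n_folds` folds of near-equal size (sizes differ by
#' at most one), uniformly at random given the seed.
#'
#' @param ids character vector of phenotyped individuals
#' @param n_folds number of folds (default 12)
#' @param seed RNG seed
#' @return an object of class `fold_plan`: data.frame (`id`, `fold`) plus
#'   attributes `n_folds` and `seed`
#' @export
make_folds <- function(ids, n_folds = 12, seed = 1) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  ids <- unique(as.character(ids))
  if (n_folds > length(ids)) stop("more folds than individuals")
  with_seed(seed, {
    perm <- sample(ids)
    fold <- rep(seq_len(n_folds), length.out = length(ids))
    plan <- data.frame(id = perm, fold = sort(fold))
    plan <- plan[order(match(plan$id, ids)), ]
    rownames(plan) <- NULL
    structure(plan, n_folds = n_folds, seed = seed, class = c("fold_plan", "data.frame"))
  })
}

#' Phenotypes corrected for fixed effects via pedigree BLUP
#'
#' Fits the same mixed model as the genomic analysis but with the
#' pedigree-based (or identity) relationship matrix `A` in place of G,
#' extracts the fixed-effect solutions, and returns
#' `y_c = y - x' b_hat` per record. Random effects are not subtracted.
#'
#' @param spec a [model_spec()]
#' @param pheno long phenotype table
#' @param A a `grm` object (source `"pedigree"` typically) or matrix with id
#'   dimnames covering every phenotyped individual; identity corresponds to
#'   an unrelated base population
#' @param ... passed to [reml_fit()]
#' @return data.frame `id`, `trait`, `yc`
#' @export
corrected_phenotypes <- function(spec, pheno, A, ...) {
  Am <- if (inherits(A, "grm")) A$G else A
  ids <- rownames(Am)
  ph_ids <- unique(as.character(pheno$id[!is.na(pheno$value)]))
  miss <- setdiff(ph_ids, ids)
  if (length(miss))
    stop("individuals missing from the pedigree relationship matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  fit <- reml_fit(spec, pheno, Am, ...)
  des <- build_design(spec, fit$pheno, ids)
  out <- vector("list", length(spec$traits))
  for (t in seq_along(spec$traits)) {
    b <- fit$bhat[[t]]
    yc <- des[[t]]$y - as.vector(des[[t]]$X %*% b)
    out[[t]] <- data.frame(id = ids[des[[t]]$ind], trait = spec$traits[t],
                           yc = yc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Prediction accuracy and dispersion bias for one validation set
#'
#' Accuracy is the Pearson correlation between corrected phenotypes and
#' GEBVs; the slope is the least-squares regression coefficient of `yc` on
#' `gebv`; bias is `1 - slope` (0 for dispersion-perfect prediction, with a
#' slope below 1 flagging over-dispersed GEBVs).
#'
#' @param yc corrected phenotypes
#' @param gebv predicted breeding values, same length
#' @return list with `accuracy`, `slope`, `bias` (all `NA` when the GEBVs
#'   are constant)
#' @export
prediction_metrics <- function(yc, gebv) {
  if (length(yc) != length(gebv)) stop("length mismatch")
  if (stats::sd(gebv) == 0 || stats::sd(yc) == 0)
    return(list(accuracy = NA_real_, slope = NA_real_, bias = NA_real_))
  slope <- stats::cov(yc, gebv) / stats::var(gebv)
  list(accuracy = stats::cor(yc, gebv), slope = slope, bias = 1 - slope)
}

#' Cross-validated prediction accuracy and bias
#'
#' For each fold, withholds the phenotypes of the fold's individuals (both
#' traits jointly for a two-trait model), predicts their GEBVs at the
#' full-data variance components (or re-estimated per training fold), and
#' scores on the validation set: accuracy = Pearson `r(y_c, GEBV)` and
#' slope = least-squares regression coefficient of `y_c` on GEBV; bias is
#' reported as `1 - slope` (1 would be a slope-perfect prediction).
#'
#' @param folds a [make_folds()] plan
#' @param fit a full-data `gblup_fit` (supplies model, data, G and the
#'   variance components reused across folds)
#' @param yc corrected phenotypes from [corrected_phenotypes()]
#' @param reestimate re-fit variance components within each training fold
#'   (default FALSE: components reused from `fit`)
#' @param pooled also compute accuracy/slope on the pooled validation
#'   predictions across folds
#' @return an object of class `cv_report`: `per_fold` data.frame (fold,
#'   trait, n, accuracy, slope, bias), `summary` (per trait: mean and
#'   empirical SE over folds), optionally `pooled`
#' @export
cv_evaluate <- function(folds, fit, yc, reestimate = FALSE, pooled = FALSE) {
  stopifnot(inherits(folds, "fold_plan"), inherits(fit, "gblup_fit"))
  traits <- fit$spec$traits
  nf <- attr(folds, "n_folds")
  rows <- list()
  pool <- list()
  for (f in seq_len(nf)) {
    val_ids <- folds$id[folds$fold == f]
    use_fit <- fit
    if (reestimate) {
      train_ph <- fit$pheno[!(as.character(fit$pheno$id) %in% val_ids), , drop = FALSE]
      use_fit <- reml_fit(fit$spec, train_ph, fit$G)
    }
    u <- predict_gebv(use_fit, masked_ids = val_ids)
    for (t in traits) {
      yct <- yc[yc$trait == t & yc$id %in% val_ids, ]
      uv <- u[match(yct$id, rownames(u)), t]
      pm <- prediction_metrics(yct$yc, uv)
      if (is.na(pm$accuracy)) {
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, trait = t, n = nrow(yct), accuracy = NA_real_,
          slope = NA_real_, bias = NA_real_, flag = "constant GEBV")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, trait = t, n = nrow(yct), accuracy = pm$accuracy,
        slope = pm$slope, bias = pm$bias, flag = "")
      pool[[length(pool) + 1L]] <- data.frame(trait = t, yc = yct$yc, u = uv)
    }
  }
  per_fold <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(traits, function(t) {
    d <- per_fold[per_fold$trait == t & per_fold$flag == "", ]
    data.frame(trait = t,
               accuracy = mean(d$accuracy), accuracy_se = stats::sd(d$accuracy) / sqrt(nrow(d)),
               bias = mean(d$bias), bias_se = stats::sd(d$bias) / sqrt(nrow(d)))
  }))
  out <- list(per_fold = per_fold, summary = summ,
              n_folds = nf, seed = attr(folds, "seed"))
  if (pooled) {
    pl <- do.call(rbind, pool)
    out$pooled <- do.call(rbind, lapply(traits, function(t) {
      d <- pl[pl$trait == t, ]
      data.frame(trait = t, accuracy = stats::cor(d$yc, d$u),
                 slope = stats::cov(d$yc, d$u) / stats::var(d$u))
    }))
  }
  structure(out, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %s)\n", x$n_folds, x$seed))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a CV report as CSV
#'
#' Per-fold rows plus one summary row per trait; the root seed is recorded
#' in a comment header line.
#' @param report a `cv_report`
#' @param path output path
#' @export
write_cv_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_folds=%d seed=%s", report$n_folds, report$seed), con)
  tab <- report$per_fold[, c("fold", "trait", "accuracy", "slope", "bias")]
  summ <- data.frame(fold = "mean", trait = report$summary$trait,
                     accuracy = report$summary$accuracy,
                     slope = 1 - report$summary$bias,
                     bias = report$summary$bias)
  tab$fold <- as.character(tab$fold)
  utils::write.csv(rbind(tab, summ), con, row.names = FALSE)
  invisible(path)
}
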