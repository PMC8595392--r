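## Imputation accuracy: genotypic concordance, dosage r2, MAF stratification.

#' Genotypic concordance
#'
#' Proportion of hard-called genotypes equal to the true genotypes, over all
#' (optionally masked) entries.
#'
#' @param hard_calls integer matrix of calls in {0,1,2}
#' @param truth integer matrix of true genotypes, same shape
#' @param mask optional logical matrix; only `TRUE` entries are scored
#' @return a single proportion in `[0, 1]`
#' @export
genotypic_concordance <- function(hard_calls, truth, mask = NULL) {
  if (!all(dim(hard_calls) == dim(truth)))
    stop("shape mismatch between calls and truth")
  ok <- hard_calls == truth
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(truth))) stop("mask shape mismatch")
    if (!any(mask)) stop("no scored entries: concordance undefined")
    return(sum(ok[mask]) / sum(mask))
  }
  mean(ok)
}

#' Per-site dosage r-squared
#'
#' Squared Pearson correlation between expected dosages and true genotypes,
#' computed per site across individuals and averaged (unweighted) over sites
#' where the correlation is defined. Sites where either vector is constant
#' are excluded and counted.
#'
#' @param dosages numeric matrix in `[0, 2]`
#' @param truth integer matrix of true genotypes, same shape
#' @return the mean per-site r2, with attributes `n_used` and `n_excluded`
#' @export
dosage_r2 <- function(dosages, truth) {
  if (!all(dim(dosages) == dim(truth)))
    stop("shape mismatch between dosages and truth")
  r2 <- per_site_r2(dosages, truth)
  used <- !is.na(r2)
  if (!any(used)) stop("no site with defined correlation: dosage r2 undefined")
  structure(mean(r2[used]), n_used = sum(used), n_excluded = sum(!used))
}

per_site_r2 <- function(dosages, truth) {
  vd <- col_pvar(dosages); vt <- col_pvar(truth)
  cd <- colMeans(dosages * truth) - colMeans(dosages) * colMeans(truth)
  r2 <- rep(NA_real_, ncol(truth))
  ok <- vd > 0 & vt > 0
  r2[ok] <- (cd[ok]^2) / (vd[ok] * vt[ok])
  r2
}

## the 15 MAF bin edges used throughout; half-open on the left
maf_bin_edges <- function() {
  c(0, 0.001, 0.002, 0.005, 0.01, 0.02, 0.05,
    0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5)
}

#' MAF-stratified imputation accuracy
#'
#' Assigns each site to one of 15 minor-allele-frequency bins
#' (edges 0.001, 0.002, 0.005, 0.01, 0.02, 0.05, then steps of 0.05 up to
#' 0.5; intervals half-open on the left, closed on the right) using
#' MAF = min(p, 1 - p) of the truth alternate-allele frequency, and reports
#' per-bin mean concordance and dosage r2 plus the pooled summary.
#'
#' @param post a `posterior_genotypes` object
#' @param truth integer matrix of true genotypes
#' @param freqs optional per-site alternate-allele frequencies; defaults to
#'   the truth allele frequencies
#' @return an object of class `accuracy_report`: list with `overall`
#'   (concordance, dosage_r2, n_sites_scored) and `by_bin`, a data.frame
#'   with columns bin_low, bin_high, n_sites, concordance, dosage_r2
#' @export
maf_stratified_accuracy <- function(post, truth, freqs = NULL) {
  stopifnot(inherits(post, "posterior_genotypes"))
  if (is.null(freqs)) freqs <- colMeans(truth) / 2
  ## snap to 10 decimals so 1 - 0.7 lands exactly on the 0.3 bin edge
  maf <- round(pmin(freqs, 1 - freqs), 10)
  edges <- maf_bin_edges()
  bin <- findInterval(maf, edges, left.open = TRUE, rightmost.closed = FALSE)
  bin[maf <= 0] <- NA  # monomorphic in truth: no MAF bin
  r2 <- per_site_r2(post$dosage, truth)
  conc_site <- colMeans(post$hard == truth)
  nb <- length(edges) - 1L
  by_bin <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                       n_sites = 0L, concordance = NA_real_,
                       dosage_r2 = NA_real_)
  for (b in seq_len(nb)) {
    idx <- which(!is.na(bin) & bin == b)
    by_bin$n_sites[b] <- length(idx)
    if (length(idx)) {
      by_bin$concordance[b] <- mean(conc_site[idx])
      r2b <- r2[idx]
      if (any(!is.na(r2b))) by_bin$dosage_r2[b] <- mean(r2b, na.rm = TRUE)
    }
  }
  overall <- list(concordance = genotypic_concordance(post$hard, truth),
                  dosage_r2 = as.numeric(dosage_r2(post$dosage, truth)),
                  n_sites_scored = ncol(truth))
  structure(list(overall = overall, by_bin = by_bin),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Imputation accuracy over %d sites: concordance %.4f, dosage r2 %.4f\n",
              x$overall$n_sites_scored, x$overall$concordance,
              x$overall$dosage_r2))
  pop <- x$by_bin[x$by_bin$n_sites > 0, ]
  if (nrow(pop)) print(pop, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an accuracy report to CSV
#'
#' Emits the per-bin table with a trailing `overall` row.
#' @param report an `accuracy_report`
#' @param path output CSV path
#' @export
write_accuracy_report <- function(report, path) {
  tab <- report$by_bin
  tab <- rbind(tab, data.frame(bin_low = NA, bin_high = NA,
                               n_sites = report$overall$n_sites_scored,
                               concordance = report$overall$concordance,
                               dosage_r2 = report$overall$dosage_r2))
  tab$scope <- c(rep("bin", nrow(tab) - 1L), "overall")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
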