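## File formats: VCF genotype sources, phenotype/pedigree CSV, truth tables.

#' Read a genotype field from a VCF
#'
#' Extracts one of GT (hard genotypes), DS (expected dosages), GL or PL
#' (genotype likelihoods) from a biallelic-SNP VCF. GT is recoded as the
#' count of alternate alleles; GL is de-logged (10^GL) and PL converted via
#' 10^(-PL/10); both likelihood encodings return a `lik_tensor`.
#'
#' @param path VCF path (plain text or bgzipped)
#' @param field one of "GT", "DS", "GL", "PL"
#' @return for GT/DS an individuals x sites numeric matrix (sample ids as
#'   rownames, `CHROM:POS` as colnames); for GL/PL a `lik_tensor`
#' @export
read_genotype_source <- function(path, field = c("GT", "DS", "GL", "PL")) {
  field <- match.arg(field)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  site_ids <- paste(v@fix[, "CHROM"], v@fix[, "POS"], sep = ":")
  raw <- tryCatch(vcfR::extract.gt(v, element = field),
                  error = function(e) NULL)
  if (is.null(raw) || all(is.na(raw)))
    stop(sprintf("field %s absent from %s (first record: %s)", field, path,
                 site_ids[1]))
  m <- nrow(raw); n <- ncol(raw)   # vcfR: rows = variants, cols = samples
  if (field == "GT") {
    cnt <- (substr(raw, 1, 1) == "1") + (substr(raw, 3, 3) == "1")
    out <- t(matrix(as.integer(cnt), m, n))
    dimnames(out) <- list(colnames(raw), site_ids)
    return(out)
  }
  if (field == "DS") {
    out <- t(matrix(as.numeric(raw), m, n))
    dimnames(out) <- list(colnames(raw), site_ids)
    return(out)
  }
  ## GL / PL: three comma-separated values per entry
  L <- array(NA_real_, c(n, m, 3))
  sp <- strsplit(as.vector(raw), ",")
  vals <- vapply(sp, function(x) as.numeric(x[1:3]), numeric(3))
  for (g in 1:3) {
    mt <- matrix(vals[g, ], m, n)  # sites x samples
    L[, , g] <- t(if (field == "GL") 10^mt else 10^(-mt / 10))
  }
  mx <- pmax(matrix(L[, , 1], n, m), matrix(L[, , 2], n, m),
             matrix(L[, , 3], n, m))
  for (g in 1:3) L[, , g] <- matrix(L[, , g], n, m) / mx
  structure(L, class = "lik_tensor", ids = colnames(raw))
}

## minimal VCF writer used for simulated truth and imputation output
write_vcf_lines <- function(path, ids, n_sites, format, geno_fields) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
               "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior probabilities\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(n_sites)) {
    fields <- geno_fields(j)
    writeLines(paste(c("1", j, paste0("site", j), "A", "G", ".", "PASS", ".",
                       format, fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write true genotypes to VCF (GT field)
#'
#' Sites are placed at 1-based positions equal to their column index on a
#' single synthetic contig.
#' @param truth a `true_genotypes` object or 0/1/2 matrix with rownames
#' @param path output VCF path
#' @export
write_truth_vcf <- function(truth, path) {
  g <- if (inherits(truth, "true_genotypes")) truth$genotypes else truth
  gt_str <- c("0/0", "0/1", "1/1")
  write_vcf_lines(path, rownames(g), ncol(g), "GT",
                  function(j) gt_str[g[, j] + 1L])
}

#' Write imputed posteriors to VCF (GT, DS, GP fields)
#'
#' DS is the expected dosage to 3 decimals; GT the hard call; GP the
#' posterior triplet.
#' @param post a `posterior_genotypes` object
#' @param path output VCF path
#' @export
write_posteriors_vcf <- function(post, path) {
  stopifnot(inherits(post, "posterior_genotypes"))
  gt_str <- c("0/0", "0/1", "1/1")
  ids <- if (!is.null(post$ids)) post$ids else
    sprintf("ind%04d", seq_len(nrow(post$dosage)))
  write_vcf_lines(path, ids, ncol(post$dosage), "GT:DS:GP", function(j) {
    sprintf("%s:%.3f:%.4g,%.4g,%.4g",
            gt_str[post$hard[, j] + 1L], post$dosage[, j],
            post$prob[, j, 1], post$prob[, j, 2], post$prob[, j, 3])
  })
}

#' Write a phenotype table to CSV
#'
#' Columns id, trait, value, sex, year_season, age.
#' @param pheno long phenotype data.frame
#' @param path output path
#' @export
write_phenotypes <- function(pheno, path) {
  keep <- intersect(c("id", "trait", "value", "sex", "year_season", "age"),
                    names(pheno))
  utils::write.csv(pheno[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#' @param path CSV path
#' @return data.frame with factor trait/sex/year_season columns
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("trait", "sex", "year_season"), names(ph)))
    ph[[col]] <- factor(ph[[col]])
  ph
}

#' Read a 3-column pedigree CSV (id, sire, dam; 0/empty = unknown)
#' @param path CSV path
#' @return data.frame ready for [pedigree_a_matrix()]
#' @export
read_pedigree <- function(path) {
  utils::read.csv(path, colClasses = "character")
}

#' Write a simulation truth table (breeding values and mosaic paths)
#'
#' Tab-delimited sidecar with one row per individual: id, per-trait true
#' breeding values (if phenotypes supplied), and the two mosaic founder
#' paths as comma-separated founder indices.
#' @param truth a `true_genotypes` object
#' @param path output path
#' @param pheno optional phenotype table carrying `tbv`
#' @export
write_truth_table <- function(truth, path, pheno = NULL) {
  stopifnot(inherits(truth, "true_genotypes"))
  tab <- data.frame(id = truth$ids)
  if (!is.null(pheno) && "tbv" %in% names(pheno)) {
    for (t in levels(factor(pheno$trait))) {
      sub <- pheno[pheno$trait == t, ]
      tab[[paste0("tbv_", t)]] <- sub$tbv[match(tab$id, sub$id)]
    }
  }
  tab$hap1_path <- apply(truth$mosaic_paths[[1]], 1, paste, collapse = ",")
  tab$hap2_path <- apply(truth$mosaic_paths[[2]], 1, paste, collapse = ",")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
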