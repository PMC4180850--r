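#' QC thresholds
#'
#' Defaults follow the standard 50k-chip cascade: per-call confidence 0.6,
#' SNP call rate 95%, per-SNP heterozygosity within 3 SD of the panel mean,
#' minor allele frequency 0.01, sex chromosomes dropped, Hardy-Weinberg
#' chi-square p below 1e-15, and duplicate-sample genotype correlation 0.99.
#'
#' @param call_rate Minimum SNP call rate (SNPs *below* this are removed).
#' @param confidence Per-call confidence threshold; calls with scores below
#'   it are set to missing before the call-rate filter.
#' @param het_sd Allowed deviation (in panel SDs) of per-SNP heterozygosity
#'   from the panel average.
#' @param maf Minimum minor allele frequency.
#' @param hwe_p Hardy-Weinberg p-value threshold (removal if p < `hwe_p`).
#' @param drop_chromosomes Chromosome labels to drop (sex chromosomes).
#' @param dup_corr Sample-duplicate correlation threshold (removal if >=).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(call_rate = 0.95, confidence = 0.6, het_sd = 3,
                          maf = 0.01, hwe_p = 1e-15,
                          drop_chromosomes = c("X", "Y"), dup_corr = 0.99) {
  list(call_rate = call_rate, confidence = confidence, het_sd = het_sd,
       maf = maf, hwe_p = hwe_p, drop_chromosomes = drop_chromosomes,
       dup_corr = dup_corr)
}

new_qc_report <- function(kind, n_in, steps, thresholds) {
  removed <- unlist(lapply(steps, `[[`, "removed"), use.names = FALSE)
  structure(list(kind = kind, n_in = n_in, n_out = n_in - length(removed),
                 steps = steps, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$kind, "): ", x$n_in, " in -> ", x$n_out, " out\n",
      sep = "")
  for (s in x$steps) {
    cat(sprintf("  %-12s removed %d\n", s$reason, length(s$removed)))
  }
  invisible(x)
}

#' Removed items of a QC report
#'
#' @param report A `qc_report`.
#' @param reason Optional filter on the removal reason.
#' @return Character vector of removed SNP/sample identifiers.
#' @export
qc_removed <- function(report, reason = NULL) {
  steps <- report$steps
  if (!is.null(reason)) steps <- Filter(function(s) s$reason %in% reason,
                                        steps)
  unlist(lapply(steps, `[[`, "removed"), use.names = FALSE)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(kind = report$kind, n_in = report$n_in, n_out = report$n_out,
         thresholds = report$thresholds,
         steps = lapply(report$steps, function(s)
           list(reason = s$reason, removed = s$removed))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the genotype counts
#' `(n0, n1, n2)` against Hardy-Weinberg expectations at the estimated
#' allele frequency.
#'
#' @param n0,n1,n2 Counts of the three genotype classes (second-allele
#'   dosage 0, 1, 2).
#' @return The p-value.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n <= 0) stop("zero genotype count")
  p <- (n1 + 2 * n2) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((c(n0, n1, n2) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

## per-SNP summaries on the current table
snp_call_rate <- function(geno) 1 - colMeans(is.na(geno))
snp_het <- function(geno) colMeans(geno == 1, na.rm = TRUE)
snp_freq <- function(geno) colMeans(geno, na.rm = TRUE) / 2

#' SNP quality-control cascade
#'
#' Applies, in this fixed order: (1) per-call confidence masking (calls with
#' score below the threshold become missing), (2) SNP call-rate filter,
#' (3) per-SNP heterozygosity filter (observed heterozygosity deviating more
#' than `het_sd` panel SDs from the panel average, panel statistics computed
#' on the SNPs that survived the call-rate step), (4) minor-allele-frequency
#' filter, (5) sex-chromosome drop, (6) Hardy-Weinberg chi-square filter.
#' A SNP is removed by the first filter that catches it; the report itemizes
#' every removal.
#'
#' @param table A [genotype_table()].
#' @param thresholds See [qc_thresholds()].
#' @param stratify_hwe_by Optional factor (one level per sample) to compute
#'   the HWE test within strata (e.g. breeds) and remove a SNP only if it
#'   fails in some stratum; the default pools all samples, which in mixed
#'   multi-breed panels inflates failures (Wahlund effect).
#' @return List with the filtered `table` and a `qc_report`.
#' @export
qc_snps <- function(table, thresholds = qc_thresholds(),
                    stratify_hwe_by = NULL) {
  if (ncol(table$geno) == 0L) stop("empty genotype table")
  geno <- table$geno
  steps <- list()

  ## 1. confidence masking (not a removal step by itself)
  n_masked <- 0L
  if (!is.null(table$conf)) {
    low <- !is.na(geno) & table$conf < thresholds$confidence
    n_masked <- sum(low)
    geno[low] <- NA
    table$geno <- geno
    table$conf[low] <- NA
  }
  steps[[length(steps) + 1L]] <- list(reason = "confidence_mask",
                                      removed = character(0),
                                      n_calls_masked = n_masked)

  keep <- rep(TRUE, ncol(geno))
  drop_step <- function(bad, reason) {
    ids <- colnames(geno)[keep & bad]
    keep[keep & bad] <<- FALSE
    steps[[length(steps) + 1L]] <<- list(reason = reason, removed = ids)
  }

  ## 2. call rate
  cr <- snp_call_rate(geno)
  drop_step(cr < thresholds$call_rate, "call_rate")

  ## 3. heterozygosity (panel statistics over surviving SNPs)
  het <- snp_het(geno)
  het_mean <- mean(het[keep])
  het_sdv <- stats::sd(het[keep])
  if (is.finite(het_sdv) && het_sdv > 0) {
    drop_step(abs(het - het_mean) > thresholds$het_sd * het_sdv, "het")
  } else {
    steps[[length(steps) + 1L]] <- list(reason = "het", removed = character(0))
  }

  ## 4. MAF
  p <- snp_freq(geno)
  maf <- pmin(p, 1 - p)
  drop_step(is.na(maf) | maf < thresholds$maf, "maf")

  ## 5. sex chromosomes
  drop_step(table$map$chr %in% thresholds$drop_chromosomes, "sex_chromosome")

  ## 6. HWE
  hwe_p_snp <- function(rows) {
    vapply(seq_len(ncol(geno)), function(j) {
      g <- geno[rows, j]
      n0 <- sum(g == 0, na.rm = TRUE)
      n1 <- sum(g == 1, na.rm = TRUE)
      n2 <- sum(g == 2, na.rm = TRUE)
      if (n0 + n1 + n2 == 0) return(NA_real_)
      hwe_test(n0, n1, n2)
    }, numeric(1))
  }
  if (is.null(stratify_hwe_by)) {
    pv <- hwe_p_snp(seq_len(nrow(geno)))
    bad_hwe <- !is.na(pv) & pv < thresholds$hwe_p
  } else {
    strata <- split(seq_len(nrow(geno)), stratify_hwe_by)
    bad_hwe <- Reduce(`|`, lapply(strata, function(rows) {
      pv <- hwe_p_snp(rows)
      !is.na(pv) & pv < thresholds$hwe_p
    }))
  }
  drop_step(bad_hwe, "hwe")

  if (!any(keep)) stop("empty panel: every SNP was removed by QC")
  report <- new_qc_report("snp", ncol(geno), steps, thresholds)
  list(table = subset_genotype_table(table, snps = which(keep)),
       report = report)
}

#' Duplicate-sample removal
#'
#' Computes pairwise Pearson correlations of the 0/1/2 genotype vectors over
#' jointly non-missing calls; for every pair at or above the threshold whose
#' earlier-indexed member is still present, the later-indexed sample is
#' removed (i.e. the first occurrence is kept).
#'
#' @param table A [genotype_table()].
#' @param dup_threshold Correlation threshold (default 0.99).
#' @return List with the filtered `table`, a `qc_report` and the matrix of
#'   flagged `pairs`.
#' @export
qc_samples <- function(table, dup_threshold = 0.99) {
  n <- nrow(table$geno)
  if (n < 2L) stop("need at least 2 samples")
  cc <- suppressWarnings(stats::cor(t(table$geno),
                                    use = "pairwise.complete.obs"))
  removed <- logical(n)
  pairs <- NULL
  for (i in seq_len(n - 1L)) {
    if (removed[i]) next
    for (j in seq.int(i + 1L, n)) {
      if (removed[j]) next
      if (!is.na(cc[i, j]) && cc[i, j] >= dup_threshold) {
        removed[j] <- TRUE
        pairs <- rbind(pairs, data.frame(kept = table$ids[i],
                                         removed = table$ids[j],
                                         correlation = cc[i, j]))
      }
    }
  }
  if (all(removed)) stop("all samples removed")
  steps <- list(list(reason = "duplicate", removed = table$ids[removed]))
  report <- new_qc_report("sample", n, steps,
                          list(dup_corr = dup_threshold))
  list(table = subset_genotype_table(table, samples = which(!removed)),
       report = report, pairs = pairs)
}

#' Mean imputation of missing genotypes
#'
#' Replaces each missing call with the SNP mean dosage `2 p-hat` computed
#' over the non-missing calls (optionally rounded to the nearest integer
#' genotype). This preserves allele frequencies and is adequate at the low
#' missingness remaining after QC; it deliberately ignores linkage
#' information.
#'
#' @param table A [genotype_table()].
#' @param round Logical; round imputed dosages to 0/1/2.
#' @return The table with no missing calls (dosages may be fractional).
#' @export
impute_missing <- function(table, round = FALSE) {
  geno <- table$geno
  miss <- is.na(geno)
  if (!any(miss)) return(table)
  mu <- 2 * snp_freq(geno)
  if (anyNA(mu)) {
    stop("SNP(s) with all calls missing: ",
         paste(colnames(geno)[is.na(mu)], collapse = ", "),
         " (should have been removed by qc_snps)")
  }
  fill <- matrix(mu, nrow(geno), ncol(geno), byrow = TRUE)
  if (round) fill <- round(fill)
  geno[miss] <- fill[miss]
  table$geno <- geno
  table
}

#' Trim phenotype outliers
#'
#' Removes records further than `k_sd` standard deviations from the mean of
#' all records; mean and SD are computed once on the full set (not
#' iterated).
#'
#' @param y Numeric vector of phenotypes (or a data.frame with column `y`).
#' @param k_sd Number of SDs (default 4); `Inf` removes nothing.
#' @return List with `kept` (the retained values or rows), `removed`
#'   (indices removed) and the `mean`/`sd` used.
#' @export
trim_phenotype_outliers <- function(y, k_sd = 4) {
  vals <- if (is.data.frame(y)) y$y else y
  if (length(vals) < 2L) stop("need at least 2 records")
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  if (!is.finite(sdv) || sdv == 0) {
    if (any(vals != mu)) warning("zero variance; no records removed")
    return(list(kept = y, removed = integer(0), mean = mu, sd = sdv))
  }
  out <- which(abs(vals - mu) > k_sd * sdv)
  kept <- if (is.data.frame(y)) y[setdiff(seq_along(vals), out), , drop = FALSE]
    else vals[setdiff(seq_along(vals), out)]
  list(kept = kept, removed = out, mean = mu, sd = sdv)
}
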