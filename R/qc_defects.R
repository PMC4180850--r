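#' Specification of planted QC defects
#'
#' Counts of SNP-level and sample-level defects to inject into a clean
#' genotype table. The defaults plant seven SNP violations covering all six
#' SNP filter types (two of them MAF: one monomorphic, one rare) plus one
#' near-duplicate sample.
#'
#' @param n_call_rate SNPs pushed below the call-rate threshold by missing
#'   calls.
#' @param n_low_conf SNPs whose confidence scores are lowered on enough calls
#'   that confidence masking pushes them below the call-rate threshold.
#' @param n_het SNPs with inflated heterozygosity (all calls heterozygous).
#' @param n_maf SNPs with minor allele frequency below 0.01; the first is
#'   made monomorphic, the rest carry three heterozygous calls.
#' @param n_sex SNPs relabelled to chromosome "X".
#' @param n_hwe SNPs replaced by a heterozygote-deficient genotype column at
#'   intermediate frequency, violating Hardy-Weinberg equilibrium beyond the
#'   filter threshold while keeping heterozygosity inside the panel band.
#' @param n_dup Near-duplicate sample pairs (one discordant call each).
#' @param n_discord Discordant calls per duplicate pair.
#' @return A named list.
#' @export
qc_defect_spec <- function(n_call_rate = 1L, n_low_conf = 1L, n_het = 1L,
                           n_maf = 2L, n_sex = 1L, n_hwe = 1L, n_dup = 1L,
                           n_discord = 1L) {
  list(n_call_rate = n_call_rate, n_low_conf = n_low_conf, n_het = n_het,
       n_maf = n_maf, n_sex = n_sex, n_hwe = n_hwe, n_dup = n_dup,
       n_discord = n_discord)
}

#' Plant QC defects into a clean genotype table
#'
#' Injects, at recorded loci and samples, the defects described by
#' `defect_spec` and returns the modified table together with a ground-truth
#' ledger naming every planted defect. Running [qc_snps()] and
#' [qc_samples()] at default thresholds on the result removes exactly the
#' ledger entries (provided the input table itself is clean).
#'
#' @param genotypes A clean [genotype_table()].
#' @param defect_spec See [qc_defect_spec()]. An all-zero spec returns the
#'   table unchanged.
#' @param seed Optional integer seed.
#' @param thresholds The [qc_thresholds()] the defects are designed to
#'   violate.
#' @return List with `table` (defective) and `ledger` (data.frame with
#'   columns `kind` ("snp"/"sample"), `id`, `defect`).
#' @export
plant_qc_defects <- function(genotypes, defect_spec = qc_defect_spec(),
                             seed = NULL, thresholds = qc_thresholds()) {
  if (!is.null(seed)) set.seed(seed)
  gt <- genotypes
  n <- nrow(gt$geno)
  m <- ncol(gt$geno)
  ds <- defect_spec
  n_snp_defects <- ds$n_call_rate + ds$n_low_conf + ds$n_het + ds$n_maf +
    ds$n_sex + ds$n_hwe
  if (n_snp_defects > m) stop("defect counts exceed the number of SNPs")
  if (2L * ds$n_dup > n) stop("defect counts exceed the number of samples")
  ledger <- data.frame(kind = character(0), id = character(0),
                       defect = character(0), stringsAsFactors = FALSE)
  if (n_snp_defects == 0L && ds$n_dup == 0L) {
    return(list(table = gt, ledger = ledger))
  }
  targets <- sample.int(m, n_snp_defects)
  take <- function(k) {
    out <- targets[seq_len(k)]
    targets <<- targets[-seq_len(k)]
    out
  }
  log_snp <- function(cols, defect) {
    ledger <<- rbind(ledger, data.frame(kind = "snp",
                                        id = colnames(gt$geno)[cols],
                                        defect = defect,
                                        stringsAsFactors = FALSE))
  }
  n_miss <- ceiling((1 - thresholds$call_rate) * n) + 2L
  if (n_miss > n) stop("too few samples to violate the call-rate threshold")

  for (j in take(ds$n_call_rate)) {
    gt$geno[sample.int(n, n_miss), j] <- NA
    log_snp(j, "call_rate")
  }
  if (ds$n_low_conf > 0L) {
    if (is.null(gt$conf)) gt$conf <- matrix(1, n, m)
    for (j in take(ds$n_low_conf)) {
      gt$conf[sample.int(n, n_miss), j] <- thresholds$confidence / 2
      log_snp(j, "low_confidence")
    }
  }
  for (j in take(ds$n_het)) {
    gt$geno[, j] <- 1
    log_snp(j, "het")
  }
  maf_cols <- take(ds$n_maf)
  for (k in seq_along(maf_cols)) {
    j <- maf_cols[k]
    gt$geno[, j] <- 0
    if (k > 1L) {
      n_rare <- min(3L, max(1L, floor(0.02 * n)))
      if (n_rare / (2 * n) >= thresholds$maf) {
        stop("too few samples to plant a rare (MAF < threshold) SNP")
      }
      gt$geno[sample.int(n, n_rare), j] <- 1
    }
    log_snp(j, "maf")
  }
  for (j in take(ds$n_sex)) {
    gt$map$chr[j] <- "X"
    log_snp(j, "sex_chromosome")
  }
  if (ds$n_hwe > 0L) {
    # heterozygote deficit at p = 0.5: chi-square = 4 n d^2 where d is the
    # drop in heterozygosity below 0.5; aim well past the threshold while
    # keeping observed heterozygosity in the typical panel range
    x2_target <- 1.25 * stats::qchisq(thresholds$hwe_p, df = 1,
                                      lower.tail = FALSE)
    d <- sqrt(x2_target / (4 * n))
    het <- 0.5 - d
    if (het < 0.15) {
      stop("too few samples to plant an HWE violation that survives the ",
           "heterozygosity filter")
    }
    for (j in take(ds$n_hwe)) {
      n1 <- round(n * het)
      n0 <- floor((n - n1) / 2)
      n2 <- n - n1 - n0
      gt$geno[, j] <- sample(rep.int(c(0, 1, 2), c(n0, n1, n2)))
      log_snp(j, "hwe")
    }
  }
  if (ds$n_dup > 0L) {
    pool <- sample.int(n, 2L * ds$n_dup)
    for (k in seq_len(ds$n_dup)) {
      pair <- sort(pool[c(2L * k - 1L, 2L * k)])
      gt$geno[pair[2], ] <- gt$geno[pair[1], ]
      if (ds$n_discord > 0L) {
        flip <- sample.int(m, ds$n_discord)
        g <- gt$geno[pair[2], flip]
        gt$geno[pair[2], flip] <- ifelse(is.na(g), 1, (g + 1) %% 3)
      }
      ledger <- rbind(ledger, data.frame(kind = "sample",
                                         id = gt$ids[pair[2]],
                                         defect = "duplicate",
                                         stringsAsFactors = FALSE))
    }
  }
  list(table = gt, ledger = ledger)
}
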