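test_that("Hardy-Weinberg chi-square matches hand and brute-force oracles", {
  # perfect HWE: chi-square 0
  expect_equal(hwe_test(25, 50, 25), 1)
  # complete heterozygote deficit: chi-square = n, p tiny
  n <- 100
  p_val <- hwe_test(50, 0, 50)
  expect_equal(p_val, pchisq(n, df = 1, lower.tail = FALSE))
  expect_lt(p_val, 1e-15)
  # textbook computation for arbitrary counts
  cnt <- c(30, 49, 21)
  ph <- (cnt[2] + 2 * cnt[3]) / (2 * sum(cnt))
  e <- sum(cnt) * c((1 - ph)^2, 2 * ph * (1 - ph), ph^2)
  x2 <- sum((cnt - e)^2 / e)
  expect_equal(hwe_test(30, 49, 21),
               pchisq(x2, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(hwe_test(0, 0, 0), "zero")
})

test_that("call-rate filter removes exactly the sub-threshold SNPs", {
  gt <- make_clean_table(n = 100, m = 20, seed = 2)
  gt$geno[1:6, 3] <- NA   # 94% call rate: below the 95% threshold
  gt$geno[1:5, 7] <- NA   # exactly 95%: kept
  res <- qc_snps(gt)
  expect_identical(qc_removed(res$report, "call_rate"), "s003")
  expect_true("s007" %in% res$table$map$snp)
})

test_that("monomorphic and rare SNPs fall to the MAF filter", {
  gt <- make_clean_table(n = 200, m = 30, seed = 3)
  gt$geno[, 5] <- 0
  res <- qc_snps(gt)
  expect_true("s005" %in% qc_removed(res$report))
  expect_false("s005" %in% res$table$map$snp)
})

test_that("planted defects are removed exactly and QC is idempotent", {
  gt <- make_clean_table(n = 400, m = 100, seed = 4, conf = TRUE)
  planted <- plant_qc_defects(gt, qc_defect_spec(n_discord = 0), seed = 11)
  expect_equal(nrow(planted$ledger), 8)  # 7 SNP defects + 1 duplicate
  res <- qc_snps(planted$table)
  removed <- sort(qc_removed(res$report))
  expect_identical(removed,
                   sort(planted$ledger$id[planted$ledger$kind == "snp"]))
  # duplicate sample removed exactly per ledger
  res2 <- qc_samples(res$table)
  expect_identical(qc_removed(res2$report),
                   planted$ledger$id[planted$ledger$kind == "sample"])
  # idempotence: a second pass removes nothing
  res3 <- qc_snps(res2$table)
  expect_length(qc_removed(res3$report), 0)
  res4 <- qc_samples(res3$table)
  expect_length(qc_removed(res4$report), 0)
  # conservation: in = out + removed
  expect_equal(res$report$n_in,
               res$report$n_out + length(qc_removed(res$report)))
})

test_that("an empty defect spec leaves the table unchanged", {
  gt <- make_clean_table(n = 50, m = 20, seed = 5)
  out <- plant_qc_defects(gt, qc_defect_spec(0, 0, 0, 0, 0, 0, 0), seed = 1)
  expect_identical(out$table$geno, gt$geno)
  expect_equal(nrow(out$ledger), 0)
})

test_that("defect counts beyond the table dimensions are rejected", {
  gt <- make_clean_table(n = 50, m = 5, seed = 6)
  expect_error(plant_qc_defects(gt, qc_defect_spec(n_call_rate = 10)),
               "exceed")
})

test_that("near-duplicate samples are detected, unrelated ones kept", {
  gt <- make_clean_table(n = 60, m = 5000, seed = 7)
  gt$geno[42, ] <- gt$geno[17, ]
  gt$geno[42, 100] <- (gt$geno[42, 100] + 1) %% 3  # 1 discordance in 5000
  cc <- cor(gt$geno[17, ], gt$geno[42, ])
  expect_gte(cc, 0.99)
  res <- qc_samples(gt)
  expect_identical(qc_removed(res$report), "a042")  # later index removed
  expect_true("a017" %in% res$table$ids)
  # unrelated samples never reach the threshold
  off <- cor(t(res$table$geno))
  expect_lt(max(off[upper.tri(off)]), 0.99)
})

test_that("exact duplicates give correlation 1 and one removal", {
  gt <- make_clean_table(n = 20, m = 200, seed = 8)
  gt$geno[9, ] <- gt$geno[3, ]
  res <- qc_samples(gt)
  expect_equal(res$pairs$correlation, 1)
  expect_identical(res$pairs$kept, "a003")
  expect_identical(res$pairs$removed, "a009")
})

test_that("mean imputation fills missing calls with 2p and preserves G1", {
  # symmetric case: p = 0.5 imputes to 1
  gt <- genotype_table(matrix(c(0, 1, 2, NA), 4, 1),
                       data.frame(snp = "s1", chr = "1", pos = 0.1))
  imp <- impute_missing(gt)
  expect_equal(imp$geno[4, 1], 1)
  # identity on complete tables
  gt2 <- make_clean_table(n = 30, m = 40, seed = 9)
  expect_identical(impute_missing(gt2), gt2)
  # 5% missingness on a family-structured panel (30 full-sib families of 5,
  # the signal-rich setting a reference population provides): imputed
  # dosages still track the truth and G1 is element-wise preserved
  set.seed(10)
  m <- 1000
  p <- runif(m, 0.15, 0.85)
  gamete <- function(par) ifelse(par == 1, rbinom(m, 1, 0.5), par / 2)
  fams <- lapply(1:30, function(f) {
    sire <- rbinom(m, 2, p)
    dam <- rbinom(m, 2, p)
    t(vapply(1:5, function(k) gamete(sire) + gamete(dam), numeric(m)))
  })
  truth <- do.call(rbind, fams)
  holes <- sample(length(truth), 0.05 * length(truth))
  miss <- truth
  miss[holes] <- NA
  gt3 <- genotype_table(miss, data.frame(snp = paste0("m", seq_len(m)),
                                         chr = "1", pos = seq_len(m) / m))
  imp3 <- impute_missing(gt3)
  expect_false(anyNA(imp3$geno))
  expect_gt(cor(imp3$geno[holes], truth[holes]), 0)
  g_true <- build_g1(truth, colMeans(truth) / 2)
  g_imp <- build_g1(imp3$geno, colMeans(imp3$geno) / 2)
  expect_gt(grm_element_correlation(g_true$values, g_imp$values), 0.99)
  # all-missing SNP is an error
  gt4 <- make_clean_table(n = 10, m = 3, seed = 11)
  gt4$geno[, 2] <- NA
  expect_error(impute_missing(gt4), "all calls missing")
})

test_that("phenotype trimming removes only records beyond k SD", {
  y <- c(rep(10, 50), 100)
  out <- trim_phenotype_outliers(y, 4)
  expect_equal(out$removed, 51L)
  # all equal: nothing removed, no error
  out2 <- trim_phenotype_outliers(rep(5, 10))
  expect_length(out2$removed, 0)
  # infinite k: identity
  out3 <- trim_phenotype_outliers(rnorm(100), Inf)
  expect_length(out3$removed, 0)
  # the mean/SD are computed once, not iterated
  y4 <- c(rnorm(200), 6, 30)
  out4 <- trim_phenotype_outliers(y4, 4)
  expect_true(all(abs(y4[out4$removed] - out4$mean) > 4 * out4$sd))
  expect_true(all(abs(y4[-out4$removed] - out4$mean) <= 4 * out4$sd))
})

test_that("confidence masking feeds the call-rate filter", {
  gt <- make_clean_table(n = 100, m = 20, seed = 12, conf = TRUE)
  gt$conf[1:8, 4] <- 0.3
  res <- qc_snps(gt)
  expect_equal(res$report$steps[[1]]$n_calls_masked, 8)
  expect_true("s004" %in% qc_removed(res$report, "call_rate"))
})

test_that("stratified HWE avoids Wahlund false positives", {
  set.seed(13)
  n <- 300
  # two pools fixed for different frequencies: pooled HWE fails, per-pool is
  # fine
  p1 <- 0.9
  p2 <- 0.1
  diverged <- rbind(matrix(rbinom(n * 10, 2, p1), n),
                    matrix(rbinom(n * 10, 2, p2), n))
  shared <- matrix(rbinom(2 * n * 10, 2, 0.5), 2 * n)
  geno <- cbind(diverged, shared)
  gt <- genotype_table(geno, data.frame(snp = paste0("s", 1:20),
                                        chr = "1", pos = (1:20) / 20))
  pooled <- qc_snps(gt, qc_thresholds(hwe_p = 1e-6, het_sd = 10))
  strat <- qc_snps(gt, qc_thresholds(hwe_p = 1e-6, het_sd = 10),
                   stratify_hwe_by = rep(c("A", "B"), each = n))
  expect_gt(length(qc_removed(pooled$report, "hwe")), 0)
  expect_length(qc_removed(strat$report, "hwe"), 0)
})

test_that("PLINK ped/map round trip preserves calls and metadata", {
  gt <- make_clean_table(n = 12, m = 30, seed = 14)
  gt$geno[3, 5] <- NA
  prefix <- file.path(tempdir(), "rt")
  write_plink(gt, prefix)
  back <- read_plink(prefix)
  expect_equal(unname(back$geno), unname(gt$geno))
  expect_equal(back$map$snp, gt$map$snp)
  expect_equal(back$ids, gt$ids)
})
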