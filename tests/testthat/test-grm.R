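test_that("observed allele frequencies are simple dosage means", {
  gt <- genotype_table(matrix(c(0, 1, 2), 3, 1),
                       data.frame(snp = "s1", chr = "1", pos = 0.5))
  expect_equal(unname(allele_frequencies(gt)), 0.5)
  gt2 <- genotype_table(matrix(2, 3, 1),
                        data.frame(snp = "s1", chr = "1", pos = 0.5))
  expect_equal(unname(allele_frequencies(gt2)), 1)
  sim <- small_single_breed(seed = 31, n_progeny = 40)
  ids <- sim$pop$pedigree$id[sim$pop$pedigree$cohort == "purebred"]
  gt3 <- extract_genotypes(sim$pop, ids, include_qtl = TRUE)
  # counting oracle: frequency over the haplotype pool
  pool <- rbind(sim$pop$hap[2 * ids - 1, ], sim$pop$hap[2 * ids, ])
  expect_equal(unname(allele_frequencies(gt3)), unname(colMeans(pool)))
})

test_that("breed-specific frequencies count labelled haplotypes", {
  hap <- rbind(c(1, 0), c(0, 0), c(1, 1), c(1, 1))
  bf <- breed_allele_frequencies(hap, rep("A", 4))
  expect_equal(unname(bf["A", 1]), 0.75)
  # two breeds fixed for opposite alleles
  hap2 <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  bf2 <- breed_allele_frequencies(hap2, c("A", "A", "B", "B"))
  expect_equal(unname(bf2["A", ]), c(1, 1))
  expect_equal(unname(bf2["B", ]), c(0, 0))
  expect_error(breed_allele_frequencies(hap2, c("A", "A", "B", "B"),
                                        breeds = c("A", "B", "C")),
               "zero haplotypes: C")
})

test_that("build_g1 reproduces the hand-computed 2x2 example", {
  m <- rbind(c(0, 2), c(2, 0))
  g <- build_g1(m, freqs = c(0.5, 0.5))
  expect_equal(unname(g$values), rbind(c(2, -2), c(-2, 2)))
})

test_that("build_g1 equals the brute-force double-loop oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    p0 <- runif(40, 0.1, 0.9)
    m <- matrix(rbinom(12 * 40, 2, rep(p0, each = 12)), 12)
    p <- colMeans(m) / 2
    keep <- p > 0 & p < 1
    g <- build_g1(m[, keep], p[keep])
    expect_equal(unname(g$values), g1_oracle(m[, keep], p[keep]),
                 tolerance = 1e-10)
    # observed-frequency centering: rows sum to zero exactly
    expect_lt(max(abs(rowSums(g$values))), 1e-10)
  }
})

test_that("identical twin rows coincide in G1", {
  set.seed(6)
  m <- matrix(rbinom(8 * 50, 2, 0.4), 8)
  m[5, ] <- m[2, ]
  p <- colMeans(m) / 2
  keep <- p > 0 & p < 1
  g <- build_g1(m[, keep], p[keep])$values
  expect_equal(g[2, ], g[5, ], ignore_attr = TRUE)
  expect_equal(g[2, 5], g[2, 2])
})

test_that("build_g1 rejects missing calls and fixed alleles", {
  m <- rbind(c(0, NA), c(2, 1))
  expect_error(build_g1(m), "missing")
  expect_error(build_g1(rbind(c(0, 2), c(0, 0)), freqs = c(0, 0.5)),
               "monomorphic")
})

test_that("gametic centering uses the breed-of-origin frequency", {
  # one animal, one SNP: paternal allele 1 centered by breed-A p = 0.5
  bf <- matrix(c(0.5, 0.2), 2, 1, dimnames = list(c("A", "B"), "s1"))
  g <- build_g2(matrix(1, 1, 1), matrix(0, 1, 1), "A", "B", bf, ids = "x")
  # Z1 = 1 - 0.5 = 0.5; Z2 = 0 - 0.2 = -0.2
  expect_equal(g$meta$G2_paternal[1, 1], 0.5^2 / 0.25)
  expect_equal(g$meta$G2_maternal[1, 1], 0.2^2 / 0.16)
  expect_error(build_g2(matrix(1, 1, 1), matrix(0, 1, 1), "A", "mixed", bf),
               "mixed")
})

test_that("G2 denominator is the haplotype-weighted breed average", {
  set.seed(7)
  pat <- matrix(rbinom(6 * 20, 1, 0.5), 6)
  mat <- matrix(rbinom(6 * 20, 1, 0.5), 6)
  bf <- rbind(A = runif(20, 0.2, 0.8), B = runif(20, 0.2, 0.8))
  g <- build_g2(pat, mat, rep(c("A", "B"), 3), rep("A", 6), bf)
  sA <- sum(bf["A", ] * (1 - bf["A", ]))
  sB <- sum(bf["B", ] * (1 - bf["B", ]))
  expect_equal(unname(g$denominator["paternal"]), (3 * sA + 3 * sB) / 6)
  expect_equal(unname(g$denominator["maternal"]), sA)
})

test_that("element correlation is 1 under identity and scaling", {
  set.seed(8)
  a <- crossprod(matrix(rnorm(100), 10))
  expect_equal(grm_element_correlation(a, a), 1)
  expect_equal(grm_element_correlation(a, 2 * a), 1)
  expect_error(grm_element_correlation(a, a[1:5, 1:5]), "mismatch")
})

test_that("permuting animals permutes the GRM consistently", {
  set.seed(9)
  m <- matrix(rbinom(10 * 60, 2, 0.5), 10)
  p <- colMeans(m) / 2
  keep <- p > 0 & p < 1
  g <- build_g1(m[, keep], p[keep])$values
  perm <- sample(10)
  g_perm <- build_g1(m[perm, keep], p[keep])$values
  expect_equal(g_perm, g[perm, perm], ignore_attr = TRUE)
})

test_that("PCA separates simulated breeds and flags the isotropic case", {
  sim <- small_two_breed(seed = 32)
  ped <- sim$pop$pedigree
  ids <- ped$id[!is.na(ped$breed)]
  ids <- unlist(lapply(split(ids, ped$breed[match(ids, ped$id)]), head, 40))
  gt <- extract_genotypes(sim$pop, ids, include_qtl = TRUE)
  p <- allele_frequencies(gt)
  keep <- p > 0.02 & p < 0.98
  g <- build_g1(subset_genotype_table(gt, snps = which(keep)))
  lab <- ped$breed[match(ids, ped$id)]
  pc <- grm_pca(g, labels = lab)
  expect_equal(pc$purity, 1)
  # identity matrix: all eigenvalues equal, purity degenerate
  iso <- grm_pca(diag(10), labels = rep(c("A", "B"), 5))
  expect_true(is.na(iso$purity))
  expect_error(grm_pca(matrix(c(1, NA, NA, 1), 2)), "non-finite")
})

test_that("haplotype-group relationships order as relatedness does", {
  sim <- small_single_breed(seed = 33, n_progeny = 120)
  pop <- sim$pop
  ped <- pop$pedigree
  prog_all <- ped$id[ped$cohort == "purebred"]
  lab <- function(n) rep("B1", n)
  # frequencies from the whole progeny pool; the probed animal subset is a
  # few families, so group means are not forced to zero by centering
  hp_all <- extract_haplotypes(pop, prog_all, include_qtl = TRUE)
  bf <- breed_allele_frequencies(rbind(hp_all$paternal, hp_all$maternal),
                                 lab(2 * length(prog_all)))
  sires <- unique(ped$sire[match(prog_all, ped$id)])
  focal_sires <- sires[1:3]
  # one progeny per focal sire: self-products then dominate family products
  prog <- vapply(focal_sires, function(s)
    prog_all[ped$sire[match(prog_all, ped$id)] == s][1], numeric(1))
  hp_prog <- extract_haplotypes(pop, prog, include_qtl = TRUE)
  animals <- list(paternal = hp_prog$paternal, maternal = hp_prog$maternal,
                  paternal_breed = lab(length(prog)),
                  maternal_breed = lab(length(prog)))
  other <- setdiff(ped$id[!is.na(ped$breed) & ped$sex == "M"], sires)[1:10]
  hp_sire <- extract_haplotypes(pop, focal_sires, include_qtl = TRUE)
  hp_other <- extract_haplotypes(pop, other, include_qtl = TRUE)
  rel_sire <- haplotype_group_relationship(
    rbind(hp_sire$paternal, hp_sire$maternal), lab(2 * length(focal_sires)),
    animals, bf)
  rel_other <- haplotype_group_relationship(
    rbind(hp_other$paternal, hp_other$maternal), lab(2 * length(other)),
    animals, bf)
  # the sires of these families relate more than non-parent males
  expect_gt(rel_sire$mean, rel_other$mean)
  # a group against its own haplotypes is the most related of all
  rel_self <- haplotype_group_relationship(
    rbind(hp_prog$paternal, hp_prog$maternal), lab(2 * length(prog)),
    animals, bf)
  expect_gt(rel_self$mean, rel_sire$mean)
  expect_error(haplotype_group_relationship(
    hp_sire$paternal[0, , drop = FALSE], character(0), animals, bf),
    "empty group")
})

test_that("GCTA text format round-trips a GRM", {
  set.seed(10)
  m <- matrix(rbinom(6 * 80, 2, 0.5), 6)
  p <- colMeans(m) / 2
  keep <- p > 0 & p < 1
  g <- build_g1(m[, keep], p[keep])
  prefix <- file.path(tempdir(), "g")
  write_grm(g, prefix, n_snps = sum(keep))
  back <- read_grm(prefix)
  expect_equal(back$values, g$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$ids, g$ids)
})
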