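test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_breeds = 0), "positive")
  expect_error(sim_config(trait_h2 = 0), "variance ratios")
  expect_error(sim_config(trait_h2 = 0.9, maternal_variance_ratio = 0.2),
               "variance ratios")
  expect_error(sim_config(across_breed_qtl_correlation = 1.2), "\\[-1, 1\\]")
  expect_error(sim_config(family_size_range = c(30, 10)), "ascending")
})

test_that("founder simulation has the right shape, range and determinism", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, snps_per_chromosome = 10,
                    n_founders = 50, burnin_generations = 2, n_breeds = 1,
                    effective_size = 10, n_qtl = 2)
  base <- simulate_founders(cfg)
  expect_equal(dim(base$hap), c(100, 10))
  expect_true(all(base$hap %in% 0:1))
  expect_equal(nrow(base$pedigree), 50)
  base2 <- simulate_founders(cfg)
  expect_identical(base$hap, base2$hap)
})

test_that("mean minor-allele frequency matches the folded Beta(2,2) law", {
  # oracle: E[min(p, 1-p)] by numeric integration of the Beta(2,2) density
  expected <- integrate(function(p) pmin(p, 1 - p) * dbeta(p, 2, 2),
                        0, 1)$value
  cfg <- sim_config(seed = 7, n_chromosomes = 1, snps_per_chromosome = 600,
                    n_founders = 2000, burnin_generations = 0, n_breeds = 1,
                    effective_size = 100, n_qtl = 5)
  base <- simulate_founders(cfg)
  p <- colMeans(base$hap)
  expect_lt(abs(mean(pmin(p, 1 - p)) - expected), 0.02)
})

test_that("zero divergence leaves breed frequencies at base frequencies", {
  cfg <- sim_config(seed = 2, n_breeds = 2, divergence_generations = c(0, 0),
                    n_chromosomes = 1, snps_per_chromosome = 40,
                    n_founders = 60, burnin_generations = 5,
                    effective_size = 30, n_qtl = 5)
  base <- simulate_founders(cfg)
  pop <- derive_breeds(base, cfg)
  expect_equal(pop$breed_freq["B1", ], base$base_freq,
               ignore_attr = TRUE)
  expect_equal(pop$breed_freq["B2", ], base$base_freq,
               ignore_attr = TRUE)
})

test_that("derive_breeds rejects Ne above the base size", {
  cfg <- sim_config(seed = 2, n_breeds = 1, n_founders = 20,
                    effective_size = 50, burnin_generations = 0,
                    n_chromosomes = 1, snps_per_chromosome = 10, n_qtl = 2)
  base <- simulate_founders(cfg)
  expect_error(derive_breeds(base, cfg), "exceeds base")
})

test_that("QTL effects respect the across-breed correlation", {
  sim <- small_two_breed(seed = 3)
  # perfect correlation: identical effect vectors
  cfg1 <- sim$cfg
  cfg1$across_breed_qtl_correlation <- 1
  pop1 <- sample_qtl(sim$pop, cfg1)
  expect_equal(pop1$qtl$effects["B1", ], pop1$qtl$effects["B2", ])
  # zero correlation: sample correlation near 0 with SE ~ 1/sqrt(n_qtl)
  set.seed(99)
  cfg0 <- sim$cfg
  cfg0$across_breed_qtl_correlation <- 0
  cfg0$n_qtl <- 150L
  cors <- replicate(20, {
    p <- sample_qtl(sim$pop, cfg0)
    cor(p$qtl$effects["B1", ], p$qtl$effects["B2", ])
  })
  expect_lt(abs(mean(cors)), 3 / sqrt(150 * 20))
  cfg_bad <- sim$cfg
  cfg_bad$across_breed_qtl_correlation <- 2
  expect_error(sample_qtl(sim$pop, cfg_bad), "\\[-1, 1\\]")
})

test_that("realized additive variance in the focal pool matches the target", {
  sim <- small_single_breed(seed = 4)
  ped <- sim$pop$pedigree
  pool <- ped$id[!is.na(ped$breed) & ped$breed == "B1"]
  tbv <- true_breeding_values(sim$pop, pool)
  target <- sim$cfg$trait_h2 * sim$cfg$trait_sd^2
  expect_equal(var(tbv), target, tolerance = 1e-10)
})

test_that("mating design yields Mendelian-consistent half-sib families", {
  sim <- small_single_breed(seed = 5, n_progeny = 50)
  ped <- sim$pop$pedigree
  prog <- ped[ped$cohort == "purebred", ]
  # paternal half-sib structure: one sire per family, dams distinct within
  fam <- split(prog, prog$sire)
  for (f in fam) {
    expect_equal(length(unique(f$sire)), 1L)
    expect_false(anyDuplicated(f$dam) > 0)
  }
  # exhaustive Mendelian check: every progeny allele comes from a parent
  hap <- sim$pop$hap
  for (i in seq_len(nrow(prog))) {
    id <- prog$id[i]
    s <- prog$sire[i]
    d <- prog$dam[i]
    pat <- hap[2 * id - 1, ]
    mat <- hap[2 * id, ]
    expect_true(all(pat == hap[2 * s - 1, ] | pat == hap[2 * s, ]))
    expect_true(all(mat == hap[2 * d - 1, ] | mat == hap[2 * d, ]))
  }
})

test_that("F1 haplotype breed-of-origin follows the pedigree", {
  sim <- small_two_breed(seed = 6)
  ped <- sim$pop$pedigree
  f1 <- ped$id[ped$cohort == "B2xB1"]
  org <- sim$pop$origin
  # sire breed B2 on the paternal strand, dam breed B1 on the maternal
  expect_true(all(org[2 * f1 - 1, ] == 2L))
  expect_true(all(org[2 * f1, ] == 1L))
})

test_that("empty parent pool raises an error", {
  sim <- small_two_breed(seed = 7)
  cfg <- sim$cfg
  cfg$design$crosses[[1]]$dam_type <- "NOxNO"
  base <- simulate_founders(cfg)
  pop <- derive_breeds(base, cfg)
  expect_error(build_design(pop, cfg), "empty dam pool")
})

test_that("phenotypes reduce to mu + TBV in the noise-free limit", {
  sim <- small_single_breed(seed = 8, trait_h2 = 1 - 1e-9,
                            maternal_variance_ratio = 0,
                            sire_flock_variance_ratio = 0)
  rec <- simulate_phenotypes(sim$pop, sim$cfg, include_fixed = FALSE)
  tbv <- true_breeding_values(sim$pop, rec$animal)
  expect_equal(rec$y, as.numeric(sim$cfg$trait_mean + tbv),
               tolerance = 1e-3)
})

test_that("phenotype variance partition matches the heritability", {
  slopes <- r2s <- numeric(4)
  for (k in 1:4) {
    sim <- small_single_breed(seed = 40 + k, n_progeny = 400,
                              maternal_variance_ratio = 0,
                              sire_flock_variance_ratio = 0)
    rec <- simulate_phenotypes(sim$pop, sim$cfg, include_fixed = FALSE)
    tbv <- true_breeding_values(sim$pop, rec$animal)
    fit <- lm(rec$y ~ tbv)
    slopes[k] <- coef(fit)[2]
    r2s[k] <- summary(fit)$r.squared
  }
  expect_lt(abs(mean(slopes) - 1), 0.1)
  expect_lt(abs(mean(r2s) - 0.3), 0.05)
})

test_that("sire-by-flock variance is recoverable from the records", {
  # oracle: one-way ANOVA on y with the true additive/maternal parts removed
  ests <- numeric(20)
  for (k in 1:20) {
    sim <- small_single_breed(seed = 60 + k, n_progeny = 300,
                              snps_per_chromosome = 60,
                              maternal_variance_ratio = 0,
                              sire_flock_variance_ratio = 0.05)
    rec <- simulate_phenotypes(sim$pop, sim$cfg, include_fixed = FALSE)
    comp <- attr(rec, "true_components")
    resid <- rec$y - comp$g
    ests[k] <- anova_varcomp(resid, paste(rec$sire, rec$flock))
  }
  target <- 0.05 * sim$cfg$trait_sd^2
  expect_lt(abs(mean(ests) - target) / target, 0.3)
})

test_that("progeny-test EBVs hit the requested accuracy", {
  set.seed(10)
  tbv <- rnorm(500, 20, 3)
  # r = 1: perfect rank correlation
  e1 <- simulate_progeny_test_ebv(tbv, 1)
  expect_equal(cor(e1$ebv, tbv, method = "spearman"), 1)
  # moderate r: realized correlation close to target over replicates
  rs <- replicate(25, cor(simulate_progeny_test_ebv(tbv, 0.92)$ebv, tbv))
  expect_lt(abs(mean(rs) - 0.92), 0.03)
  expect_error(simulate_progeny_test_ebv(tbv, 1.2), "\\(0, 1\\]")
  expect_error(simulate_progeny_test_ebv(tbv, 0), "\\(0, 1\\]")
})

test_that("the full pipeline is bit-identical under one seed", {
  cfg <- sim_config(seed = 123, n_breeds = 2,
                    n_chromosomes = 1, snps_per_chromosome = 60,
                    divergence_generations = c(5, 5), effective_size = 40,
                    breed_pool_size = 60, burnin_generations = 5,
                    n_founders = 80, n_qtl = 10,
                    design = list(n_purebred = 60, crosses = list(),
                                  n_validation_sires = c(B1 = 4L)))
  a <- simulate_sheep_population(cfg)
  b <- simulate_sheep_population(cfg)
  expect_identical(a$population$hap, b$population$hap)
  expect_identical(a$population$qtl, b$population$qtl)
  expect_identical(a$records, b$records)
})
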