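# Shared fixture builders: everything is generated in code at test time.

# Clean genotype table: independent HWE samples at frequencies drawn inside
# a safe band, full call rate, no defects.
make_clean_table <- function(n = 400, m = 100, freq_range = c(0.15, 0.85),
                             seed = 1, conf = FALSE) {
  set.seed(seed)
  p <- runif(m, freq_range[1], freq_range[2])
  geno <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  map <- data.frame(snp = sprintf("s%03d", seq_len(m)),
                    chr = as.character(rep(1:2, length.out = m)),
                    pos = seq_len(m) / m)
  genotype_table(geno, map, ids = sprintf("a%03d", seq_len(n)),
                 conf = if (conf) matrix(1, n, m))
}

# Small single-breed population with paternal half-sib families.
small_single_breed <- function(seed = 1, n_progeny = 200,
                               snps_per_chromosome = 120,
                               n_chromosomes = 2, ...) {
  cfg <- sim_config(seed = seed, n_breeds = 1,
                    n_chromosomes = n_chromosomes,
                    snps_per_chromosome = snps_per_chromosome,
                    divergence_generations = 5, effective_size = 60,
                    breed_pool_size = 120, burnin_generations = 20,
                    n_founders = 120, n_qtl = 40,
                    design = list(n_purebred = n_progeny, crosses = list(),
                                  n_validation_sires = c(B1 = 5L)),
                    ...)
  base <- simulate_founders(cfg)
  pop <- derive_breeds(base, cfg)
  pop <- sample_qtl(pop, cfg)
  pop <- build_design(pop, cfg)
  list(pop = pop, cfg = cfg)
}

# Two-breed population with an F1 cohort (for Q / phasing / G2 tests).
small_two_breed <- function(seed = 1, n_purebred = 120, n_f1 = 80, ...) {
  cfg <- sim_config(seed = seed, n_breeds = 2,
                    n_chromosomes = 2, snps_per_chromosome = 100,
                    divergence_generations = c(40, 40), effective_size = 50,
                    breed_pool_size = 100, burnin_generations = 20,
                    n_founders = 100, n_qtl = 30,
                    design = list(
                      n_purebred = n_purebred,
                      crosses = list(list(name = "B2xB1", sire_breed = "B2",
                                          dam_type = "purebred", n = n_f1)),
                      n_validation_sires = c(B1 = 8L, B2 = 6L)),
                    ...)
  base <- simulate_founders(cfg)
  pop <- derive_breeds(base, cfg)
  pop <- sample_qtl(pop, cfg)
  pop <- build_design(pop, cfg)
  list(pop = pop, cfg = cfg)
}

# Brute-force per-element GRM oracle: an explicit double loop over elements,
# independent of build_g1's matrix algebra.
g1_oracle <- function(M, p) {
  n <- nrow(M)
  g <- matrix(0, n, n)
  denom <- 2 * sum(p * (1 - p))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      g[i, j] <- sum((M[i, ] - 2 * p) * (M[j, ] - 2 * p)) / denom
    }
  }
  g
}

# Founder-path enumeration oracle for breed proportions: walks every
# ancestry path to depth `max_depth`, adding 2^-depth per labelled founder.
breed_prop_oracle <- function(ped, animal, max_depth = 6L) {
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  acc <- new.env()
  add <- function(lbl, wt) {
    cur <- mget(lbl, envir = acc, ifnotfound = 0)[[1]]
    assign(lbl, cur + wt, envir = acc)
  }
  walk <- function(id, depth, wt) {
    if (is.na(id) || depth > max_depth) {
      add("unknown", wt)
      return(invisible())
    }
    i <- idx[[as.character(id)]]
    if (!is.na(ped$breed[i])) {
      add(ped$breed[i], wt)
      return(invisible())
    }
    if (is.na(ped$sire[i]) && is.na(ped$dam[i])) {
      add("unknown", wt)
      return(invisible())
    }
    walk(ped$sire[i], depth + 1L, wt / 2)
    walk(ped$dam[i], depth + 1L, wt / 2)
  }
  walk(animal, 0L, 1)
  out <- unlist(as.list(acc))
  out / sum(out)
}

# Random small mixed-model instance with maternal and sire-by-flock terms;
# some animals in G carry no records.
random_instance <- function(seed, n_extra = 5) {
  set.seed(seed)
  n <- sample(10:30, 1)
  na <- n + n_extra
  ids <- as.character(seq_len(na))
  G <- crossprod(matrix(rnorm(na * (na + 20)), na + 20, na)) / (na + 20) +
    diag(0.05, na)
  rec <- data.frame(animal = sample(ids[seq_len(n)]),
                    y = rnorm(n, 10, 2),
                    birth_type = sample(1:2, n, TRUE),
                    gender = sample(c("M", "F"), n, TRUE),
                    age = runif(n, 100, 300),
                    cg = sample(c("c1", "c2"), n, TRUE),
                    sire = sample(1:4, n, TRUE),
                    flock = sample(1:2, n, TRUE),
                    dam = sample(100:107, n, TRUE))
  des <- build_design_matrices(rec, ids,
                               fixed = ~ factor(birth_type) + gender + age,
                               maternal = TRUE, sire_flock = TRUE)
  list(des = des, G = G,
       vc = list(g = runif(1, 0.2, 1), m = runif(1, 0.05, 0.3),
                 sf = runif(1, 0.05, 0.3), e = runif(1, 0.3, 1)))
}

# Method-of-moments one-way ANOVA variance component (balanced-ish groups).
anova_varcomp <- function(y, group) {
  group <- factor(group)
  k <- nlevels(group)
  n <- length(y)
  ni <- tabulate(group)
  gm <- tapply(y, group, mean)
  msb <- sum(ni * (gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[group])^2) / (n - k)
  n0 <- (n - sum(ni^2) / n) / (k - 1)
  (msb - msw) / n0
}
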