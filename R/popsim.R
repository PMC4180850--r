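#' Simulation configuration for a multi-breed sheep-like population
#'
#' Collects every parameter of the forward-in-time simulator: genome layout,
#' breed divergence, QTL architecture, trait variance partition and the
#' crossbreeding design. The seed stored here fully determines every
#' downstream draw when the pipeline is run through
#' [simulate_sheep_population()].
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_chromosomes Number of chromosomes.
#' @param snps_per_chromosome Loci simulated per chromosome (markers + QTL).
#' @param chromosome_length Genetic length of each chromosome in Morgans;
#'   crossover counts per meiosis are Poisson with this mean (no
#'   interference).
#' @param n_breeds Number of diverged breeds.
#' @param breed_names Labels for the breeds. The first is the focal,
#'   numerically dominant "Merino-analog" unless `focal_breed` says otherwise.
#' @param divergence_generations Generations of independent drift per breed
#'   (recycled to `n_breeds`). Unequal values give a star topology in which
#'   short-branch breeds end up mutually closer than to long-branch breeds.
#' @param effective_size Effective population size (Ne) of each breed during
#'   divergence.
#' @param n_founders Size of the ancestral base population.
#' @param burnin_generations Random-mating generations in the base population
#'   used to induce within-chromosome linkage disequilibrium before the
#'   breeds split.
#' @param breed_pool_size Number of animals kept per breed after divergence;
#'   the final divergence generation is expanded to this size so that enough
#'   parents exist for the mating design.
#' @param n_qtl Number of QTL underlying the trait.
#' @param across_breed_qtl_correlation Pairwise correlation of additive QTL
#'   effects between breeds, in \[-1, 1\] (must keep the equicorrelation
#'   matrix positive semi-definite).
#' @param qtl_on_panel Logical; if `FALSE` (default) QTL are excluded from
#'   the genotyping panel, mimicking a 50k chip that tags but does not type
#'   causal loci.
#' @param trait_h2 Narrow-sense heritability of the trait.
#' @param maternal_variance_ratio,sire_flock_variance_ratio Maternal and
#'   sire-by-flock variance as fractions of phenotypic variance.
#' @param trait_mean,trait_sd Phenotypic mean and standard deviation in trait
#'   units (defaults emulate post-weaning weight in kg).
#' @param breed_effects Mean breed effects in trait units (length
#'   `n_breeds`); an animal's expected phenotype shifts by its
#'   breed-proportion-weighted sum of these.
#' @param n_flocks Number of flocks (sites).
#' @param family_size_range Two integers: min/max paternal half-sib family
#'   size.
#' @param validation_reliability_floor Minimum progeny-test EBV accuracy
#'   (correlation scale) for a sire to enter the validation set.
#' @param focal_breed Label of the focal breed.
#' @param design Mating design, see [default_design()]. `NULL` uses the
#'   default derived from the other parameters.
#' @return An object of class `sim_config`.
#' @seealso [sheep_sim_config()] for the four-breed preset used throughout
#'   the package.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       snps_per_chromosome = 350L,
                       chromosome_length = 1,
                       n_breeds = 4L,
                       breed_names = NULL,
                       divergence_generations = c(150L, 100L, 60L, 60L),
                       effective_size = 100L,
                       n_founders = 2L * effective_size,
                       burnin_generations = 50L,
                       breed_pool_size = 300L,
                       n_qtl = 100L,
                       across_breed_qtl_correlation = 0.2,
                       qtl_on_panel = FALSE,
                       trait_h2 = 0.3,
                       maternal_variance_ratio = 0.05,
                       sire_flock_variance_ratio = 0.05,
                       trait_mean = 36.6,
                       trait_sd = 7.6,
                       breed_effects = NULL,
                       n_flocks = 5L,
                       family_size_range = c(10L, 30L),
                       validation_reliability_floor = 0.7,
                       focal_breed = NULL,
                       design = NULL) {
  if (is.null(breed_names)) {
    breed_names <- if (n_breeds == 4L) c("MER", "BL", "PD", "WS") else
      paste0("B", seq_len(n_breeds))
  }
  counts <- c(n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome,
              n_breeds = n_breeds, effective_size = effective_size,
              n_founders = n_founders, breed_pool_size = breed_pool_size,
              n_qtl = n_qtl, n_flocks = n_flocks)
  if (any(counts < 1L)) {
    stop("configuration error: all counts must be positive (",
         paste(names(counts)[counts < 1L], collapse = ", "), ")")
  }
  if (burnin_generations < 0L) stop("configuration error: negative burn-in")
  if (length(breed_names) != n_breeds) {
    stop("breed_names must have length n_breeds")
  }
  if (chromosome_length <= 0) {
    stop("configuration error: chromosome_length must be positive")
  }
  divergence_generations <- rep_len(as.integer(divergence_generations),
                                    n_breeds)
  if (any(divergence_generations < 0L)) {
    stop("configuration error: negative divergence_generations")
  }
  if (abs(across_breed_qtl_correlation) > 1) {
    stop("across_breed_qtl_correlation must be in [-1, 1]")
  }
  if (trait_h2 <= 0 || trait_h2 >= 1 ||
      maternal_variance_ratio < 0 || sire_flock_variance_ratio < 0 ||
      trait_h2 + maternal_variance_ratio + sire_flock_variance_ratio > 1) {
    stop("variance ratios invalid: need h2 in (0,1), ratios >= 0, sum <= 1")
  }
  if (length(family_size_range) != 2L ||
      family_size_range[1] > family_size_range[2] ||
      family_size_range[1] < 1L) {
    stop("family_size_range must be an ascending pair of positive counts")
  }
  if (validation_reliability_floor <= 0 || validation_reliability_floor >= 1) {
    stop("validation_reliability_floor must be in (0, 1)")
  }
  if (is.null(breed_effects)) breed_effects <- rep(0, n_breeds)
  if (length(breed_effects) != n_breeds) {
    stop("breed_effects must have length n_breeds")
  }
  if (is.null(focal_breed)) focal_breed <- breed_names[1L]
  if (!focal_breed %in% breed_names) stop("unknown focal_breed")
  names(breed_effects) <- breed_names
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length = chromosome_length,
              n_breeds = as.integer(n_breeds),
              breed_names = breed_names,
              divergence_generations = divergence_generations,
              effective_size = as.integer(effective_size),
              n_founders = as.integer(n_founders),
              burnin_generations = as.integer(burnin_generations),
              breed_pool_size = as.integer(breed_pool_size),
              n_qtl = as.integer(n_qtl),
              across_breed_qtl_correlation = across_breed_qtl_correlation,
              qtl_on_panel = isTRUE(qtl_on_panel),
              trait_h2 = trait_h2,
              maternal_variance_ratio = maternal_variance_ratio,
              sire_flock_variance_ratio = sire_flock_variance_ratio,
              trait_mean = trait_mean, trait_sd = trait_sd,
              breed_effects = breed_effects,
              n_flocks = as.integer(n_flocks),
              family_size_range = as.integer(family_size_range),
              validation_reliability_floor = validation_reliability_floor,
              focal_breed = focal_breed,
              design = design)
  class(cfg) <- "sim_config"
  cfg
}

#' Four-breed sheep-like preset
#'
#' A `sim_config` emulating the structure of an Australian sheep resource
#' population: one numerically dominant Merino-analog (`MER`), a maternal
#' breed (`BL`) and two terminal breeds (`PD`, `WS`) that diverged less from
#' each other; purebred focal-breed families, F1 `BL x MER` crossbreds and
#' three-way `PD x (BL x MER)` crossbreds in paternal half-sib families.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sheep_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             breed_effects = c(0, 7, 9, 9),
             ...)
}

#' Default crossbreeding design
#'
#' Purebred focal-breed progeny plus an F1 cross and a three-way cross via F1
#' dams, mirroring a resource-flock design in which most dams are purebred
#' focal-breed ewes or F1 ewes.
#'
#' @param config A `sim_config`.
#' @return A list with elements `n_purebred`, `crosses` (each a list with
#'   `name`, `sire_breed`, `dam_type`, `n`), `n_validation_sires` (named per
#'   breed).
#' @export
default_design <- function(config) {
  bn <- config$breed_names
  focal <- config$focal_breed
  others <- setdiff(bn, focal)
  crosses <- list()
  if (length(others) >= 1) {
    crosses[[1]] <- list(name = paste0(others[1], "x", focal),
                         sire_breed = others[1], dam_type = "purebred",
                         n = 450L)
  }
  if (length(others) >= 2) {
    crosses[[2]] <- list(name = paste0(others[2], "x", crosses[[1]]$name),
                         sire_breed = others[2],
                         dam_type = crosses[[1]]$name, n = 150L)
  }
  nval <- integer(0)
  nval[focal] <- 60L
  if (length(others) >= 1) nval[others[1]] <- 40L
  list(n_purebred = 700L, crosses = crosses, n_validation_sires = nval)
}

## ---------------------------------------------------------------------------
## genome / meiosis machinery

# Precomputed chromosome layout: per-chromosome locus indices and positions.
chromosome_layout <- function(config) {
  m_chr <- config$snps_per_chromosome
  n_chr <- config$n_chromosomes
  idx <- split(seq_len(m_chr * n_chr), rep(seq_len(n_chr), each = m_chr))
  pos1 <- seq(0, config$chromosome_length, length.out = m_chr + 2L)
  pos1 <- pos1[-c(1L, m_chr + 2L)]               # uniform, off the ends
  list(idx = idx, pos = rep(list(pos1), n_chr),
       len = rep(config$chromosome_length, n_chr),
       M = m_chr * n_chr)
}

sim_map <- function(config) {
  lay <- chromosome_layout(config)
  data.frame(snp = sprintf("snp%04d", seq_len(lay$M)),
             chr = as.character(rep(seq_len(config$n_chromosomes),
                                    each = config$snps_per_chromosome)),
             pos = unlist(lay$pos, use.names = FALSE),
             is_qtl = FALSE,
             stringsAsFactors = FALSE)
}

# Per-locus selector (1 = parent's paternal strand, 2 = maternal strand) for
# one gamete: random start strand per chromosome, Poisson(length) crossovers
# at uniform positions, no interference.
gamete_selector <- function(layout) {
  sel <- integer(layout$M)
  for (k in seq_along(layout$idx)) {
    start <- sample.int(2L, 1L)
    ncx <- stats::rpois(1L, layout$len[k])
    if (ncx == 0L) {
      sel[layout$idx[[k]]] <- start
    } else {
      bp <- sort(stats::runif(ncx, 0, layout$len[k]))
      seg <- findInterval(layout$pos[[k]], bp)
      sel[layout$idx[[k]]] <- 1L + (start - 1L + seg) %% 2L
    }
  }
  sel
}

# One gamete (allele vector) from parent row-pair (2p-1, 2p) of `hap`.
meiosis_gamete <- function(hap, parent, layout) {
  sel <- gamete_selector(layout)
  a <- hap[2L * parent - 1L, ]
  j <- sel == 2L
  if (any(j)) a[j] <- hap[2L * parent, ][j]
  a
}

# Random-mating Wright-Fisher-like generation: each offspring draws two
# distinct parents; one gamete from each.
random_mating_generation <- function(hap, layout, n_out) {
  n <- nrow(hap) %/% 2L
  out <- matrix(0L, 2L * n_out, ncol(hap))
  for (i in seq_len(n_out)) {
    prt <- if (n == 1L) c(1L, 1L) else sample.int(n, 2L)
    out[2L * i - 1L, ] <- meiosis_gamete(hap, prt[1L], layout)
    out[2L * i, ] <- meiosis_gamete(hap, prt[2L], layout)
  }
  out
}

# `generations - 1` generations at size `n_per_gen`, final one expanded to
# `n_final` so the last pool is large enough for the mating design without
# adding an extra drift generation.
evolve_pool <- function(hap, layout, generations, n_per_gen, n_final) {
  if (generations == 0L) return(hap)
  for (g in seq_len(generations)) {
    n_out <- if (g == generations) n_final else n_per_gen
    hap <- random_mating_generation(hap, layout, n_out)
  }
  hap
}

new_population <- function(hap, origin, pedigree, map, config,
                           base_freq = NULL, breed_freq = NULL, qtl = NULL,
                           design_info = NULL) {
  structure(list(hap = hap, origin = origin, pedigree = pedigree, map = map,
                 config = config, base_freq = base_freq,
                 breed_freq = breed_freq, qtl = qtl,
                 design_info = design_info),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population:", nrow(x$pedigree), "animals,",
      nrow(x$map), "loci on", length(unique(x$map$chr)), "chromosomes\n")
  if (!is.null(x$breed_freq)) {
    cat("breeds:", paste(rownames(x$breed_freq), collapse = ", "), "\n")
  }
  if (!is.null(x$qtl)) cat("QTL:", length(x$qtl$index), "loci\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## pipeline operations

#' Simulate the ancestral base population
#'
#' Draws per-locus allele frequencies from Beta(2, 2), samples founder
#' haplotypes in linkage equilibrium and then runs a configurable number of
#' random-mating generations to induce within-chromosome LD.
#'
#' @param config A [sim_config()].
#' @return A `sim_population` holding the final base generation (founders of
#'   everything downstream); `$base_freq` records its allele frequencies.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- chromosome_layout(config)
  map <- sim_map(config)
  m <- lay$M
  n <- config$n_founders
  p0 <- stats::rbeta(m, 2, 2)
  hap <- matrix(stats::rbinom(2L * n * m, 1L, rep(p0, each = 2L * n)),
                nrow = 2L * n)
  hap <- evolve_pool(hap, lay, config$burnin_generations, n, n)
  ped <- data.frame(id = seq_len(n), sire = NA_integer_, dam = NA_integer_,
                    sex = rep_len(c("M", "F"), n), generation = 0L,
                    breed = NA_character_, cohort = "base", flock = NA_integer_,
                    stringsAsFactors = FALSE)
  new_population(hap = hap, origin = matrix(0L, 2L * n, m), pedigree = ped,
                 map = map, config = config, base_freq = colMeans(hap))
}

#' Derive breeds by independent drift
#'
#' Each breed is an independent Wright-Fisher lineage of size
#' `effective_size` started from the common base population and drifted for
#' its own number of generations; the final generation is expanded to
#' `breed_pool_size`. With zero divergence generations a breed is the base
#' population itself, so its allele frequencies equal the base frequencies
#' exactly.
#'
#' @param base A `sim_population` from [simulate_founders()].
#' @param config The same [sim_config()].
#' @return A `sim_population` whose pedigree contains only the breed founder
#'   pools (generation 0, labelled by breed); `$breed_freq` is the
#'   breeds-by-loci truth frequency matrix.
#' @export
derive_breeds <- function(base, config) {
  stopifnot(inherits(base, "sim_population"))
  n_base <- nrow(base$pedigree)
  if (config$effective_size > n_base) {
    stop("effective_size (Ne) exceeds base population size")
  }
  lay <- chromosome_layout(config)
  pools <- vector("list", config$n_breeds)
  for (b in seq_len(config$n_breeds)) {
    t_b <- config$divergence_generations[b]
    pools[[b]] <- if (t_b == 0L) base$hap else
      evolve_pool(base$hap, lay, t_b, config$effective_size,
                  config$breed_pool_size)
  }
  sizes <- vapply(pools, function(h) nrow(h) %/% 2L, integer(1))
  hap <- do.call(rbind, pools)
  origin <- matrix(rep(rep.int(seq_len(config$n_breeds), 2L * sizes),
                       ncol(hap)),
                   nrow = nrow(hap))
  n <- sum(sizes)
  ped <- data.frame(id = seq_len(n), sire = NA_integer_, dam = NA_integer_,
                    sex = unlist(lapply(sizes, function(s)
                      rep_len(c("M", "F"), s))),
                    generation = 0L,
                    breed = rep.int(config$breed_names, sizes),
                    cohort = "breed_founder", flock = NA_integer_,
                    stringsAsFactors = FALSE)
  bf <- t(vapply(pools, colMeans, numeric(ncol(hap))))
  rownames(bf) <- config$breed_names
  new_population(hap = hap, origin = origin, pedigree = ped, map = base$map,
                 config = config, base_freq = base$base_freq, breed_freq = bf)
}

#' Sample QTL with breed-specific correlated effects
#'
#' Picks `n_qtl` loci segregating across the pooled breeds and draws one
#' additive effect vector per breed from an equicorrelated multivariate
#' normal with pairwise correlation `across_breed_qtl_correlation`. Effects
#' are scaled once so that the realized additive variance of true breeding
#' values in the focal breed pool equals `trait_h2 * trait_sd^2`.
#'
#' @param population Breed-labelled `sim_population` from [derive_breeds()].
#' @param config The [sim_config()].
#' @return The population with `$qtl` set (`index`, `effects` matrix of
#'   breeds x QTL) and `map$is_qtl` flagged.
#' @export
sample_qtl <- function(population, config) {
  stopifnot(inherits(population, "sim_population"))
  if (abs(config$across_breed_qtl_correlation) > 1) {
    stop("across_breed_qtl_correlation must be in [-1, 1]")
  }
  freq <- colMeans(population$hap)
  seg <- which(freq > 0 & freq < 1)
  if (config$n_qtl > length(seg)) {
    stop("n_qtl exceeds the number of segregating loci")
  }
  qidx <- sort(sample(seg, config$n_qtl))
  k <- config$n_breeds
  rho <- config$across_breed_qtl_correlation
  sigma <- matrix(rho, k, k); diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("equicorrelation ", rho, " is not positive semi-definite for ",
         k, " breeds")
  }
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  eff <- root %*% matrix(stats::rnorm(k * config$n_qtl), k)
  rownames(eff) <- config$breed_names
  population$qtl <- list(index = qidx, effects = eff)
  tbv0 <- true_breeding_values(population,
                               ids = population$pedigree$id[
                                 population$pedigree$breed %in%
                                   config$focal_breed])
  v0 <- stats::var(tbv0)
  if (!is.finite(v0) || v0 <= 0) {
    stop("no additive variance in the focal breed; cannot scale QTL effects")
  }
  population$qtl$effects <- eff *
    sqrt(config$trait_h2 * config$trait_sd^2 / v0)
  population$map$is_qtl <- seq_len(nrow(population$map)) %in% qidx
  population
}

#' True breeding values under the haplotype breed-of-origin effect regime
#'
#' The breeding value of an animal is the sum over its two haplotypes of
#' allele content times the QTL effect of the breed that haplotype segment
#' originates from, so crossbreds combine breed-specific effect regimes
#' segment by segment.
#'
#' @param population A `sim_population` with `$qtl` set.
#' @param ids Animal ids (default: all).
#' @return Named numeric vector of true breeding values in trait units.
#' @export
true_breeding_values <- function(population, ids = population$pedigree$id) {
  if (is.null(population$qtl)) stop("no QTL sampled yet; see sample_qtl()")
  qidx <- population$qtl$index
  eff <- population$qtl$effects
  n <- length(ids)
  tbv <- numeric(n)
  for (strand in 0:1) {
    rows <- 2L * ids - 1L + strand
    h <- population$hap[rows, qidx, drop = FALSE]
    o <- population$origin[rows, qidx, drop = FALSE]
    for (b in seq_len(nrow(eff))) {
      tbv <- tbv + (h * (o == b)) %*% eff[b, ]
    }
  }
  stats::setNames(as.numeric(tbv), ids)
}

## internal: append progeny of given sire/dam id vectors to a population
add_progeny <- function(pop, sires, dams, cohort, flocks, layout) {
  n_new <- length(sires)
  m <- ncol(pop$hap)
  hap_new <- matrix(0L, 2L * n_new, m)
  org_new <- matrix(0L, 2L * n_new, m)
  for (i in seq_len(n_new)) {
    sel_p <- gamete_selector(layout)
    sel_m <- gamete_selector(layout)
    sp <- 2L * sires[i] - 1L
    dp <- 2L * dams[i] - 1L
    jp <- sel_p == 2L
    jm <- sel_m == 2L
    a <- pop$hap[sp, ]; a[jp] <- pop$hap[sp + 1L, ][jp]
    o <- pop$origin[sp, ]; o[jp] <- pop$origin[sp + 1L, ][jp]
    hap_new[2L * i - 1L, ] <- a
    org_new[2L * i - 1L, ] <- o
    a <- pop$hap[dp, ]; a[jm] <- pop$hap[dp + 1L, ][jm]
    o <- pop$origin[dp, ]; o[jm] <- pop$origin[dp + 1L, ][jm]
    hap_new[2L * i, ] <- a
    org_new[2L * i, ] <- o
  }
  id0 <- nrow(pop$pedigree)
  gen <- max(pop$pedigree$generation[c(sires, dams)]) + 1L
  ped_new <- data.frame(id = id0 + seq_len(n_new), sire = sires, dam = dams,
                        sex = sample(c("M", "F"), n_new, replace = TRUE),
                        generation = gen, breed = NA_character_,
                        cohort = cohort, flock = flocks,
                        stringsAsFactors = FALSE)
  pop$hap <- rbind(pop$hap, hap_new)
  pop$origin <- rbind(pop$origin, org_new)
  pop$pedigree <- rbind(pop$pedigree, ped_new)
  pop
}

## internal: build paternal half-sib families until n_target progeny exist.
## Sires are used in shuffled order (recycled if exhausted); dams are sampled
## without replacement within a family.
make_families <- function(pop, sire_pool, dam_pool, n_target, cohort, config,
                          layout) {
  if (length(sire_pool) == 0L || length(dam_pool) == 0L) {
    stop("empty parent pool for cross '", cohort, "'")
  }
  fr <- config$family_size_range
  sire_order <- sample(sire_pool)
  si <- 0L
  fams <- list()
  total <- 0L
  while (total < n_target) {
    fs <- sample(seq.int(fr[1], fr[2]), 1L)
    fs <- min(fs, n_target - total, length(dam_pool))
    si <- si + 1L
    if (si > length(sire_order)) {
      sire_order <- sample(sire_pool)
      si <- 1L
    }
    fams[[length(fams) + 1L]] <- list(
      sire = sire_order[si],
      dams = sample(dam_pool, fs),
      flock = sample.int(config$n_flocks, 1L))
    total <- total + fs
  }
  sires <- unlist(lapply(fams, function(f) rep.int(f$sire, length(f$dams))))
  dams <- unlist(lapply(fams, function(f) f$dams))
  flocks <- unlist(lapply(fams, function(f) rep.int(f$flock, length(f$dams))))
  add_progeny(pop, sires, dams, cohort, flocks, layout)
}

#' Build the crossbreeding design
#'
#' Generates purebred focal-breed progeny, F1 crosses of another breed's
#' sires on purebred focal dams, and three-way crosses of a third breed's
#' sires on F1 dams, all in paternal half-sib families with sizes drawn from
#' `family_size_range`. Each family gets one flock. Validation sires are
#' withheld purebred sons of the family sires (one extra purebred male
#' offspring each, dam drawn from the breed's female pool, never
#' phenotyped): they are paternal half-sibs of reference progeny, so the
#' mean genomic relationship between a validation sire and the reference is
#' of the order of a percent, as between progeny-tested industry sires and
#' a research reference population, and the relatedness runs through the
#' paternal line.
#'
#' @param breeds A breed-labelled `sim_population` from [derive_breeds()]
#'   (QTL may be sampled before or after).
#' @param config The [sim_config()]; `config$design` or [default_design()]
#'   fixes cohort sizes.
#' @return The population grown with progeny cohorts; `$design_info` records
#'   families, cohorts and the validation sires per breed.
#' @export
build_design <- function(breeds, config) {
  stopifnot(inherits(breeds, "sim_population"))
  design <- if (is.null(config$design)) default_design(config) else
    config$design
  lay <- chromosome_layout(config)
  ped <- breeds$pedigree
  focal <- config$focal_breed
  pool <- function(breed, sex) {
    ped$id[!is.na(ped$breed) & ped$breed == breed & ped$sex == sex]
  }
  pop <- breeds
  pop <- make_families(pop, pool(focal, "M"), pool(focal, "F"),
                       design$n_purebred, "purebred", config, lay)
  for (cr in design$crosses) {
    sires <- pool(cr$sire_breed, "M")
    dams <- if (identical(cr$dam_type, "purebred")) pool(focal, "F") else
      pop$pedigree$id[pop$pedigree$cohort == cr$dam_type &
                        pop$pedigree$sex == "F"]
    if (length(dams) == 0L) {
      stop("empty dam pool for cross '", cr$name, "' (dam_type ",
           cr$dam_type, ")")
    }
    pop <- make_families(pop, sires, dams, cr$n, cr$name, config, lay)
  }
  ## validation sires: withheld purebred sons of the family sires
  nval <- design$n_validation_sires
  val <- list()
  ped2 <- pop$pedigree
  for (b in names(nval)) {
    if (nval[[b]] < 1L) next
    fathers <- if (b == focal) {
      unique(ped2$sire[ped2$cohort == "purebred"])
    } else {
      coh <- vapply(design$crosses, function(cr)
        if (cr$sire_breed == b) cr$name else NA_character_, character(1))
      unique(ped2$sire[ped2$cohort %in% coh[!is.na(coh)]])
    }
    if (length(fathers) == 0L) {
      stop("no family sires of breed ", b, " to derive validation sires from")
    }
    mothers_pool <- pool(b, "F")
    if (length(mothers_pool) == 0L) stop("no dams of breed ", b,
                                         " for validation sires")
    fathers_use <- sample(rep_len(sample(fathers), nval[[b]]))
    mothers_use <- sample(mothers_pool, nval[[b]],
                          replace = nval[[b]] > length(mothers_pool))
    pop <- add_progeny(pop, fathers_use, mothers_use, "validation_sire",
                       rep(NA_integer_, nval[[b]]), lay)
    new_ids <- utils::tail(pop$pedigree$id, nval[[b]])
    pop$pedigree$sex[match(new_ids, pop$pedigree$id)] <- "M"
    val[[b]] <- new_ids
  }
  pop$design_info <- list(design = design, validation_sires = val)
  pop
}

#' Simulate phenotypes under the evaluation model
#'
#' Generates records `y = mu + fixed + breed means + g + w_dam + s_sire:flock
#' + e` where `g` is the true breeding value, `w` a random maternal effect
#' shared by progeny of one dam, `s` a sire-by-flock interaction and `e`
#' residual; variances follow the config ratios on the `trait_sd^2` scale.
#' Fixed effects are birth type, rearing type, gender, an age covariate, a
#' correlated weight covariate and contemporary group (site x birth year x
#' management group).
#'
#' @param population Population with QTL and design cohorts.
#' @param config The [sim_config()].
#' @param animals Animal ids to phenotype (default: all progeny except the
#'   withheld validation sires).
#' @param include_fixed Logical; turn off to get `y = mu + g (+ w + s + e)`
#'   with no fixed-effect structure.
#' @return A data.frame of records (one row per animal) with the phenotype
#'   `y`, all model covariates and the true components as attributes.
#' @export
simulate_phenotypes <- function(population, config, animals = NULL,
                                include_fixed = TRUE) {
  ped <- population$pedigree
  if (is.null(animals)) {
    animals <- ped$id[ped$generation > 0L & ped$cohort != "validation_sire"]
  }
  if (length(animals) == 0L) stop("no animals to phenotype")
  idx <- match(animals, ped$id)
  if (anyNA(idx)) stop("unknown animal ids")
  mr <- config$maternal_variance_ratio
  sfr <- config$sire_flock_variance_ratio
  if (mr > 0 && anyNA(ped$dam[idx])) {
    stop("maternal effect requested but some animals have no recorded dam")
  }
  sdp <- config$trait_sd
  g <- true_breeding_values(population, animals)

  n <- length(animals)
  birth_type <- sample.int(3L, n, replace = TRUE, prob = c(0.35, 0.55, 0.10))
  rearing_type <- pmin(birth_type,
                       sample.int(3L, n, replace = TRUE,
                                  prob = c(0.45, 0.45, 0.10)))
  gender <- ped$sex[idx]
  age <- round(stats::runif(n, 125, 300))
  weight <- 40 + 0.05 * (age - 212) + stats::rnorm(n, 0, 3)
  site <- ped$flock[idx]
  site[is.na(site)] <- 1L
  birth_year <- sample.int(2L, n, replace = TRUE)
  mgmt <- sample.int(2L, n, replace = TRUE)
  cg <- interaction(site, birth_year, mgmt, drop = TRUE)

  fixed <- numeric(n)
  if (include_fixed) {
    bt_eff <- c(0, -0.4, -0.8) * sdp
    rt_eff <- c(0, -0.3, -0.6) * sdp
    sex_eff <- c(M = 0.2, F = 0) * sdp
    cg_eff <- stats::rnorm(nlevels(cg), 0, 0.5 * sdp)
    beta_age <- 0.3 * sdp / 52.4
    fixed <- bt_eff[birth_type] + rt_eff[rearing_type] + sex_eff[gender] +
      beta_age * (age - mean(age)) + cg_eff[as.integer(cg)]
  }
  breed_contrib <- numeric(n)
  if (any(config$breed_effects != 0)) {
    q <- breed_proportions(ped, max_depth = 10L)
    q <- q[match(animals, q$animal), config$breed_names, drop = FALSE]
    breed_contrib <- as.numeric(as.matrix(q) %*% config$breed_effects)
  }
  w <- numeric(n)
  if (mr > 0) {
    dams <- ped$dam[idx]
    ud <- unique(dams)
    w_dam <- stats::setNames(stats::rnorm(length(ud), 0, sqrt(mr) * sdp), ud)
    w <- w_dam[as.character(dams)]
  }
  s <- numeric(n)
  if (sfr > 0) {
    sf <- paste(ped$sire[idx], site, sep = ":")
    usf <- unique(sf)
    s_eff <- stats::setNames(stats::rnorm(length(usf), 0, sqrt(sfr) * sdp),
                             usf)
    s <- s_eff[sf]
  }
  res_var <- max(0, 1 - config$trait_h2 - mr - sfr) * sdp^2
  e <- if (res_var > 0) stats::rnorm(n, 0, sqrt(res_var)) else numeric(n)
  y <- config$trait_mean + fixed + breed_contrib + as.numeric(g) + w + s + e
  rec <- data.frame(animal = animals, y = y, birth_type = birth_type,
                    rearing_type = rearing_type, gender = gender, age = age,
                    weight = weight, site = site, birth_year = birth_year,
                    mgmt = mgmt, cg = as.character(cg),
                    flock = site, sire = ped$sire[idx], dam = ped$dam[idx],
                    stringsAsFactors = FALSE)
  attr(rec, "true_components") <- list(g = as.numeric(g), w = w, s = s, e = e,
                                       fixed = fixed,
                                       breed_contrib = breed_contrib)
  rec
}

#' Simulate progeny-test EBVs at a target accuracy
#'
#' Produces estimated breeding values whose correlation with the true
#' breeding values converges to the stated accuracy `r` (correlation scale,
#' not reliability r-squared): `EBV = r z + sqrt(1 - r^2) eps` on the
#' standardized scale, rescaled back to trait units.
#'
#' @param true_bv Numeric vector of true breeding values.
#' @param reliability Target accuracy r in (0, 1], scalar or per-animal.
#' @param seed Optional integer seed.
#' @return data.frame with columns `animal` (names of `true_bv` or index),
#'   `ebv` and `accuracy`.
#' @export
simulate_progeny_test_ebv <- function(true_bv, reliability, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_bv)
  r <- rep_len(reliability, n)
  if (any(r <= 0 | r > 1)) stop("reliability (accuracy r) must be in (0, 1]")
  sdv <- stats::sd(true_bv)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  z <- (true_bv - mean(true_bv)) / sdv
  ebv <- mean(true_bv) + sdv * (r * z + sqrt(1 - r^2) * stats::rnorm(n))
  ids <- if (!is.null(names(true_bv))) names(true_bv) else seq_len(n)
  data.frame(animal = ids, ebv = as.numeric(ebv), accuracy = r,
             stringsAsFactors = FALSE)
}

#' Run the full simulation pipeline
#'
#' Convenience wrapper: founders, breed divergence, QTL sampling, mating
#' design and phenotypes, all driven by one seed. Identical configs give
#' bit-identical populations.
#'
#' @param config A [sim_config()].
#' @return List with `population` (the grown `sim_population`) and `records`
#'   (phenotypes for all progeny).
#' @export
simulate_sheep_population <- function(config) {
  base <- simulate_founders(config)
  pop <- derive_breeds(base, config)
  pop <- sample_qtl(pop, config)
  pop <- build_design(pop, config)
  rec <- simulate_phenotypes(pop, config)
  list(population = pop, records = rec)
}

#' Extract a genotype table from a simulated population
#'
#' Sums the two haplotypes into 0/1/2 dosages. By default QTL are excluded
#' from the panel (see `qtl_on_panel` in [sim_config()]).
#'
#' @param population A `sim_population`.
#' @param ids Animal ids (default all).
#' @param include_qtl Logical; default taken from the population's config.
#' @return A [genotype_table()].
#' @export
extract_genotypes <- function(population, ids = population$pedigree$id,
                              include_qtl = NULL) {
  if (is.null(include_qtl)) {
    include_qtl <- isTRUE(population$config$qtl_on_panel) ||
      is.null(population$qtl)
  }
  keep <- if (include_qtl) seq_len(nrow(population$map)) else
    which(!population$map$is_qtl)
  geno <- population$hap[2L * ids - 1L, keep, drop = FALSE] +
    population$hap[2L * ids, keep, drop = FALSE]
  genotype_table(geno = geno, map = population$map[keep, 1:3], ids = ids)
}

#' Extract phased haplotypes (simulator truth)
#'
#' @param population A `sim_population`.
#' @param ids Animal ids.
#' @param include_qtl As in [extract_genotypes()].
#' @return List with `paternal` and `maternal` 0/1 matrices (animals x SNPs,
#'   dimnames set) and the corresponding `map`.
#' @export
extract_haplotypes <- function(population, ids = population$pedigree$id,
                               include_qtl = NULL) {
  if (is.null(include_qtl)) {
    include_qtl <- isTRUE(population$config$qtl_on_panel) ||
      is.null(population$qtl)
  }
  keep <- if (include_qtl) seq_len(nrow(population$map)) else
    which(!population$map$is_qtl)
  pat <- population$hap[2L * ids - 1L, keep, drop = FALSE]
  mat <- population$hap[2L * ids, keep, drop = FALSE]
  dimnames(pat) <- dimnames(mat) <-
    list(as.character(ids), population$map$snp[keep])
  list(paternal = pat, maternal = mat, map = population$map[keep, 1:3])
}
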