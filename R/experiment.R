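#' Scenario configuration
#'
#' Describes a full comparison experiment: the simulation settings, the
#' reference-population designs to contrast, the GRM flavors, the target
#' breeds whose validation sires are predicted, and the replicate seeds.
#'
#' @param sim A [sim_config()].
#' @param designs List of reference designs; each a list with `name` and
#'   `type` in `"purebred"` (field `n`), `"crossbred"` (fields `breed`,
#'   `threshold`, optional `n`) or `"combined"` (both sets of fields).
#' @param grm_flavors Subset of `c("G1", "G2")`.
#' @param target_breeds Breeds whose validation sires are evaluated.
#' @param seeds Integer vector of replicate seeds.
#' @param output_dir Optional directory for result files.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(sim, designs, grm_flavors = c("G1", "G2"),
                            target_breeds = NULL, seeds = 1:10,
                            output_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (length(designs) == 0L) stop("designs must be non-empty")
  nms <- vapply(designs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicated design names")
  if (is.null(target_breeds)) {
    target_breeds <- names(default_design(sim)$n_validation_sires)
  }
  bad <- setdiff(target_breeds, sim$breed_names)
  if (length(bad)) stop("unknown target breeds: ", paste(bad, collapse = ", "))
  if (!all(grm_flavors %in% c("G1", "G2"))) stop("unknown GRM flavor")
  structure(list(sim = sim, designs = designs, grm_flavors = grm_flavors,
                 target_breeds = target_breeds, seeds = as.integer(seeds),
                 output_dir = output_dir),
            class = "scenario_config")
}

#' Desk-scale preset mirroring the purebred/crossbred comparison
#'
#' Three nested purebred focal-breed reference sizes, a crossbred-only
#' reference with the same number of focal-breed haplotypes as the smallest
#' purebred reference, and a combined design; evaluated for the focal breed
#' and the crossbred sire breed with both GRM flavors.
#'
#' @param seed Base seed.
#' @param seeds Replicate seeds.
#' @param purebred_sizes Reference sizes for the purebred designs.
#' @param crossbred_n Crossbred reference size (animals).
#' @param ... Overrides for [sheep_sim_config()].
#' @return A `scenario_config`.
#' @export
sheep_scenario_preset <- function(seed = 1L, seeds = 1:10,
                                  purebred_sizes = c(200L, 400L, 600L),
                                  crossbred_n = 400L, ...) {
  sim <- sheep_sim_config(seed = seed, ...)
  cross_breed <- setdiff(sim$breed_names, sim$focal_breed)[1]
  designs <- c(
    lapply(purebred_sizes, function(n)
      list(name = paste0("P", n), type = "purebred", n = n)),
    list(list(name = "CB", type = "crossbred", breed = cross_breed,
              threshold = 0.45, n = crossbred_n),
         list(name = paste0("CB+P", purebred_sizes[2]), type = "combined",
              breed = cross_breed, threshold = 0.45, n = crossbred_n,
              n_purebred = purebred_sizes[2])))
  scenario_config(sim = sim, designs = designs,
                  target_breeds = c(sim$focal_breed, cross_breed),
                  seeds = seeds)
}

## internal: reference animal ids for one design, given per-seed materials
design_reference <- function(design, purebred_order, Q, records) {
  ids <- switch(
    design$type,
    purebred = purebred_order[seq_len(min(design$n, length(purebred_order)))],
    crossbred = ,
    combined = {
      sel <- select_crossbred_reference(Q, design$breed, design$threshold)
      sel <- intersect(sel, records$animal)
      if (!is.null(design$n) && length(sel) > design$n) {
        sel <- sel[seq_len(design$n)]
      }
      if (design$type == "combined") {
        sel <- union(sel, purebred_order[
          seq_len(min(design$n_purebred, length(purebred_order)))])
      }
      sel
    },
    stop("unknown design type: ", design$type)
  )
  if (length(ids) == 0L) stop("design '", design$name, "' selected no animals")
  ids
}

## internal: fit one design x flavor cell and return accuracies per breed
fit_cell <- function(pop, cfg, kept_snps, records, Q, origins, ref_ids,
                     val, flavor) {
  sim <- cfg$sim
  val_ids <- unlist(lapply(val, `[[`, "animal"), use.names = FALSE)
  val_ids <- as.integer(val_ids)
  n_ref_used <- length(ref_ids)
  if (flavor == "G2") {
    ok <- origins$animal[origins$g2_eligible]
    ref_ids <- intersect(ref_ids, ok)
    if (length(ref_ids) < 10L) stop("too few G2-eligible reference animals")
  }
  all_ids <- c(setdiff(ref_ids, val_ids), val_ids)
  if (flavor == "G1") {
    gt <- extract_genotypes(pop, all_ids)
    gt <- subset_genotype_table(gt, snps = match(kept_snps, gt$map$snp))
    p <- allele_frequencies(gt, subset = as.character(ref_ids))
    poly <- which(p > 0 & p < 1)
    G <- build_g1(subset_genotype_table(gt, snps = poly), p[poly])
  } else {
    hp <- extract_haplotypes(pop, all_ids)
    keep <- match(kept_snps, hp$map$snp)
    oi <- origins[match(all_ids, origins$animal), ]
    hap_all <- rbind(hp$paternal[, keep, drop = FALSE],
                     hp$maternal[, keep, drop = FALSE])
    lab_all <- c(oi$paternal_breed, oi$maternal_breed)
    bf <- breed_allele_frequencies(hap_all, lab_all)
    G <- build_g2(hp$paternal[, keep, drop = FALSE],
                  hp$maternal[, keep, drop = FALSE],
                  oi$paternal_breed, oi$maternal_breed, bf,
                  ids = as.character(all_ids))
  }
  rec <- records[records$animal %in% ref_ids, , drop = FALSE]
  trim <- trim_phenotype_outliers(rec, k_sd = 4)
  rec <- trim$kept
  des <- build_design_matrices(
    rec, animal_ids = as.character(all_ids),
    fixed = ~ factor(birth_type) + factor(rearing_type) + gender + age + cg,
    Q = Q[, setdiff(names(Q), "unknown"), drop = FALSE],
    reference_breed = sim$focal_breed,
    maternal = sim$maternal_variance_ratio > 0,
    sire_flock = sim$sire_flock_variance_ratio > 0)
  sdp2 <- sim$trait_sd^2
  vc <- list(g = sim$trait_h2 * sdp2,
             m = sim$maternal_variance_ratio * sdp2,
             sf = sim$sire_flock_variance_ratio * sdp2,
             e = (1 - sim$trait_h2 - sim$maternal_variance_ratio -
                    sim$sire_flock_variance_ratio) * sdp2)
  fit <- solve_mme(des, G, vc)
  out <- list()
  for (b in names(val)) {
    vb <- val[[b]]
    gbv <- fit$gbv[as.character(vb$animal)]
    acc <- if (length(vb$animal) >= 3 && stats::sd(gbv) > 0 &&
               stats::sd(vb$ebv) > 0) stats::cor(gbv, vb$ebv) else NA_real_
    out[[b]] <- data.frame(breed = b, accuracy = acc,
                           n_validation = length(vb$animal),
                           n_reference = n_ref_used,
                           n_reference_fitted = length(unique(rec$animal)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run a reference-design comparison scenario
#'
#' For every replicate seed: simulate the multi-breed population and its
#' crossbreeding design, apply SNP QC (HWE stratified within purebred
#' groups to avoid Wahlund false positives), derive the pedigree Q matrix
#' and haplotype breed-of-origin labels, simulate progeny-test EBVs for the
#' validation sires, and then, for every design x GRM flavor, build the
#' relationship matrix, solve the mixed model with maternal and
#' sire-by-flock terms, and record the within-breed validation accuracy.
#' A failing cell is recorded with its error message and the run continues.
#'
#' @param config A [scenario_config()].
#' @return An object of class `scenario_result`: `results` (one row per
#'   seed x design x flavor x breed), `summary` (means over seeds run
#'   through [summarize_scenarios()]), `failures`, `manifest`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  rows <- list()
  failures <- list()
  for (seed in config$seeds) {
    sim <- config$sim
    sim$seed <- (sim$seed + 104729L * as.integer(seed)) %% 2147483647L
    piece <- simulate_sheep_population(sim)
    pop <- piece$population
    records <- piece$records
    ped <- pop$pedigree

    ## SNP QC on the full genotyped set; HWE within purebred strata only
    gt <- extract_genotypes(pop)
    strata <- ped$breed
    strata[ped$cohort == "purebred"] <- sim$focal_breed
    qc <- qc_snps(gt, stratify_hwe_by = strata)
    kept_snps <- qc$table$map$snp

    Q <- breed_proportions(ped, max_depth = 6L)
    origins <- assign_haplotype_origin(ped, Q, purity_threshold = 0.97)

    ## validation sires with progeny-test EBVs; reliability floor applied
    val <- list()
    for (b in config$target_breeds) {
      sires <- pop$design_info$validation_sires[[b]]
      if (is.null(sires) || length(sires) == 0L) next
      rel <- stats::runif(length(sires), 0.60, 0.98)
      keep <- rel >= sim$validation_reliability_floor
      sires <- sires[keep]
      tbv <- true_breeding_values(pop, sires)
      ebv <- simulate_progeny_test_ebv(tbv, rel[keep])
      val[[b]] <- data.frame(animal = sires, ebv = ebv$ebv,
                             accuracy = ebv$accuracy)
    }
    purebred_pool <- intersect(ped$id[ped$cohort == "purebred"],
                               records$animal)
    purebred_order <- sample(purebred_pool)

    for (design in config$designs) {
      ref_ids <- design_reference(design, purebred_order, Q, records)
      for (flavor in config$grm_flavors) {
        cell <- tryCatch(
          fit_cell(pop, config, kept_snps, records, Q, origins, ref_ids,
                   val, flavor),
          error = function(e) e)
        key <- paste(seed, design$name, flavor, sep = "/")
        if (inherits(cell, "error")) {
          failures[[key]] <- conditionMessage(cell)
        } else {
          cell$seed <- seed
          cell$design <- design$name
          cell$grm <- flavor
          rows[[key]] <- cell
        }
      }
    }
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summary <- NULL
  if (!is.null(results)) {
    agg <- stats::aggregate(accuracy ~ design + grm + breed, data = results,
                            FUN = mean, na.rm = TRUE)
    nagg <- stats::aggregate(n_validation ~ design + grm + breed,
                             data = results, FUN = stats::median)
    agg$n <- nagg$n_validation
    agg <- agg[order(match(agg$design,
                           vapply(config$designs, `[[`, character(1),
                                  "name"))), ]
    summary <- summarize_scenarios(agg)
  }
  res <- structure(list(results = results, summary = summary,
                        failures = failures,
                        manifest = list(seeds = config$seeds,
                                        designs = vapply(config$designs,
                                                         `[[`, character(1),
                                                         "name"),
                                        grm_flavors = config$grm_flavors,
                                        target_breeds = config$target_breeds,
                                        sim_seed = config$sim$seed)),
                   class = "scenario_result")
  if (!is.null(config$output_dir)) write_scenario_result(res,
                                                         config$output_dir)
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario_result:", nrow(x$results) %||% 0L, "cells,",
      length(x$failures), "failures\n")
  if (!is.null(x$summary)) {
    cat(format_scenario_table(x$summary), sep = "\n")
  }
  invisible(x)
}

#' Write scenario results to disk
#'
#' @param result A `scenario_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_scenario_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  if (!is.null(result$summary)) {
    utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                     row.names = FALSE)
    writeLines(format_scenario_table(result$summary),
               file.path(dir, "summary.md"))
  }
  jsonlite::write_json(c(result$manifest, list(failures = result$failures)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a scenario config from YAML
#'
#' Expects top-level keys `sim` (arguments to [sim_config()]), `designs`,
#' and optionally `grm_flavors`, `target_breeds`, `seeds`, `output_dir`.
#'
#' @param path YAML file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$sim %||% list())
  scenario_config(sim = sim, designs = raw$designs,
                  grm_flavors = raw$grm_flavors %||% c("G1", "G2"),
                  target_breeds = raw$target_breeds,
                  seeds = raw$seeds %||% 1:10,
                  output_dir = raw$output_dir)
}

#' Export a simulated population to standard file formats
#'
#' Writes PLINK ped/map genotypes, the pedigree, phenotype records,
#' validation EBVs and a truth ledger (config echo, QTL, breed
#' frequencies) to a directory.
#'
#' @param population A `sim_population`.
#' @param records Phenotype records from [simulate_phenotypes()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
export_population <- function(population, records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(extract_genotypes(population), file.path(dir, "genotypes"))
  utils::write.csv(population$pedigree, file.path(dir, "pedigree.csv"),
                   row.names = FALSE)
  utils::write.csv(records, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  cfg <- population$config
  truth <- list(config = unclass(cfg),
                qtl_index = population$qtl$index,
                qtl_effects = population$qtl$effects,
                breed_freq = population$breed_freq)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
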