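#' Pedigree-based breed proportions (Q matrix)
#'
#' Each animal's breed composition is the recursive average of its parents'
#' compositions; labelled founders are unit vectors on their breed and
#' unlabelled founders (or ancestors beyond `max_depth` generations)
#' contribute to an `"unknown"` pseudo-breed, keeping every row an honest
#' partition of the genome.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` and a founder
#'   breed label column `breed` (`NA` for non-founders/unknown).
#' @param max_depth Pedigree depth used (generations; default 6).
#' @return data.frame: `animal`, one proportion column per breed (plus
#'   `unknown` when needed); rows sum to 1.
#' @export
breed_proportions <- function(pedigree, max_depth = 6L) {
  ped <- pedigree
  req <- c("id", "sire", "dam", "breed")
  if (!all(req %in% names(ped))) {
    stop("pedigree needs columns ", paste(req, collapse = ", "))
  }
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  if (anyDuplicated(ped$id)) stop("duplicated animal ids in pedigree")
  breeds <- sort(unique(ped$breed[!is.na(ped$breed)]))
  cols <- c(breeds, "unknown")
  k <- length(cols)
  q <- matrix(NA_real_, nrow(ped), k, dimnames = list(ped$id, cols))
  unknown_row <- c(rep(0, k - 1L), 1)
  sire_i <- idx[as.character(ped$sire)]
  dam_i <- idx[as.character(ped$dam)]
  if (any(!is.na(ped$sire) & is.na(sire_i)) ||
      any(!is.na(ped$dam) & is.na(dam_i))) {
    stop("pedigree refers to parents that are absent from the id column")
  }
  # cycle check: DFS over the parent graph (white/grey/black colouring)
  colour <- integer(nrow(ped))
  visit <- function(i) {
    if (is.na(i) || colour[i] == 2L) return(invisible())
    if (colour[i] == 1L) stop("pedigree cycle detected at id ", ped$id[i])
    colour[i] <<- 1L
    visit(sire_i[i])
    visit(dam_i[i])
    colour[i] <<- 2L
    invisible()
  }
  for (i in seq_len(nrow(ped))) visit(i)

  comp <- function(i, depth) {
    if (is.na(i) || depth > max_depth) return(unknown_row)
    if (!is.na(ped$breed[i])) {
      row <- rep(0, k)
      row[match(ped$breed[i], cols)] <- 1
      return(row)
    }
    if (is.na(sire_i[i]) && is.na(dam_i[i])) return(unknown_row)
    (comp(sire_i[i], depth + 1L) + comp(dam_i[i], depth + 1L)) / 2
  }
  for (i in seq_len(nrow(ped))) q[i, ] <- comp(i, 0L)
  stopifnot(all(abs(rowSums(q) - 1) < 1e-12))
  out <- data.frame(animal = ped$id, q, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (all(out$unknown == 0)) out$unknown <- NULL
  attr(out, "max_depth") <- max_depth
  out
}

#' Select crossbred reference animals by breed proportion
#'
#' Retains animals whose proportion of `breed` is at least `threshold`,
#' excluding purebreds of any other breed.
#'
#' @param compositions Output of [breed_proportions()].
#' @param breed Breed label.
#' @param threshold Minimum proportion (e.g. 0.45, or 0.35 for a rarer
#'   breed).
#' @param purebred_cut Proportion at or above which an animal counts as
#'   purebred of a breed (default 1).
#' @return Character/integer vector of selected animal ids.
#' @export
select_crossbred_reference <- function(compositions, breed, threshold,
                                       purebred_cut = 1) {
  qcols <- setdiff(names(compositions), "animal")
  if (!breed %in% qcols) stop("unknown breed label: ", breed)
  p <- compositions[[breed]]
  other <- as.matrix(compositions[, setdiff(qcols, breed), drop = FALSE])
  pure_other <- if (ncol(other)) apply(other, 1, max) >= purebred_cut else
    rep(FALSE, nrow(compositions))
  compositions$animal[p >= threshold & !pure_other]
}

#' Assign breed-of-origin labels to parental haplotypes
#'
#' A haplotype is labelled with its parent's majority breed when that parent
#' is more than `purity_threshold` purebred; otherwise it is `"mixed"`.
#' Founders carrying their own breed label (purebred by construction) are
#' labelled with that breed directly. Animals with any mixed haplotype are
#' flagged ineligible for the gametic breed-specific-frequency relationship
#' matrix (G2).
#'
#' @param pedigree Pedigree data.frame (`id`, `sire`, `dam`, `breed`).
#' @param compositions Output of [breed_proportions()] for (at least) every
#'   parent.
#' @param purity_threshold Minimum parental purity (default 0.97).
#' @return data.frame: `animal`, `paternal_breed`, `maternal_breed`,
#'   `paternal_purity`, `maternal_purity`, `g2_eligible`.
#' @export
assign_haplotype_origin <- function(pedigree, compositions,
                                    purity_threshold = 0.97) {
  qcols <- setdiff(names(compositions), c("animal", "unknown"))
  qm <- as.matrix(compositions[, qcols, drop = FALSE])
  rownames(qm) <- compositions$animal
  parent_label <- function(parent) {
    out <- data.frame(breed = rep("mixed", length(parent)),
                      purity = rep(0, length(parent)),
                      stringsAsFactors = FALSE)
    known <- !is.na(parent) & as.character(parent) %in% rownames(qm)
    if (any(known)) {
      sub <- qm[as.character(parent[known]), , drop = FALSE]
      best <- max.col(sub, ties.method = "first")
      purity <- sub[cbind(seq_len(nrow(sub)), best)]
      lab <- colnames(sub)[best]
      lab[purity <= purity_threshold] <- "mixed"
      out$breed[known] <- lab
      out$purity[known] <- purity
    }
    out
  }
  pat <- parent_label(pedigree$sire)
  mat <- parent_label(pedigree$dam)
  if ("breed" %in% names(pedigree)) {
    own <- !is.na(pedigree$breed)
    pat$breed[own] <- mat$breed[own] <- pedigree$breed[own]
    pat$purity[own] <- mat$purity[own] <- 1
  }
  data.frame(animal = pedigree$id,
             paternal_breed = pat$breed, maternal_breed = mat$breed,
             paternal_purity = pat$purity, maternal_purity = mat$purity,
             g2_eligible = pat$breed != "mixed" & mat$breed != "mixed",
             stringsAsFactors = FALSE)
}

#' Rule-based phasing from parental genotypes
#'
#' Resolves the parental origin of offspring alleles locus by locus using
#' only trio genotypes: a homozygous parent always transmits its allele, and
#' a heterozygous offspring of one homozygous parent is fully resolved;
#' loci where both parents and the offspring are heterozygous stay
#' unresolved (`NA`). Mendelian-inconsistent loci are set missing and
#' counted.
#'
#' @param genotypes A [genotype_table()] containing offspring and both
#'   parents.
#' @param pedigree Pedigree rows for the offspring to phase (`id`, `sire`,
#'   `dam`).
#' @return List with `paternal`/`maternal` allele matrices (0/1/NA, animals
#'   x SNPs), `resolution_fraction` and `n_mendel_errors`.
#' @export
rule_based_phase <- function(genotypes, pedigree) {
  g <- genotypes$geno
  ids <- genotypes$ids
  off <- as.character(pedigree$id)
  if (!all(off %in% ids)) stop("offspring missing from genotype table")
  if (anyNA(pedigree$sire) || anyNA(pedigree$dam) ||
      !all(as.character(pedigree$sire) %in% ids) ||
      !all(as.character(pedigree$dam) %in% ids)) {
    stop("parental genotypes must be available for every offspring")
  }
  go <- g[off, , drop = FALSE]
  gs <- g[as.character(pedigree$sire), , drop = FALSE]
  gd <- g[as.character(pedigree$dam), , drop = FALSE]
  pat <- mat <- matrix(NA_real_, nrow(go), ncol(go),
                       dimnames = dimnames(go))
  # homozygous offspring: both strands known
  hom0 <- !is.na(go) & go == 0
  hom2 <- !is.na(go) & go == 2
  pat[hom0] <- 0; mat[hom0] <- 0
  pat[hom2] <- 1; mat[hom2] <- 1
  # heterozygous offspring: resolved when a parent is homozygous
  het <- !is.na(go) & go == 1
  s_hom0 <- !is.na(gs) & gs == 0; s_hom2 <- !is.na(gs) & gs == 2
  d_hom0 <- !is.na(gd) & gd == 0; d_hom2 <- !is.na(gd) & gd == 2
  r <- het & s_hom0; pat[r] <- 0; mat[r] <- 1
  r <- het & s_hom2; pat[r] <- 1; mat[r] <- 0
  r <- het & d_hom0 & is.na(pat); pat[r] <- 1; mat[r] <- 0
  r <- het & d_hom2 & is.na(pat); pat[r] <- 0; mat[r] <- 1
  # Mendelian inconsistencies: offspring allele impossible given a parent
  err <- (hom0 & (s_hom2 | d_hom2)) | (hom2 & (s_hom0 | d_hom0)) |
    (het & ((s_hom0 & d_hom0) | (s_hom2 & d_hom2)))
  n_err <- sum(err)
  pat[err] <- NA; mat[err] <- NA
  called <- !is.na(go) & !err
  list(paternal = pat, maternal = mat,
       resolution_fraction = sum(!is.na(pat)) / max(1, sum(called)),
       n_mendel_errors = n_err)
}
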