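new_grmatrix <- function(values, ids, flavor, freqs, denominator,
                         meta = list()) {
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = as.character(ids), flavor = flavor,
                 allele_frequencies_used = freqs, denominator = denominator,
                 meta = meta),
            class = "grmatrix")
}

#' @export
print.grmatrix <- function(x, ...) {
  cat("grmatrix (", x$flavor, "): ", length(x$ids), " animals, denominator ",
      signif(sum(x$denominator), 6), "\n", sep = "")
  invisible(x)
}

#' @export
dim.grmatrix <- function(x) dim(x$values)

#' Observed allele frequencies
#'
#' Frequency of the second allele per SNP: mean dosage over non-missing
#' calls divided by two, computed on an optional subset of samples (for
#' GBLUP these are conventionally the reference animals).
#'
#' @param table A [genotype_table()].
#' @param subset Optional sample ids or indices.
#' @return Named numeric vector of frequencies.
#' @export
allele_frequencies <- function(table, subset = NULL) {
  geno <- table$geno
  if (!is.null(subset)) {
    rows <- if (is.character(subset)) match(subset, table$ids) else subset
    if (anyNA(rows)) stop("subset contains unknown sample ids")
    if (length(rows) == 0L) stop("empty subset")
    geno <- geno[rows, , drop = FALSE]
  }
  p <- colMeans(geno, na.rm = TRUE) / 2
  if (anyNA(p)) {
    stop("SNP(s) with no calls in the subset: ",
         paste(colnames(geno)[is.na(p)], collapse = ", "))
  }
  p
}

#' Breed-specific allele frequencies from labelled haplotypes
#'
#' Frequency of the second allele among the haplotypes labelled with each
#' breed.
#'
#' @param haplotypes 0/1 matrix, haplotypes in rows, SNPs in columns.
#' @param breed_labels Breed label per haplotype row.
#' @param breeds Breeds to report (default: those present); a requested
#'   breed with no labelled haplotype is an error.
#' @return Matrix breeds x SNPs.
#' @export
breed_allele_frequencies <- function(haplotypes, breed_labels,
                                     breeds = NULL) {
  stopifnot(nrow(haplotypes) == length(breed_labels))
  if (is.null(breeds)) breeds <- sort(unique(breed_labels))
  empty <- setdiff(breeds, breed_labels[!is.na(breed_labels)])
  if (length(empty)) stop("breed with zero haplotypes: ",
                          paste(empty, collapse = ", "))
  out <- t(vapply(breeds, function(b)
    colMeans(haplotypes[breed_labels == b, , drop = FALSE]),
    numeric(ncol(haplotypes))))
  rownames(out) <- breeds
  out
}

#' Genotype-based genomic relationship matrix (G1)
#'
#' VanRaden's first method: `G1 = Z Z' / (2 * sum p_j (1 - p_j))` with
#' `Z = M - 2 p` where `M` holds 0/1/2 second-allele dosages and `p` the
#' allele frequencies used for centering. With frequencies observed on the
#' same animals, each column of `Z` has zero mean, so rows of `G1` sum to
#' zero exactly.
#'
#' @param table A [genotype_table()] with no missing calls (impute first),
#'   or a plain dosage matrix.
#' @param freqs Allele frequencies for centering and scaling; default:
#'   observed frequencies of the table itself. All must lie strictly in
#'   (0, 1).
#' @return A `grmatrix` (flavor "G1").
#' @export
build_g1 <- function(table, freqs = NULL) {
  geno <- if (inherits(table, "genotype_table")) table$geno else
    as.matrix(table)
  if (anyNA(geno)) stop("missing genotypes; run impute_missing() first")
  if (is.null(freqs)) freqs <- colMeans(geno) / 2
  if (length(freqs) != ncol(geno)) stop("freqs length mismatch")
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("allele frequencies at 0 or 1; remove monomorphic SNPs first")
  }
  z <- sweep(geno, 2L, 2 * freqs)
  denom <- 2 * sum(freqs * (1 - freqs))
  g <- tcrossprod(z) / denom
  ids <- if (inherits(table, "genotype_table")) table$ids else
    rownames(geno) %||% as.character(seq_len(nrow(geno)))
  new_grmatrix(g, ids, "G1", freqs, denom)
}

## internal: one gametic matrix. Each haplotype row is centered by the
## breed-of-origin frequency; the common denominator is the haplotype-count
## weighted average over breeds of sum_j p_bj (1 - p_bj), with SNPs that are
## monomorphic within a breed excluded from that breed's term.
gametic_z <- function(hap, labels, breed_freqs) {
  miss <- setdiff(unique(labels), rownames(breed_freqs))
  if (length(miss)) {
    stop("haplotypes with unlabelled or unknown breed: ",
         paste(miss, collapse = ", "))
  }
  p <- breed_freqs[labels, , drop = FALSE]
  z <- hap - p
  s_b <- apply(breed_freqs, 1, function(pb) sum(pb * (1 - pb)))
  w <- table(factor(labels, levels = rownames(breed_freqs)))
  denom <- sum(s_b * as.numeric(w)) / sum(w)
  list(z = z, denom = denom)
}

#' Gametic breed-specific-frequency relationship matrix (G2)
#'
#' The gametic version of VanRaden's algorithm with breed-of-origin allele
#' frequencies: `G2_i = Z_i Z_i' / sum p_j (1 - p_j)` is computed separately
#' from the paternal (`i = 1`) and maternal (`i = 2`) haplotypes, where
#' `Z_i` holds 0/1 alleles centered by the allele frequency of the breed
#' each haplotype originates from, and `G2 = (G2_1 + G2_2) / 2`. Because
#' several breeds can contribute haplotypes to one gametic matrix, the
#' denominator is the haplotype-count weighted average over breeds of
#' `sum_j p_bj (1 - p_bj)` (recorded in the metadata); SNPs monomorphic
#' within a breed contribute zero centering variance and are excluded from
#' that breed's denominator term.
#'
#' @param paternal,maternal 0/1 haplotype matrices (animals x SNPs).
#' @param paternal_breed,maternal_breed Breed label per animal for each
#'   haplotype (no `"mixed"` allowed; exclude such animals first).
#' @param breed_freqs Breeds x SNPs frequency matrix, e.g. from
#'   [breed_allele_frequencies()].
#' @param ids Animal ids.
#' @param full_gametic Logical; if `TRUE` include the paternal x maternal
#'   cross-gamete products, i.e. `(Z1 + Z2)(Z1 + Z2)' / (denom1 + denom2)`.
#'   Off by default: the printed form omits cross-gamete terms.
#' @return A `grmatrix` (flavor "G2" or "G2full") with the per-gamete
#'   matrices in `$meta`.
#' @export
build_g2 <- function(paternal, maternal, paternal_breed, maternal_breed,
                     breed_freqs, ids = rownames(paternal),
                     full_gametic = FALSE) {
  stopifnot(all(dim(paternal) == dim(maternal)))
  if (anyNA(paternal) || anyNA(maternal)) {
    stop("haplotypes contain missing alleles")
  }
  bad <- paternal_breed == "mixed" | maternal_breed == "mixed" |
    is.na(paternal_breed) | is.na(maternal_breed)
  if (any(bad)) {
    stop("unlabelled (mixed) haplotypes for animals: ",
         paste(utils::head(ids[bad], 10), collapse = ", "))
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(paternal)))
  zp <- gametic_z(paternal, paternal_breed, breed_freqs)
  zm <- gametic_z(maternal, maternal_breed, breed_freqs)
  if (full_gametic) {
    z <- zp$z + zm$z
    g <- tcrossprod(z) / (zp$denom + zm$denom)
    return(new_grmatrix(g, ids, "G2full", breed_freqs,
                        c(paternal = zp$denom, maternal = zm$denom)))
  }
  g21 <- tcrossprod(zp$z) / zp$denom
  g22 <- tcrossprod(zm$z) / zm$denom
  g <- (g21 + g22) / 2
  new_grmatrix(g, ids, "G2", breed_freqs,
               c(paternal = zp$denom, maternal = zm$denom),
               meta = list(G2_paternal = g21, G2_maternal = g22))
}

#' Element-wise correlation between two relationship matrices
#'
#' Pearson correlation over the upper-triangle elements (diagonal excluded
#' by default).
#'
#' @param a,b `grmatrix` objects (or plain matrices) over the same animals
#'   in the same order.
#' @param include_diagonal Logical.
#' @return The correlation.
#' @export
grm_element_correlation <- function(a, b, include_diagonal = FALSE) {
  va <- if (inherits(a, "grmatrix")) a$values else a
  vb <- if (inherits(b, "grmatrix")) b$values else b
  if (!all(dim(va) == dim(vb))) stop("dimension mismatch")
  if (inherits(a, "grmatrix") && inherits(b, "grmatrix") &&
      !identical(a$ids, b$ids)) {
    stop("animal sets/order differ")
  }
  ut <- upper.tri(va, diag = include_diagonal)
  stats::cor(va[ut], vb[ut])
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition of the (symmetric) GRM; scores are eigenvectors scaled
#' by the square root of their eigenvalues. When labels are supplied, a
#' cluster-purity metric is computed by k-means (k = number of label groups)
#' on the first two components: purity is the fraction of animals whose
#' label is the majority label of their cluster. Between-group centroid
#' distances in PC1/PC2 space are also returned.
#'
#' @param g A `grmatrix` (or symmetric matrix).
#' @param labels Optional group (breed) label per animal.
#' @param n_pc Number of components to return.
#' @return List with `scores`, `variance_share`, and (with labels) `purity`
#'   and `centroid_distances`; `purity` is `NA` (degenerate) when the
#'   leading eigenvalues are indistinguishable.
#' @export
grm_pca <- function(g, labels = NULL, n_pc = 2L) {
  v <- if (inherits(g, "grmatrix")) g$values else as.matrix(g)
  if (any(!is.finite(v))) stop("non-finite entries in relationship matrix")
  ev <- eigen((v + t(v)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  n_pc <- min(n_pc, ncol(v))
  scores <- ev$vectors[, seq_len(n_pc), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(n_pc)]), n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  rownames(scores) <- rownames(v)
  out <- list(scores = scores, variance_share = lam / sum(lam),
              eigenvalues = lam)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    k <- length(unique(labels))
    degenerate <- k < 2L ||
      stats::sd(lam) / max(mean(lam), .Machine$double.eps) < 1e-8
    if (degenerate) {
      out$purity <- NA_real_
    } else {
      km <- stats::kmeans(scores[, 1:2, drop = FALSE], centers = k,
                          nstart = 25)
      tab <- table(km$cluster, labels)
      out$purity <- sum(apply(tab, 1, max)) / length(labels)
      cent <- do.call(rbind, lapply(split(seq_along(labels), labels),
                                    function(i)
                                      colMeans(scores[i, 1:2, drop = FALSE])))
      out$centroid_distances <- as.matrix(stats::dist(cent))
    }
  }
  out
}

#' Mean relationship between a haplotype class and an animal set
#'
#' Summarizes gametic relationships between a class of haplotypes (e.g. the
#' paternal, breed-labelled haplotypes of a reference set) and a group of
#' animals: each animal is represented by the average of its two gametic
#' relationship values, and the cross-block mean and SD are returned.
#'
#' @param hap_group 0/1 haplotype matrix for the haplotype class.
#' @param hap_group_breed Breed label per haplotype in `hap_group`.
#' @param animals List with `paternal`/`maternal` haplotype matrices and
#'   `paternal_breed`/`maternal_breed` labels for the animal set (e.g. from
#'   [extract_haplotypes()] plus [assign_haplotype_origin()]).
#' @param breed_freqs Breeds x SNPs frequency matrix.
#' @return List with `mean`, `sd` and the cross `values` matrix.
#' @export
haplotype_group_relationship <- function(hap_group, hap_group_breed, animals,
                                         breed_freqs) {
  if (nrow(hap_group) == 0L || nrow(animals$paternal) == 0L) {
    stop("empty group")
  }
  za <- gametic_z(hap_group, hap_group_breed, breed_freqs)
  zp <- gametic_z(animals$paternal, animals$paternal_breed, breed_freqs)
  zm <- gametic_z(animals$maternal, animals$maternal_breed, breed_freqs)
  denom <- sqrt(za$denom * (zp$denom + zm$denom) / 2)
  vals <- tcrossprod(za$z, (zp$z + zm$z) / 2) / denom
  list(mean = mean(vals), sd = stats::sd(as.numeric(vals)), values = vals)
}

#' Write / read a GRM in GCTA text format
#'
#' `<prefix>.grm` holds `i j n_snps value` for the lower triangle including
#' the diagonal; `<prefix>.grm.id` holds family/within-family ids.
#'
#' @param g A `grmatrix`.
#' @param prefix Path prefix.
#' @param n_snps SNP count recorded per element.
#' @return Invisibly, the file paths.
#' @export
write_grm <- function(g, prefix, n_snps = NA_integer_) {
  n <- length(g$ids)
  ij <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  df <- data.frame(i = ij[, 1], j = ij[, 2], n = n_snps,
                   value = g$values[ij])
  utils::write.table(df, paste0(prefix, ".grm"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(data.frame(fid = g$ids, iid = g$ids),
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(paste0(prefix, c(".grm", ".grm.id")))
}

#' @rdname write_grm
#' @param flavor Flavor label to record on the matrix read back.
#' @export
read_grm <- function(prefix, flavor = "G1") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")[[2]]
  df <- utils::read.table(paste0(prefix, ".grm"))
  n <- length(ids)
  v <- matrix(0, n, n)
  v[cbind(df[[1]], df[[2]])] <- df[[4]]
  v[upper.tri(v)] <- t(v)[upper.tri(v)]
  new_grmatrix(v, ids, flavor, NULL, NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
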