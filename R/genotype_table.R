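#' Genotype table
#'
#' Container for SNP genotype calls: a samples-by-SNPs matrix of second-allele
#' dosages (0/1/2, `NA` = missing call), SNP metadata and an optional per-call
#' confidence score matrix in \[0, 1\] (the analogue of a GenCall score).
#'
#' @param geno Numeric/integer matrix, animals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}` (imputation may later introduce fractional
#'   dosages).
#' @param map data.frame with columns `snp`, `chr`, `pos` (one row per SNP).
#' @param ids Animal identifiers (default: rownames or 1..n).
#' @param conf Optional confidence matrix of the same dimension as `geno`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(geno, map, ids = NULL, conf = NULL) {
  geno <- as.matrix(geno)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(geno))) rownames(geno) else
      as.character(seq_len(nrow(geno)))
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(geno)) stop("ids do not match genotype rows")
  if (!all(c("snp", "chr", "pos") %in% names(map))) {
    stop("map must have columns snp, chr, pos")
  }
  if (nrow(map) != ncol(geno)) stop("map does not match genotype columns")
  bad <- !is.na(geno) & !(geno %in% 0:2) & (geno < 0 | geno > 2)
  if (any(bad)) stop("genotype calls must be in {0, 1, 2} or NA")
  if (!is.null(conf)) {
    conf <- as.matrix(conf)
    if (!all(dim(conf) == dim(geno))) stop("conf dimensions must match geno")
    if (any(conf < 0 | conf > 1, na.rm = TRUE)) {
      stop("confidence scores must be in [0, 1]")
    }
  }
  dimnames(geno) <- list(ids, map$snp)
  structure(list(geno = geno, map = as.data.frame(map), ids = ids,
                 conf = conf),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$geno), "animals x", ncol(x$geno), "SNPs;",
      sum(is.na(x$geno)), "missing calls",
      if (!is.null(x$conf)) "(confidence scores present)" else "", "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

#' Subset a genotype table
#'
#' Keeps samples and/or SNPs (indices) with ids, map and confidence scores
#' aligned.
#'
#' @param gt A [genotype_table()].
#' @param samples,snps Row/column indices to keep (`NULL` = all).
#' @return A [genotype_table()].
#' @export
subset_genotype_table <- function(gt, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gt$geno))
  if (is.null(snps)) snps <- seq_len(ncol(gt$geno))
  genotype_table(geno = gt$geno[samples, snps, drop = FALSE],
                 map = gt$map[snps, , drop = FALSE],
                 ids = gt$ids[samples],
                 conf = if (!is.null(gt$conf))
                   gt$conf[samples, snps, drop = FALSE])
}

#' Write genotypes as PLINK text ped/map
#'
#' Alleles are coded 1/2 (dosage counts allele "2"); missing calls are
#' written `0 0`. Positions are emitted in base pairs assuming 1 Morgan = 1e6
#' bp on the simulated uniform map.
#'
#' @param gt A [genotype_table()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(gt, prefix) {
  codes <- c(`0` = "1 1", `1` = "1 2", `2` = "2 2")
  g <- round(gt$geno)
  n <- nrow(g)
  lines <- character(n)
  for (i in seq_len(n)) {
    al <- codes[as.character(g[i, ])]
    al[is.na(al)] <- "0 0"
    lines[i] <- paste(gt$ids[i], gt$ids[i], 0, 0, 0, -9,
                      paste(al, collapse = " "))
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  writeLines(lines, ped_path)
  map <- data.frame(chr = gt$map$chr, snp = gt$map$snp, cm = 0,
                    bp = round(as.numeric(gt$map$pos) * 1e6))
  utils::write.table(map, map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(c(ped_path, map_path))
}

#' Read PLINK text ped/map into a genotype table
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return A [genotype_table()]; dosage counts allele "2".
#' @export
read_plink <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chr", "snp", "cm", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  raw <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(raw) != 6 + 2 * m) stop("ped/map dimensions disagree")
  ids <- raw[[2]]
  a1 <- as.matrix(raw[, 6 + 2 * seq_len(m) - 1])
  a2 <- as.matrix(raw[, 6 + 2 * seq_len(m)])
  geno <- (a1 == "2") + (a2 == "2")
  geno[a1 == "0" | a2 == "0"] <- NA
  genotype_table(geno = geno,
                 map = data.frame(snp = map$snp, chr = map$chr,
                                  pos = map$bp / 1e6,
                                  stringsAsFactors = FALSE),
                 ids = ids)
}
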