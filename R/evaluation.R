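#' Validation accuracy of genomic prediction
#'
#' Pearson correlation between genomic breeding values and progeny-test
#' EBVs, computed within a validation group (conventionally within breed).
#'
#' @param gbv,ebv Paired numeric vectors.
#' @param group Optional grouping factor (e.g. breed); accuracy is computed
#'   per group.
#' @return data.frame with `group`, `n` and `correlation` (`NA` with a
#'   message attribute when a vector is constant).
#' @export
accuracy <- function(gbv, ebv, group = NULL) {
  stopifnot(length(gbv) == length(ebv))
  if (is.null(group)) group <- rep("all", length(gbv))
  out <- lapply(split(seq_along(gbv), group), function(i) {
    if (length(i) < 3L) stop("need at least 3 paired values per group")
    r <- if (stats::sd(gbv[i]) == 0 || stats::sd(ebv[i]) == 0) NA_real_ else
      stats::cor(gbv[i], ebv[i])
    data.frame(n = length(i), correlation = r)
  })
  res <- do.call(rbind, out)
  data.frame(group = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare two prediction accuracies
#'
#' Independent mode: Fisher z-transformation,
#' `z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`. Dependent mode
#' (the same validation animals under two predictors): Steiger's test,
#' which needs the correlation `r12` between the two predictors.
#'
#' @param r1,r2 The two correlations (|r| < 1).
#' @param n1,n2 Group sizes (each > 3; `n2` defaults to `n1`).
#' @param dependent Logical; use Steiger's test for overlapping samples.
#' @param r12 Correlation between the two predictor vectors (dependent mode
#'   only).
#' @return List with `z` and the two-sided `p`.
#' @export
compare_accuracies <- function(r1, n1, r2, n2 = n1, dependent = FALSE,
                               r12 = NULL) {
  if (any(c(n1, n2) <= 3)) stop("need n > 3")
  if (any(abs(c(r1, r2)) >= 1)) stop("need |r| < 1")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  if (!dependent) {
    z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(r12)) stop("dependent mode requires r12")
    if (n1 != n2) stop("dependent mode assumes one shared sample (n1 == n2)")
    rbar2 <- ((r1 + r2) / 2)^2
    f <- (1 - r12) / (2 * (1 - rbar2))
    if (!is.finite(f)) stop("degenerate inputs for Steiger's test")
    h <- (1 - f * rbar2) / (1 - rbar2)
    z <- (z1 - z2) * sqrt((n1 - 3) / (2 * (1 - r12) * h))
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Deterministic expected accuracy of genomic prediction
#'
#' Daetwyler/Goddard-style prediction:
#' `Me = 2 Ne L / ln(4 Ne L)` independent chromosome segments and
#' `accuracy = sqrt(N h2 / (N h2 + Me))` for a reference of size `N`.
#'
#' @param n_reference Reference population size `N`.
#' @param heritability Trait heritability.
#' @param ne Effective population size.
#' @param genome_length Genome length `L` in Morgans.
#' @return List with `accuracy` and `me`.
#' @export
expected_accuracy <- function(n_reference, heritability, ne, genome_length) {
  if (any(c(n_reference, ne, genome_length) <= 0) || heritability < 0 ||
      heritability > 1) {
    stop("parameters must be positive (heritability in [0, 1])")
  }
  arg <- 4 * ne * genome_length
  if (arg <= 1) stop("non-positive log argument: 4 Ne L must exceed 1")
  me <- 2 * ne * genome_length / log(arg)
  nh2 <- n_reference * heritability
  list(accuracy = sqrt(nh2 / (nh2 + me)), me = me)
}

## greedy compact letter display from a logical "significantly different"
## matrix; rows assumed ordered as desired (ties broken upstream)
compact_letters <- function(diff_mat) {
  k <- nrow(diff_mat)
  groups <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(diff_mat[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  letts <- character(k)
  for (g in seq_along(groups)) {
    for (i in groups[[g]]) {
      letts[i] <- paste0(letts[i], letters[g])
    }
  }
  letts
}

#' Summarize accuracies across reference designs
#'
#' Builds a comparison table in the layout of the reference-population
#' tables: one row per reference design, one accuracy column per target
#' breed x GRM flavor, each cell annotated with compact significance
#' letters derived greedily from pairwise Fisher z-tests at `alpha` (designs
#' sharing a letter do not differ significantly; ties are broken by
#' descending accuracy).
#'
#' @param results data.frame with columns `design`, `grm`, `breed`,
#'   `accuracy`, `n` (optionally pre-averaged over seeds).
#' @param alpha Significance level for the pairwise z-tests.
#' @return data.frame, one row per design, cells `"<accuracy> <letters>"`
#'   plus numeric columns.
#' @export
summarize_scenarios <- function(results, alpha = 0.05) {
  req <- c("design", "grm", "breed", "accuracy", "n")
  if (!all(req %in% names(results))) {
    stop("results needs columns ", paste(req, collapse = ", "))
  }
  designs <- unique(results$design)
  cells <- split(results, list(results$breed, results$grm), drop = TRUE)
  out <- data.frame(design = designs, stringsAsFactors = FALSE)
  for (nm in names(cells)) {
    cell <- cells[[nm]]
    if (anyDuplicated(cell$design)) {
      stop("duplicated design labels within a breed x GRM cell: ", nm)
    }
    cell <- cell[match(designs, cell$design), , drop = FALSE]
    k <- nrow(cell)
    lettered <- rep("", k)
    if (k > 1L) {
      ord <- order(-cell$accuracy)
      dm <- matrix(FALSE, k, k)
      for (a in seq_len(k - 1L)) {
        for (b in seq.int(a + 1L, k)) {
          ia <- ord[a]; ib <- ord[b]
          if (is.na(cell$accuracy[ia]) || is.na(cell$accuracy[ib])) next
          cmp <- compare_accuracies(min(cell$accuracy[ia], 0.999),
                                    cell$n[ia],
                                    min(cell$accuracy[ib], 0.999),
                                    cell$n[ib])
          dm[a, b] <- dm[b, a] <- cmp$p < alpha
        }
      }
      lettered[ord] <- compact_letters(dm)
    }
    out[[paste0(nm, "_accuracy")]] <- cell$accuracy
    out[[paste0(nm, "_letters")]] <- lettered
  }
  out
}

#' Render a scenario summary as Markdown or TSV
#'
#' @param summary Output of [summarize_scenarios()].
#' @param format `"markdown"` or `"tsv"`.
#' @return Character vector of lines.
#' @export
format_scenario_table <- function(summary, format = c("markdown", "tsv")) {
  format <- match.arg(format)
  acc_cols <- grep("_accuracy$", names(summary), value = TRUE)
  disp <- data.frame(design = summary$design, stringsAsFactors = FALSE)
  for (ac in acc_cols) {
    lc <- sub("_accuracy$", "_letters", ac)
    disp[[sub("_accuracy$", "", ac)]] <-
      paste0(sprintf("%.2f", summary[[ac]]),
             ifelse(nzchar(summary[[lc]]), paste0(" ", summary[[lc]]), ""))
  }
  if (format == "tsv") {
    c(paste(names(disp), collapse = "\t"),
      apply(disp, 1, paste, collapse = "\t"))
  } else {
    header <- paste0("| ", paste(names(disp), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(disp)), collapse = "|"), "|")
    rows <- apply(disp, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                              " |"))
    c(header, sep, rows)
  }
}

#' Wright's drift expectation and realized FST
#'
#' For breeds drifting independently from a common base population,
#' `E[FST] = 1 - (1 - 1/(2 Ne))^t` relative to the base frequencies.
#' `fst_wright()` estimates FST as the ratio of the mean between-breed
#' variance of allele frequencies to the mean base-frequency variance
#' `p0 (1 - p0)`, which is unbiased for the drift expectation.
#'
#' @param breed_freqs Breeds x SNPs frequency matrix.
#' @param base_freqs Base (ancestral) frequencies per SNP.
#' @return The FST estimate.
#' @export
fst_wright <- function(breed_freqs, base_freqs) {
  stopifnot(ncol(breed_freqs) == length(base_freqs))
  keep <- base_freqs > 0 & base_freqs < 1
  v_between <- apply(breed_freqs[, keep, drop = FALSE], 2, stats::var)
  mean(v_between) / mean(base_freqs[keep] * (1 - base_freqs[keep]))
}

#' @rdname fst_wright
#' @param ne Effective size during divergence.
#' @param generations Number of drift generations.
#' @export
fst_expected <- function(ne, generations) {
  1 - (1 - 1 / (2 * ne))^generations
}
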