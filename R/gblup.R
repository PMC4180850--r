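#' Build incidence structures for the evaluation model
#'
#' Assembles the design of the linear model
#' `y = X b + Z1 g + W w + Z1 Q q + Z2 s + e`: fixed-effect matrix `X`
#' (factors, covariates and the breed-proportion columns `Q` with the
#' reference breed omitted), animal incidence `Z1` mapping records to the
#' full animal set of the relationship matrix (animals without records get
#' zero columns and are predicted through `G`), maternal incidence `W`
#' (dams of recorded animals) and sire-by-flock incidence `Z2`.
#' Rank-deficient fixed-effect columns are dropped with a warning and the
#' aliasing recorded.
#'
#' @param records data.frame of phenotype records; must contain `animal`,
#'   `y` and every variable named in `fixed`.
#' @param animal_ids Ids of every animal in the relationship matrix
#'   (records' animals must be a subset).
#' @param fixed One-sided formula for fixed effects, e.g.
#'   `~ factor(birth_type) + factor(rearing_type) + gender + age + cg`.
#' @param Q Optional breed-proportion data.frame from
#'   [breed_proportions()]; its columns (minus `reference_breed`) enter `X`
#'   as covariates.
#' @param reference_breed Breed column omitted from `Q` for identifiability
#'   (default: first column).
#' @param maternal,sire_flock Logicals: include the corresponding random
#'   term's incidence.
#' @return List of class `gblup_design` with `y`, `X`, `Z1`, `W`, `Z2`,
#'   level bookkeeping and any dropped columns.
#' @export
build_design_matrices <- function(records, animal_ids,
                                  fixed = ~ factor(birth_type) +
                                    factor(rearing_type) + gender + age + cg,
                                  Q = NULL, reference_breed = NULL,
                                  maternal = FALSE, sire_flock = FALSE) {
  animal_ids <- as.character(animal_ids)
  rec_animal <- as.character(records$animal)
  if (!all(rec_animal %in% animal_ids)) {
    stop("records contain animals absent from animal_ids")
  }
  n <- nrow(records)
  X <- stats::model.matrix(fixed, data = records)
  if (nrow(X) != n) stop("records contain missing values in model variables")
  if (!is.null(Q)) {
    qcols <- setdiff(names(Q), "animal")
    if (is.null(reference_breed)) reference_breed <- qcols[1]
    keep <- setdiff(qcols, reference_breed)
    qi <- match(rec_animal, as.character(Q$animal))
    if (anyNA(qi)) stop("breed compositions missing for some records")
    qm <- as.matrix(Q[qi, keep, drop = FALSE])
    colnames(qm) <- paste0("Q_", keep)
    # constant proportion columns (e.g. purebred-only references) carry no
    # contrast and are dropped without comment
    qm <- qm[, apply(qm, 2, function(v) diff(range(v)) > 0), drop = FALSE]
    X <- cbind(X, qm)
  }
  qrx <- qr(X)
  dropped <- character(0)
  if (qrx$rank < ncol(X)) {
    keep_cols <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[-keep_cols]
    warning("dropping aliased fixed-effect columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, keep_cols, drop = FALSE]
  }
  Z1 <- Matrix::sparseMatrix(i = seq_len(n),
                             j = match(rec_animal, animal_ids),
                             x = 1, dims = c(n, length(animal_ids)),
                             dimnames = list(NULL, animal_ids))
  W <- NULL
  dam_ids <- NULL
  if (maternal) {
    if (!"dam" %in% names(records) || anyNA(records$dam)) {
      stop("maternal term requested but records lack complete dam ids")
    }
    dam_ids <- sort(unique(as.character(records$dam)))
    W <- Matrix::sparseMatrix(i = seq_len(n),
                              j = match(as.character(records$dam), dam_ids),
                              x = 1, dims = c(n, length(dam_ids)),
                              dimnames = list(NULL, dam_ids))
  }
  Z2 <- NULL
  sf_levels <- NULL
  if (sire_flock) {
    if (!all(c("sire", "flock") %in% names(records))) {
      stop("sire_flock term requested but records lack sire/flock")
    }
    sf <- paste(records$sire, records$flock, sep = ":")
    sf_levels <- sort(unique(sf))
    Z2 <- Matrix::sparseMatrix(i = seq_len(n),
                               j = match(sf, sf_levels),
                               x = 1, dims = c(n, length(sf_levels)),
                               dimnames = list(NULL, sf_levels))
  }
  structure(list(y = records$y, X = X, Z1 = Z1, W = W, Z2 = Z2,
                 animal_ids = animal_ids, dam_ids = dam_ids,
                 sf_levels = sf_levels, dropped_columns = dropped),
            class = "gblup_design")
}

#' Solve Henderson's mixed model equations
#'
#' GBLUP with a genomic relationship matrix: solves
#' `C theta = rhs` where the coefficient matrix stacks the fixed effects,
#' the additive animal effects (covariance `G sigma_g^2`), and optional
#' maternal and sire-by-flock effects with identity covariance. Animals in
#' `G` without records receive genomic breeding values through their
#' relationships. If `G` is numerically singular, 0.01 is added to its
#' diagonal (recorded in the result).
#'
#' @param design A `gblup_design` from [build_design_matrices()].
#' @param G A `grmatrix` (or matrix) over `design$animal_ids` in order.
#' @param varcomp Named list/vector of variance components: `g`, `e`, plus
#'   `m` (maternal) and `sf` (sire-by-flock) when those terms are present.
#' @param pev Logical: also return prediction error variances of the
#'   additive effects (requires inverting the coefficient matrix).
#' @return A `fit_result` list: `b`, `gbv` (named per animal), `w`, `s`,
#'   `pev`, `varcomp`, `stabilized`.
#' @export
solve_mme <- function(design, G, varcomp, pev = FALSE) {
  gv <- if (inherits(G, "grmatrix")) G$values else as.matrix(G)
  na <- length(design$animal_ids)
  if (!all(dim(gv) == na)) stop("G dimension does not match animal_ids")
  vc <- as.list(varcomp)
  if (is.null(vc$g) || is.null(vc$e) || vc$g <= 0 || vc$e <= 0) {
    stop("varcomp must contain positive components g and e")
  }
  stabilized <- FALSE
  ginv <- tryCatch(chol2inv(chol(gv)), error = function(e) NULL)
  if (is.null(ginv)) {
    gv <- gv + diag(0.01, na)
    stabilized <- TRUE
    ginv <- chol2inv(chol(gv))
  }
  X <- as.matrix(design$X)
  Z1 <- design$Z1
  blocks <- list(X = X, g = Z1)
  lambdas <- list(X = NULL, g = vc$e / vc$g)
  if (!is.null(design$W)) {
    if (is.null(vc$m) || vc$m <= 0) stop("maternal term needs varcomp m > 0")
    blocks$m <- design$W
    lambdas$m <- vc$e / vc$m
  }
  if (!is.null(design$Z2)) {
    if (is.null(vc$sf) || vc$sf <= 0) {
      stop("sire_flock term needs varcomp sf > 0")
    }
    blocks$sf <- design$Z2
    lambdas$sf <- vc$e / vc$sf
  }
  sizes <- vapply(blocks, ncol, integer(1))
  total <- sum(sizes)
  C <- matrix(0, total, total)
  rhs <- numeric(total)
  off <- cumsum(c(0, sizes))
  y <- design$y
  for (i in seq_along(blocks)) {
    ri <- off[i] + seq_len(sizes[i])
    rhs[ri] <- as.numeric(Matrix::crossprod(blocks[[i]], y))
    for (j in seq.int(i, length(blocks))) {
      rj <- off[j] + seq_len(sizes[j])
      cij <- as.matrix(Matrix::crossprod(blocks[[i]], blocks[[j]]))
      C[ri, rj] <- cij
      if (j > i) C[rj, ri] <- t(cij)
    }
  }
  gi <- off[2] + seq_len(sizes[2])
  C[gi, gi] <- C[gi, gi] + lambdas$g * ginv
  if (!is.null(lambdas$m)) {
    mi <- off[3] + seq_len(sizes[3])
    C[mi, mi] <- C[mi, mi] + diag(lambdas$m, sizes[3])
  }
  if (!is.null(lambdas$sf)) {
    si <- off[length(off) - 1L] + seq_len(sizes[length(sizes)])
    C[si, si] <- C[si, si] + diag(lambdas$sf, sizes[length(sizes)])
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular mixed-model coefficient matrix (condition estimate ",
         signif(kappa(C, exact = FALSE), 3),
         "); check for confounded effects")
  }
  theta <- backsolve(ch, forwardsolve(t(ch), rhs))
  b <- stats::setNames(theta[seq_len(sizes[1])], colnames(X))
  gbv <- stats::setNames(theta[gi], design$animal_ids)
  w <- s <- NULL
  if (!is.null(lambdas$m)) {
    w <- stats::setNames(theta[off[3] + seq_len(sizes[3])], design$dam_ids)
  }
  if (!is.null(lambdas$sf)) {
    s <- stats::setNames(theta[off[length(off) - 1L] +
                                 seq_len(sizes[length(sizes)])],
                         design$sf_levels)
  }
  pev_g <- NULL
  if (pev) {
    cinv <- chol2inv(ch)
    pev_g <- stats::setNames(diag(cinv)[gi] * vc$e, design$animal_ids)
  }
  structure(list(b = b, gbv = gbv, w = w, s = s, pev = pev_g,
                 varcomp = vc, stabilized = stabilized),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", length(x$gbv), "genomic breeding values;",
      length(x$b), "fixed-effect solutions",
      if (x$stabilized) "(G diagonal stabilized)" else "", "\n")
  invisible(x)
}

#' Direct generalized-least-squares fit (reference implementation)
#'
#' Computes GBV as `sigma_g^2 G Z1' V^-1 (y - X b-hat)` with
#' `V = Z1 G Z1' sigma_g^2 + W W' sigma_m^2 + Z2 Z2' sigma_sf^2 +
#' I sigma_e^2` and `b-hat` the GLS estimate. Algebraically identical to
#' [solve_mme()]; kept as an independent route for verification.
#'
#' @inheritParams solve_mme
#' @return List with `b` and `gbv`.
#' @export
solve_gls <- function(design, G, varcomp) {
  gv <- if (inherits(G, "grmatrix")) G$values else as.matrix(G)
  vc <- as.list(varcomp)
  Z1 <- as.matrix(design$Z1)
  V <- vc$g * (Z1 %*% gv %*% t(Z1)) + diag(vc$e, nrow(Z1))
  if (!is.null(design$W)) {
    W <- as.matrix(design$W)
    V <- V + vc$m * tcrossprod(W)
  }
  if (!is.null(design$Z2)) {
    Z2 <- as.matrix(design$Z2)
    V <- V + vc$sf * tcrossprod(Z2)
  }
  X <- as.matrix(design$X)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  b <- solve(XtVi %*% X, XtVi %*% design$y)
  r <- design$y - X %*% b
  gbv <- vc$g * (gv %*% crossprod(Z1, Vi %*% r))
  list(b = stats::setNames(as.numeric(b), colnames(X)),
       gbv = stats::setNames(as.numeric(gbv), design$animal_ids))
}

#' EM-REML for the reduced additive model
#'
#' Estimates `sigma_g^2` and `sigma_e^2` in `y = X b + g + e`,
#' `g ~ N(0, G sigma_g^2)`, by the EM algorithm on the REML likelihood. The
#' relationship matrix is eigendecomposed once, making each EM iteration
#' O(n p^2); the REML log-likelihood is non-decreasing along the iterate
#' sequence (a property the tests verify). Heritability estimates at the
#' boundary stay non-negative because EM updates are sums of squares.
#'
#' @param y Phenotype vector (one record per animal in `G`, same order).
#' @param X Fixed-effect design matrix (default: intercept).
#' @param G Relationship matrix (`grmatrix` or matrix).
#' @param init Optional starting values `c(g, e)`; default splits the
#'   phenotypic variance equally.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   log-likelihood change.
#' @return List: `sigma_g2`, `sigma_e2`, `h2`, `loglik` (trace),
#'   `converged`, `n_iter`.
#' @export
em_reml <- function(y, X = NULL, G, init = NULL, max_iter = 500L,
                    tol = 1e-8) {
  gv <- if (inherits(G, "grmatrix")) G$values else as.matrix(G)
  n <- length(y)
  if (!all(dim(gv) == n)) stop("G dimension does not match y")
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- qr(X)$rank
  if (n <= p) stop("need more records than fixed effects")
  ev <- eigen((gv + t(gv)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  if (is.null(init)) {
    v0 <- stats::var(y)
    init <- c(v0 / 2, v0 / 2)
  }
  sg <- init[1]
  se <- init[2]
  reml_pieces <- function(sg, se) {
    v <- d * sg + se
    wi <- 1 / v
    XtW <- Xt * wi
    XtWX <- crossprod(Xt, XtW)
    cXtWX <- chol(XtWX)
    beta <- backsolve(cXtWX, forwardsolve(t(cXtWX), crossprod(XtW, yt)))
    r <- wi * (yt - Xt %*% beta)          # r = P y
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cXtWX))) +
                    sum(yt * r))
    # tr(P A) for A = diag(d) and A = I
    B <- backsolve(cXtWX, forwardsolve(t(cXtWX), t(XtW)))  # (X'WX)^-1 X'W
    trPD <- sum(d * wi) - sum(t(B) * (XtW * d))
    trP <- sum(wi) - sum(t(B) * XtW)
    list(ll = ll, r = as.numeric(r), trPD = trPD, trP = trP)
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    pc <- reml_pieces(sg, se)
    ll_trace <- c(ll_trace, pc$ll)
    sg_new <- (sg^2 * sum(d * pc$r^2) + n * sg - sg^2 * pc$trPD) / n
    se_new <- (se^2 * sum(pc$r^2) + n * se - se^2 * pc$trP) / n
    sg_new <- max(sg_new, 1e-12)
    se_new <- max(se_new, 1e-12)
    done <- it > 1L &&
      abs(ll_trace[it] - ll_trace[it - 1L]) < tol
    sg <- sg_new
    se <- se_new
    if (done) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  if (!converged) {
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning best iterate")
  }
  list(sigma_g2 = sg, sigma_e2 = se, h2 = sg / (sg + se),
       loglik = ll_trace, converged = converged, n_iter = it)
}
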