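#' Ornstein-Uhlenbeck correlation matrix from a phylogeny
#'
#' `C[i, j] = exp(-alpha * d_ij)` with `d_ij` the patristic distance between
#' taxa i and j (the corMartins structure): correlation decays with distance
#' at rate `alpha` per unit branch length, `C[i, i] = 1`.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param alpha OU strength, `>= 0` (0 gives the degenerate all-ones matrix,
#'   with a warning).
#' @return taxon-by-taxon correlation matrix.
#' @export
ouCorrelation <- function(tree, alpha) {
  stopifnot(inherits(tree, "phylo"), alpha >= 0)
  D <- ape::cophenetic.phylo(tree)
  if (any(!is.finite(D))) stop("non-finite patristic distances")
  if (alpha == 0) warning("alpha = 0 gives a singular all-ones correlation")
  C <- exp(-alpha * D)
  diag(C) <- 1
  C
}

# GLS fit for a fixed correlation matrix via its Cholesky whitening
.glsFixed <- function(y, X, C) {
  L <- tryCatch(chol(C), error = function(e)
    stop(sprintf("correlation matrix is not positive definite (%s)",
                 conditionMessage(e))))
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) stop("singular X' C^-1 X")
  beta <- qr.coef(qrX, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  XtX <- crossprod(Xw)
  list(beta = beta, rss = rss, XtX = XtX, logdetC = 2 * sum(log(diag(L))),
       yw = yw, Xw = Xw)
}

.remlLogLik <- function(y, X, C) {
  n <- length(y)
  p <- ncol(X)
  f <- .glsFixed(y, X, C)
  sigma2 <- f$rss / (n - p)
  -0.5 * ((n - p) * log(sigma2) + f$logdetC +
            determinant(f$XtX, logarithm = TRUE)$modulus[1] + (n - p))
}

#' Phylogenetic generalized least squares with OU correlation
#'
#' Fits `y = X beta + e`, `Var(e) = sigma^2 C(alpha)` with
#' `C = exp(-alpha * patristic distance)` (see [ouCorrelation()]). With
#' `alpha = "estimate"`, alpha maximizes the restricted likelihood over a
#' log-spaced grid (`10^-3` to `10^3`, 31 points) refined by golden-section
#' search. Reports the GLS F-test of the slope terms against the
#' intercept-only model, and an ordinary least squares fit of the same model
#' for comparison (the limit of complete phylogenetic independence).
#'
#' @param formula model formula; variables resolved in `data`.
#' @param data `data.frame` with one row per taxon; rows are matched to the
#'   tree by `data[[strainCol]]` (or row names when absent).
#' @param tree `ape::phylo` whose tip labels cover the data rows.
#' @param alpha `"estimate"` or a fixed non-negative value.
#' @param strainCol column holding taxon ids.
#' @return object of class `"PGLSFit"`: coefficient table, `F`, `df1`,
#'   `df2`, `p.value`, `alpha`, `sigma2`, `r.squared` (on GLS-whitened
#'   responses), and the parallel `ols` summary.
#' @export
pglsFit <- function(formula, data, tree, alpha = "estimate",
                    strainCol = "strain") {
  stopifnot(inherits(tree, "phylo"))
  ids <- if (strainCol %in% names(data)) as.character(data[[strainCol]])
         else rownames(data)
  if (!all(ids %in% tree$tip.label))
    stop("data rows must match tree tip labels")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients")
  Dfull <- ape::cophenetic.phylo(tree)
  D <- Dfull[ids, ids]

  Cof <- function(a) {
    C <- exp(-a * D)
    diag(C) <- 1
    C
  }
  if (identical(alpha, "estimate")) {
    grid <- 10^seq(-3, 3, length.out = 31)
    ll <- vapply(grid, function(a) .remlLogLik(y, X, Cof(a)), numeric(1))
    i <- which.max(ll)
    lo <- log10(grid[max(1L, i - 1L)])
    hi <- log10(grid[min(length(grid), i + 1L)])
    opt <- stats::optimize(function(la) .remlLogLik(y, X, Cof(10^la)),
                           lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-6)
    alphaHat <- 10^opt$maximum
    if (.remlLogLik(y, X, Cof(alphaHat)) < ll[i]) alphaHat <- grid[i]
    profile <- data.frame(alpha = grid, reml = ll)
  } else {
    stopifnot(is.numeric(alpha), alpha >= 0)
    alphaHat <- alpha
    profile <- NULL
  }
  C <- Cof(alphaHat)
  fit <- .glsFixed(y, X, C)
  sigma2 <- fit$rss / (n - p)
  covB <- sigma2 * solve(fit$XtX)
  se <- sqrt(diag(covB))
  tval <- as.numeric(fit$beta) / se
  coefTab <- data.frame(estimate = as.numeric(fit$beta), se = se, t = tval,
                        p = 2 * stats::pt(-abs(tval), df = n - p),
                        row.names = colnames(X))
  # F test of slope terms vs intercept-only, same C
  X0 <- X[, 1, drop = FALSE]
  fit0 <- .glsFixed(y, X0, C)
  df1 <- p - 1L
  df2 <- n - p
  Fstat <- if (df1 > 0) ((fit0$rss - fit$rss) / df1) / (fit$rss / df2)
           else NA_real_
  pval <- if (df1 > 0) stats::pf(Fstat, df1, df2, lower.tail = FALSE)
          else NA_real_
  r2 <- if (df1 > 0) 1 - fit$rss / fit0$rss else NA_real_

  olsFit <- stats::lm(formula, data = data)
  olsAn <- stats::anova(olsFit)
  out <- list(coefficients = coefTab, F = Fstat, df1 = df1, df2 = df2,
              p.value = pval, alpha = alphaHat, sigma2 = sigma2,
              r.squared = r2, n = n, profile = profile,
              ols = list(coefficients = stats::coef(olsFit),
                         F = if (df1 > 0) olsAn$`F value`[1] else NA_real_,
                         p.value = if (df1 > 0) olsAn$`Pr(>F)`[1] else NA_real_))
  class(out) <- "PGLSFit"
  out
}

#' @export
print.PGLSFit <- function(x, ...) {
  cat(sprintf("PGLS (OU correlation, alpha = %.4g)\n", x$alpha))
  print(round(x$coefficients, 6))
  cat(sprintf("F_%d,%d = %.3f, P = %.4g, R2(GLS) = %.3f\n",
              x$df1, x$df2, x$F, x$p.value, x$r.squared))
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' @param values numeric observations.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `F`, `df1`, `df2`, `p.value`.
#' @export
groupAnova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (any(table(group) == 0L)) stop("a group has zero observations")
  if (length(values) - nlevels(group) < 1L) stop("not enough residual df")
  an <- stats::anova(stats::lm(values ~ group))
  list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
       p.value = an$`Pr(>F)`[1])
}
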