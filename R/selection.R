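# Two-stage feature selection: Wilcoxon-Mann-Whitney screening followed by
# L1-penalized logistic regression with repeated cross-validated penalty
# tuning.

# Two-sided Mann-Whitney p-value for one feature. Exact via the null run
# distribution when both groups are small and tie-free; otherwise normal
# approximation with tie and continuity correction.
wmwPvalue <- function(x1, x2, exactMax = 8L) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- tabulate(match(r, unique(r)))
  hasTies <- any(ties > 1)
  if (!hasTies && min(n1, n2) <= exactMax) {
    p <- if (u > n1 * n2 / 2)
      2 * pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    else
      2 * pwilcox(u, n1, n2)
    return(min(1, p))
  }
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1) # all values tied: no separation
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

#' Wilcoxon-Mann-Whitney screening of a feature table
#'
#' Computes the two-sided Mann-Whitney p-value of every feature for the
#' grade III vs IV contrast and keeps features with `p < alpha` (strict).
#' Exact p-values are used for small tie-free groups, otherwise the normal
#' approximation with tie and continuity correction. Constant features get
#' p = 1 and are never selected.
#'
#' @param X subjects-by-features numeric matrix.
#' @param grade character vector of `"III"`/`"IV"` per row of `X`.
#' @param alpha screening level (default 0.001).
#' @return List with `pvalues` (named numeric) and `screened` (character
#'   descriptor ids passing the screen).
#' @export
wmwScreen <- function(X, grade, alpha = 0.001) {
  g1 <- grade == "III"
  if (!any(g1) || !any(grade == "IV"))
    gliostop("gliorad_invalid_argument",
             "screening needs both grades present")
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  st <- cpp_wmw_stats(X, g1)
  n1 <- st$n1; n2 <- st$n2; n <- n1 + n2
  u <- st$u
  p <- numeric(ncol(X))
  exact <- !st$hasTies & min(n1, n2) <= 8
  if (any(exact)) {
    ue <- u[exact]
    pe <- ifelse(ue > n1 * n2 / 2,
                 2 * pwilcox(ue - 1, n1, n2, lower.tail = FALSE),
                 2 * pwilcox(ue, n1, n2))
    p[exact] <- pmin(1, pe)
  }
  if (any(!exact)) {
    ua <- u[!exact]
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - st$tiecorr[!exact] / (n * (n - 1)))
    z <- ua - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    pa <- pmin(1, 2 * pnorm(-abs(z)))
    pa[sigma2 <= 0] <- 1 # all values tied: no separation
    p[!exact] <- pa
  }
  names(p) <- colnames(X)
  list(pvalues = p, screened = names(p)[p < alpha])
}

#' Fit L1-penalized logistic regression by coordinate descent
#'
#' Minimizes the penalized negative log-likelihood
#' `sum_i [-y_i log h_i - (1 - y_i) log(1 - h_i)] + lambda * ||beta||_1`
#' (logistic link, unpenalized intercept) by cyclic coordinate descent with
#' soft thresholding on the iteratively reweighted least-squares quadratic,
#' with a step-halving safeguard so the penalized objective never increases
#' across (outer) iterations. Slopes are exactly zero or not; no epsilon
#' thresholding is needed to read off the selected set.
#'
#' @param X standardized predictor matrix (subjects x features).
#' @param y 0/1 response (grade IV = 1).
#' @param lambda penalty weight (>= 0), on the summed-loss scale.
#' @param tol convergence threshold on the largest coefficient change per
#'   outer iteration.
#' @param maxIter outer-iteration limit; non-convergence returns the best
#'   iterate with a warning.
#' @param betaInit,interceptInit optional warm start.
#' @param traceObjective record the penalized objective after each sweep.
#' @return List with `beta` (named), `intercept`, `iter`, `converged`,
#'   `objective` (per-sweep values when traced).
#' @export
lassoFit <- function(X, y, lambda, tol = 1e-7, maxIter = 1e5,
                     betaInit = NULL, interceptInit = NULL,
                     traceObjective = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), lambda >= 0)
  if (is.null(betaInit)) betaInit <- numeric(ncol(X))
  if (is.null(interceptInit))
    interceptInit <- qlogisSafe(mean(y))
  fit <- cpp_lasso_cd(X, y, lambda, tol, as.integer(maxIter),
                      as.numeric(betaInit), interceptInit,
                      traceObjective)
  if (!fit$converged)
    gliowarn("gliorad_no_convergence",
             "coordinate descent hit the sweep limit (%d)", maxIter)
  names(fit$beta) <- colnames(X)
  fit
}

qlogisSafe <- function(p) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

#' Penalized logistic objective value
#'
#' @param X predictor matrix; @param y 0/1 response; @param beta slopes;
#' @param intercept scalar; @param lambda penalty weight.
#' @return Objective value (summed loss + L1 penalty).
#' @export
lassoObjective <- function(X, y, beta, intercept, lambda) {
  eta <- intercept + as.numeric(as.matrix(X) %*% beta)
  sum(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta)))) +
    lambda * sum(abs(beta))
}

#' Smallest penalty that zeroes every slope
#'
#' At `lambda >= lambdaMax(X, y)` the LASSO solution has all slopes exactly
#' zero and intercept `logit(mean(y))` (the subgradient condition at the
#' null model).
#'
#' @param X standardized predictor matrix; @param y 0/1 response.
#' @return The penalty bound `max_j |sum_i x_ij (y_i - mean(y))|`.
#' @export
lambdaMax <- function(X, y) {
  max(abs(crossprod(as.matrix(X), y - mean(y))))
}

#' Default penalty grid
#'
#' Log-spaced over the tuning range `[1e-6, 1e2]`.
#' @param length number of grid points (default 33).
#' @return Decreasing numeric vector of penalty values.
#' @export
lambdaGrid <- function(length = 33L) {
  sort(10^seq(-6, 2, length.out = length), decreasing = TRUE)
}

# Fit the full penalty path with warm starts, largest penalty first. The
# sweep cap bounds work at tiny penalties on separable data, where the
# unpenalized optimum diverges; held-out AUC is insensitive to the tail of
# that trajectory.
lassoPath <- function(X, y, lambdas, tol = 1e-5, maxIter = 20L) {
  beta <- numeric(ncol(X))
  b0 <- qlogisSafe(mean(y))
  fits <- vector("list", length(lambdas))
  for (k in seq_along(lambdas)) {
    fit <- suppressWarnings(
      lassoFit(X, y, lambdas[k], tol = tol, maxIter = maxIter,
               betaInit = beta, interceptInit = b0))
    beta <- fit$beta
    b0 <- fit$intercept
    fits[[k]] <- fit
  }
  fits
}

#' Tune the LASSO penalty by repeated stratified cross-validation
#'
#' For each penalty in the grid, fits on k-1 folds and scores the held-out
#' fold by AUC; folds are stratified by grade and the scheme is repeated
#' with distinct seeded shuffles. The chosen penalty maximizes the mean AUC
#' over all fold-repeats, with ties broken toward the largest penalty
#' (sparser model).
#'
#' @param X standardized subjects-by-features matrix (screened features).
#' @param y 0/1 response (grade IV = 1).
#' @param lambdas penalty grid (default [lambdaGrid()]).
#' @param folds,repeats cross-validation scheme (default 5 x 5).
#' @param seed RNG seed for the fold shuffles.
#' @return List with `lambda` (the chosen penalty) and `cvCurve`
#'   (data.frame `lambda`, `meanAUC`).
#' @export
tuneLambda <- function(X, y, lambdas = lambdaGrid(), folds = 5L,
                       repeats = 5L, seed = 1L) {
  lambdas <- sort(lambdas, decreasing = TRUE)
  if (length(lambdas) == 1L)
    return(list(lambda = lambdas,
                cvCurve = data.frame(lambda = lambdas, meanAUC = NA_real_)))
  aucs <- matrix(NA_real_, nrow = folds * repeats, ncol = length(lambdas))
  row <- 0L
  for (r in seq_len(repeats)) {
    set.seed(subSeed(seed, r))
    fold <- stratifiedFolds(ifelse(y == 1, "IV", "III"), folds)
    for (f in seq_len(folds)) {
      row <- row + 1L
      tr <- fold != f
      fits <- lassoPath(X[tr, , drop = FALSE], y[tr], lambdas)
      for (k in seq_along(lambdas)) {
        eta <- fits[[k]]$intercept +
          as.numeric(X[!tr, , drop = FALSE] %*% fits[[k]]$beta)
        aucs[row, k] <- if (length(unique(y[!tr])) < 2) NA_real_
        else rocAuc(eta, y[!tr])$auc
      }
    }
  }
  meanAuc <- colMeans(aucs, na.rm = TRUE)
  best <- which(meanAuc >= max(meanAuc) - 1e-12)[1] # largest lambda wins ties
  list(lambda = lambdas[best],
       cvCurve = data.frame(lambda = lambdas, meanAUC = meanAuc))
}

#' Two-stage feature selection on a training cohort
#'
#' Runs the WMW screen at `alpha`, standardizes the screened features
#' (training statistics only), tunes the LASSO penalty by repeated
#' stratified CV maximizing mean AUC, and refits on the full training set
#' at the chosen penalty. Features with nonzero slopes are the selected
#' set. All standardization statistics are retained so validation rows can
#' be transformed with training statistics.
#'
#' @param ft a [FeatureTable-class] (training subjects only).
#' @param alpha screening level (default 0.001).
#' @param lambdas penalty grid (default [lambdaGrid()]).
#' @param folds,repeats CV scheme for penalty tuning (default 5 x 5).
#' @param seed RNG seed.
#' @return A [SelectionResult-class].
#' @export
selectFeatures <- function(ft, alpha = 0.001, lambdas = lambdaGrid(),
                           folds = 5L, repeats = 5L, seed = 1L) {
  X <- featureValues(ft)
  grade <- grades(ft)
  scr <- wmwScreen(X, grade, alpha)
  if (length(scr$screened) == 0L) {
    psum <- quantile(scr$pvalues, c(0, 0.01, 0.05, 0.5))
    gliostop("gliorad_selection_empty",
             "no features pass the WMW screen at alpha = %g (p quantiles: %s)",
             alpha, paste(signif(psum, 3), collapse = ", "))
  }
  y <- as.numeric(grade == "IV")
  std <- standardizeTrain(X[, scr$screened, drop = FALSE])
  tuned <- tuneLambda(std$X, y, lambdas, folds, repeats, seed)
  fit <- suppressWarnings(
    lassoFit(std$X, y, tuned$lambda, tol = 1e-7, maxIter = 150))
  selected <- names(fit$beta)[fit$beta != 0]
  new("SelectionResult", screened = scr$screened, pvalues = scr$pvalues,
      selected = selected, beta = fit$beta, intercept = fit$intercept,
      lambda = tuned$lambda, cvCurve = tuned$cvCurve,
      center = std$center, scale = std$scale)
}
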