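test_that("WMW p-values match enumeration and wilcox.test", {
  # exact case: 2 of 20 group assignments are at least as extreme
  p <- gliorad:::wmwPvalue(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p, 0.1)
  expect_equal(p, bfWmwP(c(1, 2, 3), c(4, 5, 6)))

  # exact path agrees with full enumeration on random tie-free data
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:8, 1)
    x1 <- rnorm(n1); x2 <- rnorm(n2, mean = runif(1, -1, 1))
    expect_equal(gliorad:::wmwPvalue(x1, x2), bfWmwP(x1, x2),
                 tolerance = 1e-12)
  }

  # normal approximation agrees with enumeration within 0.01 at min(n) = 8
  set.seed(12)
  for (i in 1:10) {
    x1 <- rnorm(8); x2 <- rnorm(9, mean = runif(1, -1.5, 1.5))
    pApprox <- gliorad:::wmwPvalue(x1, x2, exactMax = 0L)
    expect_lt(abs(pApprox - bfWmwP(x1, x2)), 0.01)
  }

  # screening matrix path agrees with wilcox.test on both branches
  set.seed(13)
  X <- cbind(matrix(rnorm(19 * 6), 19, 6),
             round(matrix(rnorm(19 * 2), 19, 2))) # ties in last columns
  colnames(X) <- sprintf("c%d", 1:8)
  grade <- c(rep("III", 9), rep("IV", 10))
  scr <- wmwScreen(X, grade, alpha = 0.05)
  # min(n) = 9 here, so the screen takes the corrected normal branch;
  # force wilcox.test onto the same approximation
  ref <- vapply(1:8, function(j) {
    suppressWarnings(stats::wilcox.test(
      X[grade == "III", j], X[grade == "IV", j],
      exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  expect_equal(unname(scr$pvalues), ref, tolerance = 1e-12)

  # constant features can never be selected
  Xc <- cbind(X, constant = 1)
  expect_equal(unname(wmwScreen(Xc, grade)$pvalues["constant"]), 1)

  # perfectly separated groups of 10 vs 10 pass the 0.001 screen
  sep <- matrix(c(rnorm(10), rnorm(10) + 50), ncol = 1)
  colnames(sep) <- "s"
  ps <- wmwScreen(sep, rep(c("III", "IV"), each = 10))
  expect_lt(ps$pvalues[["s"]], 0.001)
  expect_identical(ps$screened, "s")
})

test_that("LASSO solutions satisfy the subgradient bound and match oracles", {
  set.seed(21)
  X <- scale(matrix(rnorm(40 * 6), 40, 6))
  colnames(X) <- sprintf("x%d", 1:6)
  y <- rbinom(40, 1, plogis(1.2 * X[, 1] - 0.8 * X[, 2]))

  # at lambda >= lambda_max every slope is exactly zero
  lmax <- lambdaMax(X, y)
  f0 <- lassoFit(X, y, lmax * (1 + 1e-9))
  expect_identical(unname(f0$beta), rep(0, 6))
  expect_equal(f0$intercept, log(mean(y) / (1 - mean(y))), tolerance = 1e-8)
  # just below lambda_max at least one slope activates
  f1 <- lassoFit(X, y, lmax * 0.95)
  expect_gt(sum(f1$beta != 0), 0)

  # near-unpenalized fit matches glm on a non-separable toy
  fit <- lassoFit(X[, 1:2], y, 1e-6, tol = 1e-10, maxIter = 1e4)
  g <- glm(y ~ X[, 1:2], family = binomial())
  expect_lt(max(abs(c(fit$intercept, fit$beta) - coef(g))), 1e-3)

  # 2-feature moderate penalty: brute-force grid minimization oracle
  lam <- 4
  fit2 <- lassoFit(X[, 1:2], y, lam, tol = 1e-10, maxIter = 1e4)
  obj2 <- lassoObjective(X[, 1:2], y, fit2$beta, fit2$intercept, lam)
  grid <- seq(-1.5, 1.5, by = 0.02)
  best <- Inf
  for (b1 in grid) for (b2 in grid) {
    o <- lassoObjective(X[, 1:2], y, c(b1, b2),
                        qlogis(mean(y)), lam)
    if (o < best) best <- o
  }
  expect_lte(obj2, best + 0.05) # within grid resolution of the optimum
  expect_gte(obj2, best - 0.5)  # and no better than the true optimum allows

  # objective trace is non-increasing
  tr <- lassoFit(X, y, 2, traceObjective = TRUE)
  expect_true(all(diff(tr$objective) <= 1e-10))

  # endpoint monotonicity of the solution path
  pathFits <- gliorad:::lassoPath(X, y, lambdaGrid(10))
  nnz <- vapply(pathFits, function(f) sum(f$beta != 0), numeric(1))
  expect_gte(nnz[length(nnz)], nnz[1])
})

test_that("penalty tuning maximizes CV AUC with sparse tie-breaking", {
  # degenerate single-point grid
  t1 <- tuneLambda(scale(matrix(rnorm(60), 30, 2)),
                   rep(c(0, 1), 15), lambdas = 0.5)
  expect_equal(t1$lambda, 0.5)

  # one perfectly informative feature is retained with high CV AUC
  set.seed(31)
  n <- 60
  X <- cbind(inf1 = c(rnorm(30), rnorm(30) + 4),
             matrix(rnorm(n * 20), n, 20))
  colnames(X)[-1] <- sprintf("n%d", 1:20)
  y <- rep(c(0, 1), each = 30)
  Xs <- scale(X)
  tuned <- tuneLambda(Xs, y, lambdaGrid(15), folds = 5, repeats = 2,
                      seed = 2)
  expect_gt(max(tuned$cvCurve$meanAUC, na.rm = TRUE), 0.95)
  fit <- lassoFit(Xs, y, tuned$lambda)
  expect_true(fit$beta[["inf1"]] != 0)

  # pure-noise features: CV AUC stays near chance for every penalty
  aucRange <- c()
  for (seed in 1:10) {
    set.seed(seed + 100)
    Xn <- scale(matrix(rnorm(60 * 15), 60, 15))
    yn <- rep(c(0, 1), each = 30)
    tn <- tuneLambda(Xn, yn, lambdaGrid(8), folds = 5, repeats = 1,
                     seed = seed)
    aucRange <- c(aucRange, range(tn$cvCurve$meanAUC, na.rm = TRUE))
  }
  expect_gt(median(aucRange), 0.35)
  expect_lt(median(aucRange), 0.65)
})

test_that("two-stage selection recovers planted features and stays sparse under the null", {
  # planted signal: 5 informative of 500 (kept small for speed; the
  # full-space recovery experiment runs in the acceptance suite)
  hits <- c()
  for (seed in 1:10) {
    ft <- syntheticTable(n1 = 30, n2 = 30, p = 500, informative = 5,
                         shift = 2, seed = seed)
    sel <- selectFeatures(ft, lambdas = lambdaGrid(12), folds = 3,
                          repeats = 1, seed = seed)
    expect_true(all(sel@selected %in% sel@screened))
    hits <- c(hits, sum(sprintf("f%04d", 1:5) %in% sel@selected))
  }
  expect_gte(median(hits), 3)

  # null: few features survive, or none at all (error path)
  sizes <- c()
  for (seed in 1:5) {
    ft0 <- syntheticTable(n1 = 30, n2 = 30, p = 500, informative = 0,
                          seed = seed + 50)
    sizes <- c(sizes, tryCatch(
      length(selectFeatures(ft0, lambdas = lambdaGrid(12), folds = 3,
                            repeats = 1, seed = seed)@selected),
      gliorad_selection_empty = function(e) 0L))
  }
  expect_lte(median(sizes), 5)
})

test_that("held-out subjects cannot influence training-fold selection", {
  ft <- syntheticTable(n1 = 15, n2 = 15, p = 200, informative = 3,
                       shift = 2, seed = 9)
  train <- 1:24
  sel1 <- selectFeatures(ft[, train], lambdas = lambdaGrid(8), folds = 3,
                         repeats = 1, seed = 4)
  # permute the held-out subjects' labels; training selection is identical
  ftPerm <- ft
  cd <- SummarizedExperiment::colData(ftPerm)
  cd$grade[25:30] <- rev(cd$grade[25:30])
  SummarizedExperiment::colData(ftPerm) <- cd
  sel2 <- selectFeatures(ftPerm[, train], lambdas = lambdaGrid(8),
                         folds = 3, repeats = 1, seed = 4)
  expect_identical(sel1@selected, sel2@selected)
  expect_identical(sel1@beta, sel2@beta)
})
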