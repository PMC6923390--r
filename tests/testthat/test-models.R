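test_that("rank-based AUC matches pair counting and handles ties", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(rocAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # 3 of 4 pairs concordant under labels (1,1,0,0)
  expect_equal(rocAuc(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)

  set.seed(41)
  for (i in 1:20) {
    sc <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE) # force ties
    lb <- rbinom(12, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(rocAuc(sc, lb)$auc, bfAuc(sc, lb))
  }

  # invariance under strictly monotone score transforms
  set.seed(42)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
  expect_equal(rocAuc(plogis(3 * sc + 1), lb)$auc, rocAuc(sc, lb)$auc)

  # ROC endpoints and monotonicity
  r <- rocAuc(rnorm(20), rep(c(0, 1), 10))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  expect_error(rocAuc(rnorm(5), rep(1, 5)),
               class = "gliorad_invalid_argument")
})

test_that("every algorithm separates a separable toy and is deterministic", {
  set.seed(51)
  n <- 40
  X <- cbind(a = c(rnorm(20), rnorm(20) + 6), b = rnorm(n))
  y <- rep(c(0, 1), each = 20)
  Xs <- scale(X)
  for (spec in defaultModelSpecs(reduced = TRUE)) {
    fit <- tuneAndFit(spec, Xs, y, seed = 1, folds = 3, repeats = 1)
    expect_equal(rocAuc(fit$score(Xs), y)$auc, 1.0,
                 tolerance = 1e-9, label = spec$algorithm)
    fit2 <- tuneAndFit(spec, Xs, y, seed = 1, folds = 3, repeats = 1)
    expect_identical(fit$setting, fit2$setting)
    expect_equal(fit$score(Xs), fit2$score(Xs), tolerance = 1e-12,
                 label = paste(spec$algorithm, "determinism"))
  }
  expect_error(tuneAndFit(defaultModelSpecs()$NB, Xs, rep(1, n)),
               class = "gliorad_invalid_argument")
})

test_that("label-permuted training data gives chance-level CV AUC", {
  set.seed(52)
  aucs <- c()
  for (seed in 1:10) {
    set.seed(seed + 500)
    X <- scale(matrix(rnorm(60 * 5), 60, 5))
    y <- sample(rep(c(0, 1), each = 30))
    for (nm in c("LR", "SVM")) {
      spec <- defaultModelSpecs(reduced = TRUE)[[nm]]
      fit <- tuneAndFit(spec, X, y, seed = seed, folds = 3, repeats = 1)
      if (!is.null(fit$cv)) aucs <- c(aucs, max(fit$cv$meanAUC))
    }
  }
  expect_gt(median(aucs), 0.35)
  expect_lt(median(aucs), 0.70)
})

test_that("LOOCV touches each subject exactly once and scores perfectly separable phantoms", {
  ft <- syntheticTable(n1 = 20, n2 = 20, p = 300, informative = 1,
                       shift = 8, seed = 61)
  rep <- loocv(ft, specs = defaultModelSpecs(reduced = TRUE)["LR"],
               seed = 2, lambdas = lambdaGrid(8), selFolds = 3,
               selRepeats = 1, tuneFolds = 3, tuneRepeats = 1)
  expect_equal(nrow(rep@scores), 40)
  expect_equal(sum(!is.na(rep@scores$LR)), 40) # one score per subject
  expect_equal(metrics(rep)$auc[1], 1.0)
  expect_length(rep@foldSelections, 40)
  expect_true(all(vapply(rep@foldSelections,
                         function(s) "f0001" %in% s, logical(1))))

  expect_error(loocv(ft[, 1:5]), class = "gliorad_invalid_argument")
})

test_that("independent validation uses the all-folds intersection and transfers signal", {
  primary <- syntheticTable(n1 = 15, n2 = 15, p = 200, informative = 2,
                            shift = 6, seed = 71)
  validation <- syntheticTable(n1 = 10, n2 = 10, p = 200, informative = 2,
                               shift = 6, seed = 72)
  repL <- loocv(primary, specs = defaultModelSpecs(reduced = TRUE)[c("LR", "NB")],
                seed = 3, lambdas = lambdaGrid(8), selFolds = 3,
                selRepeats = 1, tuneFolds = 3, tuneRepeats = 1)
  common <- Reduce(intersect, repL@foldSelections)
  repV <- independentValidation(primary, validation, repL,
                                specs = defaultModelSpecs(reduced = TRUE)[c("LR", "NB")],
                                seed = 3, tuneFolds = 3, tuneRepeats = 1)
  expect_identical(repV@foldSelections$intersection, common)
  expect_gt(min(metrics(repV)$auc), 0.9)

  # an explicitly empty intersection is an error, never a silent fallback
  repBroken <- repL
  repBroken@foldSelections[[1]] <- "f9999"
  expect_error(independentValidation(primary, validation, repBroken),
               class = "gliorad_empty_intersection")
})

test_that("across-model summaries follow the printed-table conventions", {
  metricsDf <- data.frame(model = c("LR", "SVM", "SNN", "RF", "NB"),
                          accuracy = c(0.834, 0.866, 0.796, 0.815, 0.809),
                          sensitivity = c(0.833, 0.902, 0.833, 0.892, 0.853),
                          specificity = c(0.836, 0.800, 0.727, 0.673, 0.727),
                          auc = c(0.915, 0.932, 0.896, 0.902, 0.867))
  rep <- new("EvaluationReport", metrics = metricsDf, roc = list(),
             scores = data.frame(), foldSelections = list(),
             failedFolds = integer(0), kind = "loocv")
  s <- summarizeReport(rep)
  aucRow <- s[s$metric == "auc", ]
  expect_equal(round(aucRow$mean, 3), 0.902)
  expect_equal(round(aucRow$sd, 3), 0.024)
  # CI compared at printed precision +/- one last digit: the table's own
  # entries are rounded to 3 decimals before this recomputation
  expect_lt(max(abs(c(aucRow$ci_low, aucRow$ci_high) - c(0.873, 0.932))),
            0.0011)
  accRow <- s[s$metric == "accuracy", ]
  expect_equal(round(c(accRow$mean, accRow$sd), 3), c(0.824, 0.027))
  expect_equal(round(c(accRow$ci_low, accRow$ci_high), 3),
               c(0.790, 0.858))

  # identical metrics across models: zero spread
  same <- metricsDf
  same[, -1] <- 0.8
  rep2 <- new("EvaluationReport", metrics = same, roc = list(),
              scores = data.frame(), foldSelections = list(),
              failedFolds = integer(0), kind = "loocv")
  s2 <- summarizeReport(rep2)
  expect_true(all(s2$sd == 0))
  expect_true(all(s2$ci_high - s2$ci_low == 0))

  # two models: computed but flagged low-n
  s3 <- summarizeReport(new("EvaluationReport",
                            metrics = metricsDf[1:2, ], roc = list(),
                            scores = data.frame(),
                            foldSelections = list(),
                            failedFolds = integer(0), kind = "loocv"))
  expect_true(all(s3$low_n))
})
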