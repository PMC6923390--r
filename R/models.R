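# Classifier construction, LOOCV and independent validation. The five
# model families (LR, SVM-RBF, SNN, RF, NB) are backed by established
# fitting engines; the tuning protocol, CV plumbing, scoring and ROC/AUC
# are package code. Grade IV is the positive class throughout.

#' Default model specifications
#'
#' Returns the five classifier specifications with their hyper-parameter
#' grids: ridge-penalized logistic regression (LR), RBF-kernel support
#' vector machine (SVM), single-hidden-layer neural network (SNN), random
#' forest with 1000 trees (RF), and Gaussian naive Bayes (NB, untuned).
#' Grids are expressed as functions of the feature count `p` where needed
#' and are fully config-exposed; a `reduced = TRUE` call returns the
#' desk-scale grids used by the package's own experiments.
#'
#' @param reduced use the smaller desk-scale grids.
#' @return Named list of model specs (`algorithm`, `grid`, `fixed`).
#' @export
defaultModelSpecs <- function(reduced = FALSE) {
  snnGrid <- if (reduced)
    expand.grid(size = c(3L, 8L), decay = 1e-2)
  else
    expand.grid(size = c(3L, 8L), decay = c(1e-4, 1e-2))
  svmGrid <- if (reduced)
    expand.grid(gammaScale = 1, cost = c(1, 10))
  else
    expand.grid(gammaScale = c(0.5, 1, 2), cost = c(0.1, 1, 10))
  lrGrid <- if (reduced)
    expand.grid(ridge = c(1e-3, 1e-1))
  else
    expand.grid(ridge = c(1e-4, 1e-3, 1e-2, 1e-1, 1))
  rfGrid <- if (reduced)
    expand.grid(mtryRule = "sqrt", stringsAsFactors = FALSE)
  else
    expand.grid(mtryRule = c("sqrt", "third"), stringsAsFactors = FALSE)
  list(
    LR = list(algorithm = "LR", grid = lrGrid, fixed = list()),
    SVM = list(algorithm = "SVM", grid = svmGrid, fixed = list()),
    SNN = list(algorithm = "SNN", grid = snnGrid,
               fixed = list(maxit = 150L)),
    RF = list(algorithm = "RF", grid = rfGrid,
              fixed = list(numTrees = 1000L)),
    NB = list(algorithm = "NB", grid = expand.grid(), fixed = list()))
}

# Fit one algorithm at one grid setting; returns a scoring closure that
# maps a new standardized matrix to P(grade IV).
fitOne <- function(algorithm, setting, fixed, X, y, seed) {
  p <- ncol(X)
  switch(algorithm,
    LR = {
      # ridge logistic via glmnet; degenerate p = 1 gets a duplicate
      # column (glmnet needs >= 2), with halved coefficients by symmetry
      Xg <- if (p == 1L) cbind(X, X) else X
      fit <- glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                            lambda = setting$ridge, standardize = FALSE)
      function(Xn) {
        Xn <- if (p == 1L) cbind(Xn, Xn) else Xn
        as.numeric(predict(fit, Xn, type = "response"))
      }
    },
    SVM = {
      gamma <- setting$gammaScale / max(1, p)
      fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                        gamma = gamma, cost = setting$cost, scale = FALSE)
      dvTr <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                              "decision.values"))
      # monotone probability calibration fitted on training data only
      cal <- suppressWarnings(glm(y ~ dv, family = binomial(),
                                  data = data.frame(y = y, dv = dvTr)))
      function(Xn) {
        dv <- as.numeric(attr(predict(fit, Xn, decision.values = TRUE),
                              "decision.values"))
        as.numeric(predict(cal, data.frame(dv = dv), type = "response"))
      }
    },
    SNN = {
      set.seed(seed)
      fit <- nnet::nnet(X, y, size = setting$size, decay = setting$decay,
                        maxit = fixed$maxit, entropy = TRUE, trace = FALSE)
      function(Xn) as.numeric(predict(fit, Xn))
    },
    RF = {
      mtry <- if (setting$mtryRule == "sqrt") max(1L, floor(sqrt(p)))
              else max(1L, floor(p / 3))
      df <- as.data.frame(X)
      fit <- ranger::ranger(x = df, y = factor(y, levels = c(0, 1)),
                            num.trees = fixed$numTrees, mtry = mtry,
                            probability = TRUE, seed = seed,
                            num.threads = 1)
      function(Xn) {
        pr <- predict(fit, data = as.data.frame(Xn),
                      num.threads = 1)$predictions
        as.numeric(pr[, "1"])
      }
    },
    NB = {
      fit <- e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0, 1)))
      # floor within-class SDs so constant features cannot yield NaNs
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2][tb[, 2] < 1e-6] <- 1e-6
        tb
      })
      function(Xn) {
        pr <- predict(fit, as.data.frame(Xn), type = "raw")
        as.numeric(pr[, "1"])
      }
    },
    gliostop("gliorad_config", "unknown algorithm '%s'", algorithm))
}

#' Tune and fit one classifier
#'
#' Grid search scored by mean AUC over seeded repeated stratified CV,
#' followed by a refit on the full training set at the best setting. A
#' single-setting grid (or an empty one, as for NB) skips the CV. Ties are
#' broken toward the first grid row, so the choice is deterministic under
#' a fixed seed.
#'
#' @param spec one element of [defaultModelSpecs()].
#' @param X standardized training matrix (selected features).
#' @param y 0/1 response (grade IV = 1).
#' @param seed RNG seed (controls fold shuffles and stochastic fitters).
#' @param folds,repeats CV scheme for the grid search.
#' @return List with `score` (closure mapping matrices to P(IV)),
#'   `setting` (chosen grid row), `cv` (per-setting mean AUC or NULL).
#' @export
tuneAndFit <- function(spec, X, y, seed = 1L, folds = 5L, repeats = 5L) {
  if (length(unique(y)) < 2)
    gliostop("gliorad_invalid_argument",
             "training set contains a single class")
  grid <- spec$grid
  cv <- NULL
  bestRow <- if (nrow(grid) <= 1L) 1L else {
    meanAuc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      aucs <- c()
      for (r in seq_len(repeats)) {
        set.seed(subSeed(seed, 100 + r))
        fold <- stratifiedFolds(ifelse(y == 1, "IV", "III"), folds)
        for (f in seq_len(folds)) {
          tr <- fold != f
          sc <- fitOne(spec$algorithm, grid[g, , drop = FALSE], spec$fixed,
                       X[tr, , drop = FALSE], y[tr],
                       subSeed(seed, 200 + r * folds + f))
          if (length(unique(y[!tr])) == 2)
            aucs <- c(aucs, rocAuc(sc(X[!tr, , drop = FALSE]), y[!tr])$auc)
        }
      }
      meanAuc[g] <- mean(aucs)
    }
    cv <- data.frame(grid, meanAUC = meanAuc)
    which.max(meanAuc)
  }
  score <- fitOne(spec$algorithm, grid[bestRow, , drop = FALSE], spec$fixed,
                  X, y, subSeed(seed, 999))
  list(score = score,
       setting = if (nrow(grid)) grid[bestRow, , drop = FALSE] else grid,
       cv = cv)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties contributing 1/2,
#' equivalent to the trapezoidal area under the empirical ROC; ROC points
#' are generated from all score thresholds. Grade IV (label 1) is
#' positive.
#'
#' @param scores numeric scores, higher = more grade-IV-like.
#' @param labels 0/1 numeric (or `"III"`/`"IV"` character) labels.
#' @return List with `auc` and `roc` (data.frame `fpr`, `tpr`).
#' @export
rocAuc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.numeric(as.character(labels) == "IV")
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    gliostop("gliorad_invalid_argument",
             "AUC undefined with a single class")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE) # one point per distinct threshold
  roc <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(auc = auc, roc = roc)
}

confusionMetrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = tp / max(1, tp + fn),
    specificity = tn / max(1, tn + fp))
}

#' Leave-one-out cross-validation of the full modeling pipeline
#'
#' For each subject: hold it out, rerun the entire selection stage
#' (screening, penalty tuning, final LASSO fit) on the remaining subjects,
#' tune and fit every model on the selected standardized features, and
#' score the held-out subject. Out-of-fold scores are aggregated into one
#' ROC/AUC per model; hard predictions use a 0.5 probability threshold.
#' Folds whose selection is empty are recorded and skipped.
#'
#' @param ft primary-cohort [FeatureTable-class].
#' @param specs model specifications ([defaultModelSpecs()]).
#' @param seed base RNG seed.
#' @param alpha,lambdas,selFolds,selRepeats selection-stage settings
#'   passed to [selectFeatures()].
#' @param tuneFolds,tuneRepeats model-tuning CV scheme.
#' @param verbose log per-fold progress.
#' @return An [EvaluationReport-class] with `kind = "loocv"`.
#' @export
loocv <- function(ft, specs = defaultModelSpecs(), seed = 1L,
                  alpha = 0.001, lambdas = lambdaGrid(), selFolds = 5L,
                  selRepeats = 5L, tuneFolds = 5L, tuneRepeats = 5L,
                  verbose = FALSE) {
  n <- ncol(ft)
  if (n < 10)
    gliostop("gliorad_invalid_argument", "LOOCV needs at least 10 subjects")
  grade <- grades(ft)
  if (length(unique(grade)) < 2)
    gliostop("gliorad_invalid_argument", "both grades required")
  X <- featureValues(ft)
  y <- as.numeric(grade == "IV")
  scores <- matrix(NA_real_, nrow = n, ncol = length(specs),
                   dimnames = list(subjectIds(ft), names(specs)))
  foldSel <- vector("list", n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    t0 <- proc.time()[3]
    sel <- tryCatch(
      selectFeatures(ft[, -i], alpha = alpha, lambdas = lambdas,
                     folds = selFolds, repeats = selRepeats,
                     seed = subSeed(seed, i)),
      gliorad_selection_empty = function(e) NULL)
    if (is.null(sel) || length(sel@selected) == 0L) {
      failed <- c(failed, i)
      foldSel[[i]] <- character(0)
      next
    }
    foldSel[[i]] <- sel@selected
    Xtr <- applyStandardization(X[-i, sel@selected, drop = FALSE],
                                sel@center[sel@selected],
                                sel@scale[sel@selected])
    Xte <- applyStandardization(X[i, sel@selected, drop = FALSE],
                                sel@center[sel@selected],
                                sel@scale[sel@selected])
    for (mn in names(specs)) {
      fit <- tuneAndFit(specs[[mn]], Xtr, y[-i], seed = subSeed(seed, i),
                        folds = tuneFolds, repeats = tuneRepeats)
      scores[i, mn] <- fit$score(Xte)
    }
    if (verbose)
      message(sprintf("fold %d/%d: %d selected (%.1fs)", i, n,
                      length(sel@selected), proc.time()[3] - t0))
  }
  buildReport(scores, y, subjectIds(ft), foldSel, failed, kind = "loocv")
}

buildReport <- function(scores, y, ids, foldSel = list(),
                        failed = integer(0), kind) {
  ok <- rowSums(!is.na(scores)) > 0
  scorable <- sum(ok) > 0 && length(unique(y[ok])) == 2
  metrics <- do.call(rbind, lapply(colnames(scores), function(mn) {
    if (!scorable)
      return(data.frame(model = mn, accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        auc = NA_real_, row.names = NULL))
    s <- scores[ok, mn]
    ra <- rocAuc(s, y[ok])
    cm <- confusionMetrics(s, y[ok])
    data.frame(model = mn, accuracy = cm["accuracy"],
               sensitivity = cm["sensitivity"],
               specificity = cm["specificity"], auc = ra$auc,
               row.names = NULL)
  }))
  rocs <- if (!scorable) list() else
    lapply(setNames(colnames(scores), colnames(scores)),
           function(mn) rocAuc(scores[ok, mn], y[ok])$roc)
  sc <- data.frame(subject_id = ids, grade = ifelse(y == 1, "IV", "III"),
                   as.data.frame(scores), check.names = FALSE)
  new("EvaluationReport", metrics = metrics, roc = rocs, scores = sc,
      foldSelections = foldSel, failedFolds = as.integer(failed),
      kind = kind)
}

#' Independent validation with the all-folds feature intersection
#'
#' Takes the descriptors selected in every LOOCV fold of the primary
#' cohort, refits standardization and all models on the full primary
#' cohort restricted to that intersection, and evaluates once on the
#' validation cohort. An empty intersection is an error: there is no
#' principled fallback feature set.
#'
#' @param primary,validation [FeatureTable-class] cohorts.
#' @param loocvReport the [EvaluationReport-class] from [loocv()] on the
#'   primary cohort.
#' @param specs model specifications.
#' @param seed RNG seed.
#' @param tuneFolds,tuneRepeats model-tuning CV scheme.
#' @return An [EvaluationReport-class] with `kind = "validation"`.
#' @export
independentValidation <- function(primary, validation, loocvReport,
                                  specs = defaultModelSpecs(), seed = 1L,
                                  tuneFolds = 5L, tuneRepeats = 5L) {
  sel <- loocvReport@foldSelections
  sel <- sel[!vapply(sel, is.null, logical(1))]
  nonFailed <- sel[vapply(sel, length, integer(1)) > 0]
  if (!length(nonFailed))
    gliostop("gliorad_empty_intersection", "no successful LOOCV folds")
  common <- Reduce(intersect, nonFailed)
  if (!length(common))
    gliostop("gliorad_empty_intersection",
             "no feature was selected in every LOOCV fold; cannot validate")
  Xp <- featureValues(primary)[, common, drop = FALSE]
  yp <- as.numeric(grades(primary) == "IV")
  Xv <- featureValues(validation)[, common, drop = FALSE]
  yv <- as.numeric(grades(validation) == "IV")
  std <- standardizeTrain(Xp)
  Xvs <- applyStandardization(Xv, std$center, std$scale)
  scores <- matrix(NA_real_, nrow = nrow(Xv), ncol = length(specs),
                   dimnames = list(subjectIds(validation), names(specs)))
  for (mn in names(specs)) {
    fit <- tuneAndFit(specs[[mn]], std$X, yp, seed = subSeed(seed, 7),
                      folds = tuneFolds, repeats = tuneRepeats)
    scores[, mn] <- fit$score(Xvs)
  }
  rep <- buildReport(scores, yv, subjectIds(validation),
                     foldSel = list(intersection = common), kind = "validation")
  rep
}

#' Summarize metrics across models
#'
#' Per-metric mean, SD and 95% confidence interval across the evaluated
#' models (sample SD; t-based CI on the across-model mean). With fewer
#' than three models the CI is reported but flagged as low-n.
#'
#' @param report an [EvaluationReport-class].
#' @return data.frame with rows mean, sd, ci_low, ci_high per metric.
#' @export
summarizeReport <- function(report) {
  m <- report@metrics
  if (nrow(m) < 2)
    gliostop("gliorad_invalid_argument", "need at least 2 models")
  cols <- c("accuracy", "sensitivity", "specificity", "auc")
  out <- lapply(cols, function(cn) {
    v <- m[[cn]]
    k <- length(v)
    s <- sd(v)
    half <- stats::qt(0.975, df = k - 1) * s / sqrt(k)
    data.frame(metric = cn, mean = mean(v), sd = s,
               ci_low = mean(v) - half, ci_high = mean(v) + half,
               n_models = k, low_n = k < 3)
  })
  do.call(rbind, out)
}
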