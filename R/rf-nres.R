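# RF-NRES: PCA compound weights over the 30 five-day CGR features and a
# weighted random-forest classifier for the four N-responsiveness groups,
# with conventional supervised baselines.

nresClasses <- c("HYHN", "LYHN", "LYLN", "HYLN")

#' Reshape a tidy CGR table into the 30-column feature matrix
#'
#' One row per variety x treatment (x season when present); columns are
#' the 6 traits x 5 sections in a fixed, documented order
#' (trait-major: height_1-5 ... height_21-25, coverage_1-5, ...).
#'
#' @param cgrTable tidy CGR table from [buildCGRMatrix()].
#' @return list with \code{x} (numeric matrix, rownames = composite row
#'   keys), \code{rows} (data.frame of row identifiers) and
#'   \code{featureInfo} (data.frame: feature, trait, section).
#' @export
cgrFeatureMatrix <- function(cgrTable) {
  secs <- responseWindow()$sections$section
  traits <- nresTraits()
  featureInfo <- data.frame(
    feature = as.vector(t(outer(traits, secs, paste, sep = "_"))),
    trait = rep(traits, each = length(secs)),
    section = rep(secs, length(traits)),
    stringsAsFactors = FALSE)
  keyCols <- intersect(c("variety", "treatment", "season"),
                       names(cgrTable))
  key <- do.call(paste, c(cgrTable[keyCols], list(sep = "|")))
  rows <- unique(data.frame(cgrTable[keyCols], key = key,
                            stringsAsFactors = FALSE))
  X <- matrix(NA_real_, nrow(rows), nrow(featureInfo),
              dimnames = list(rows$key, featureInfo$feature))
  feat <- paste(cgrTable$trait, cgrTable$section, sep = "_")
  X[cbind(match(key, rows$key), match(feat, featureInfo$feature))] <-
    cgrTable$cgr
  if (anyNA(X))
    warning(sum(is.na(X)), " missing feature cell(s) in the CGR matrix")
  rownames(rows) <- NULL
  list(x = X, rows = rows[keyCols], featureInfo = featureInfo)
}

#' PCA compound weights of CGR features and traits
#'
#' Standardizes the 30 five-day CGR features, retains the leading
#' components whose cumulative contribution rate reaches
#' \code{ccrThreshold}, and weights each feature by the contribution-
#' rate-weighted sum of its absolute loadings. Trait weights are the
#' sums of each trait's five section weights. Both vectors are
#' normalized to sum to 1.
#'
#' @param features feature matrix (rows = samples, columns = the 30 CGR
#'   features) or the list from [cgrFeatureMatrix()].
#' @param ccrThreshold cumulative contribution-rate threshold
#'   (default 0.85).
#' @return list with \code{featureWeights} (30), \code{traitWeights}
#'   (6), \code{k}, \code{rates}.
#' @export
compoundWeights <- function(features, ccrThreshold = 0.85) {
  X <- if (is.list(features) && !is.data.frame(features)) features$x
       else as.matrix(features)
  if (nrow(X) < 3) stop("need at least 3 rows")
  sds <- apply(X, 2, stats::sd)
  if (all(sds < .Machine$double.eps^0.5))
    stop("constant feature matrix")
  pc <- stats::prcomp(X, center = TRUE,
                      scale. = ifelse(sds > 0, sds, 1))
  ev <- pc$sdev^2
  keep <- ev > max(ev) * 1e-12
  rates <- ev[keep] / sum(ev[keep])
  k <- which(cumsum(rates) >= ccrThreshold - 1e-12)[1]
  if (is.na(k)) k <- length(rates)
  w <- drop(abs(pc$rotation[, seq_len(k), drop = FALSE]) %*%
              rates[seq_len(k)])
  fw <- w / sum(w)
  trait <- sub("_[0-9]+-[0-9]+$", "", names(fw))
  tw <- tapply(fw, trait, sum)[nresTraits()]
  list(featureWeights = fw, traitWeights = tw / sum(tw),
       k = as.integer(k), rates = rates)
}

# Stratified split into train/test/verify index lists.
stratifiedSplit <- function(labels, split = c(0.70, 0.20, 0.10)) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  idx <- list(train = integer(), test = integer(), verify = integer())
  for (cl in unique(labels)) {
    rows <- sample(which(labels == cl))
    n <- length(rows)
    nTr <- min(max(1L, round(split[1] * n)), n)
    nTe <- min(n - nTr, max(if (split[2] > 0) 1L else 0L,
                            round(split[2] * n)))
    idx$train <- c(idx$train, rows[seq_len(nTr)])
    idx$test <- c(idx$test, rows[nTr + seq_len(nTe)])
    if (n > nTr + nTe)
      idx$verify <- c(idx$verify, rows[(nTr + nTe + 1):n])
  }
  idx
}

# Bootstrap-oversample minority classes with multiplicative jitter
# (sd = jitterFrac of each feature's scale) to balance the classes.
augmentBalance <- function(X, y, jitterFrac = 0.02) {
  tab <- table(y)
  target <- max(tab)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  addX <- list(); addY <- character()
  for (cl in names(tab)) {
    deficit <- target - tab[[cl]]
    if (deficit <= 0) next
    rows <- which(y == cl)
    pick <- sample(rows, deficit, replace = TRUE)
    jit <- matrix(stats::rnorm(deficit * ncol(X), 1, jitterFrac),
                  deficit, ncol(X))
    addX[[cl]] <- X[pick, , drop = FALSE] * jit
    addY <- c(addY, rep(cl, deficit))
  }
  if (length(addX)) {
    X <- rbind(X, do.call(rbind, addX))
    y <- c(y, addY)
  }
  list(x = X, y = y)
}

#' Train the RF-NRES weighted random-forest classifier
#'
#' Trains a random forest (default 26 trees, maximum depth 16) on CGR
#' features with PCA compound weights steering the trees: in the default
#' \code{"sampling"} mode the per-feature weights are used as
#' split-candidate sampling probabilities at every node; in
#' \code{"scaling"} mode features are rescaled by their weights before
#' training. Data are split into stratified training/testing/verification
#' sets (70/20/10 by default); classes are balanced in the training split
#' only, by bootstrap oversampling with 2\% multiplicative jitter.
#'
#' @param features numeric feature matrix (samples x features) or the
#'   list from [cgrFeatureMatrix()].
#' @param labels character/factor class labels, one per row.
#' @param weights per-feature weights (e.g.
#'   \code{compoundWeights(...)$featureWeights}); NULL trains an
#'   unweighted forest.
#' @param nTrees,maxDepth forest size and depth (defaults 26 and 16).
#' @param split train/test/verify fractions summing to 1.
#' @param augment balance training classes by oversampling
#'   (default TRUE).
#' @param weightMode \code{"sampling"} (default) or \code{"scaling"}.
#' @param seed integer RNG seed; the trained ensemble and report are
#'   reproducible under a fixed seed.
#' @return object of class \code{NRESModel}: list with the fitted
#'   \code{forest}, \code{weights}, \code{weightMode}, split indices and
#'   a \code{report} (overall/per-class test accuracy, verification
#'   accuracy, one-hot probability MAPE, 5-fold CV accuracy).
#' @export
trainRFNRES <- function(features, labels, weights = NULL,
                        nTrees = 26, maxDepth = 16,
                        split = c(0.70, 0.20, 0.10), augment = TRUE,
                        weightMode = c("sampling", "scaling"),
                        seed = 1L) {
  weightMode <- match.arg(weightMode)
  X <- if (is.list(features) && !is.data.frame(features)) features$x
       else as.matrix(features)
  y <- as.character(labels)
  if (length(y) != nrow(X)) stop("labels must match feature rows")
  if (length(unique(y)) < 2) stop("need at least 2 classes")
  withSeed(seed, {
    idx <- stratifiedSplit(y, split)
    if (length(unique(y[idx$train])) < length(unique(y)))
      stop("a class is absent from the training split")
    tr <- list(x = X[idx$train, , drop = FALSE], y = y[idx$train])
    if (augment) tr <- augmentBalance(tr$x, tr$y)
    scaleW <- NULL
    if (!is.null(weights) && weightMode == "scaling") {
      scaleW <- weights / max(weights)
      tr$x <- sweep(tr$x, 2, scaleW, `*`)
    }
    df <- data.frame(tr$x, check.names = FALSE)
    df$.class <- factor(tr$y, levels = sort(unique(y)))
    rfArgs <- list(
      dependent.variable.name = ".class", data = df,
      num.trees = nTrees, max.depth = maxDepth,
      probability = TRUE, seed = seed, num.threads = 1,
      respect.unordered.factors = "order")
    if (!is.null(weights) && weightMode == "sampling")
      rfArgs$split.select.weights <- unname(weights / sum(weights))
    forest <- do.call(ranger::ranger, rfArgs)

    predictClass <- function(x) {
      if (!is.null(scaleW)) x <- sweep(x, 2, scaleW, `*`)
      pr <- stats::predict(forest,
                           data.frame(x, check.names = FALSE))$predictions
      list(class = colnames(pr)[max.col(pr, ties.method = "first")],
           prob = pr)
    }

    evalSet <- function(rows) {
      if (!length(rows)) return(list(acc = NA_real_, perClass = NULL,
                                     mape = NA_real_))
      pred <- predictClass(X[rows, , drop = FALSE])
      acc <- mean(pred$class == y[rows])
      perClass <- vapply(sort(unique(y)), function(cl) {
        sel <- y[rows] == cl
        if (!any(sel)) NA_real_ else mean(pred$class[sel] == cl)
      }, numeric(1))
      onehot <- outer(y[rows], colnames(pred$prob), `==`) * 1
      denom <- pmax(onehot, 0.5)    # one-hot MAPE with bounded denominator
      mape <- mean(abs(pred$prob - onehot) / denom)
      list(acc = acc, perClass = perClass, mape = mape)
    }
    test <- evalSet(idx$test)
    verify <- evalSet(idx$verify)

    # 5-fold stratified CV on the full data with the same settings
    folds <- integer(length(y))
    for (cl in unique(y)) {
      rows <- sample(which(y == cl))
      folds[rows] <- rep_len(1:5, length(rows))
    }
    cvAcc <- vapply(1:5, function(f) {
      trRows <- which(folds != f); teRows <- which(folds == f)
      if (length(unique(y[trRows])) < 2) return(NA_real_)
      d <- data.frame(X[trRows, , drop = FALSE], check.names = FALSE)
      d$.class <- factor(y[trRows], levels = sort(unique(y)))
      a <- rfArgs; a$data <- d
      ff <- do.call(ranger::ranger, a)
      pr <- stats::predict(
        ff, data.frame(X[teRows, , drop = FALSE],
                       check.names = FALSE))$predictions
      mean(colnames(pr)[max.col(pr, ties.method = "first")] == y[teRows])
    }, numeric(1))

    structure(list(
      forest = forest, weights = weights, weightMode = weightMode,
      scaleW = scaleW, classes = sort(unique(y)), splitIdx = idx,
      seed = seed,
      report = list(
        testAccuracy = test$acc, perClassAccuracy = test$perClass,
        verifyAccuracy = verify$acc, mape = test$mape,
        cvAccuracy = mean(cvAcc, na.rm = TRUE),
        nTrain = nrow(df), split = split, augmented = augment)
    ), class = "NRESModel")
  })
}

#' @export
print.NRESModel <- function(x, ...) {
  r <- x$report
  cat(sprintf("RF-NRES model (%d trees, weighted: %s, mode: %s)\n",
              x$forest$num.trees, !is.null(x$weights), x$weightMode))
  cat(sprintf("  test accuracy %.3f | verify %.3f | 5-fold CV %.3f | MAPE %.3f\n",
              r$testAccuracy, r$verifyAccuracy, r$cvAccuracy, r$mape))
  invisible(x)
}

#' Predict N-responsiveness groups with an RF-NRES model
#'
#' @param object an \code{NRESModel}.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.NRESModel <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$scaleW)) x <- sweep(x, 2, object$scaleW, `*`)
  pr <- stats::predict(object$forest,
                       data.frame(x, check.names = FALSE))$predictions
  colnames(pr)[max.col(pr, ties.method = "first")]
}

# Compact SAMME AdaBoost on depth-2 rpart trees.
fitAdaboost <- function(X, y, nRounds = 30) {
  y <- factor(y)
  K <- nlevels(y)
  n <- length(y)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  df <- data.frame(X, check.names = FALSE)
  for (m in seq_len(nRounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = y), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 2,
                                                       cp = 0, minsplit = 2,
                                                       xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
            class = "sammeBoost")
}

predictAdaboost <- function(model, X) {
  df <- data.frame(X, check.names = FALSE)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$stumps)) {
    pred <- stats::predict(model$stumps[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + model$alphas[m]
  }
  model$levels[max.col(votes, ties.method = "first")]
}

#' Compare baseline classifiers on identical stratified splits
#'
#' Trains the requested models on identical stratified train/test splits
#' over \code{nSeeds} seeds and reports seed-averaged test accuracies.
#' Available models: \code{"svm"}, \code{"naive_bayes"}, \code{"knn"},
#' \code{"adaboost"}, \code{"xgboost"}, \code{"rf"} (plain random
#' forest) and \code{"rf_nres"} (weighted); the returned table includes
#' the plain-RF vs RF-NRES delta when both are present.
#'
#' @param features feature matrix or [cgrFeatureMatrix()] list.
#' @param labels class labels.
#' @param models character vector of model keys.
#' @param weights per-feature weights for \code{"rf_nres"} (computed via
#'   [compoundWeights()] when NULL).
#' @param nSeeds number of repeated splits (default 5).
#' @param seed base RNG seed.
#' @return list with \code{table} (model, mean_accuracy, sd_accuracy)
#'   and, when applicable, \code{rfDelta} (rf_nres minus rf).
#' @export
compareBaselines <- function(features, labels,
                             models = c("svm", "naive_bayes", "knn",
                                        "adaboost", "xgboost", "rf",
                                        "rf_nres"),
                             weights = NULL, nSeeds = 5, seed = 1L) {
  known <- c("svm", "naive_bayes", "knn", "adaboost", "xgboost", "rf",
             "rf_nres")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown model key(s): ", paste(bad, collapse = ", "))
  if (length(models) < 1) stop("request at least one model")
  X <- if (is.list(features) && !is.data.frame(features)) features$x
       else as.matrix(features)
  y <- factor(as.character(labels))
  if ("rf_nres" %in% models && is.null(weights))
    weights <- compoundWeights(X)$featureWeights

  accs <- matrix(NA_real_, nSeeds, length(models),
                 dimnames = list(NULL, models))
  for (s in seq_len(nSeeds)) {
    withSeed(seed + s - 1L, {
      idx <- stratifiedSplit(as.character(y), c(0.7, 0.3, 0))
      trX <- X[idx$train, , drop = FALSE]; trY <- y[idx$train]
      teX <- X[idx$test, , drop = FALSE]; teY <- y[idx$test]
      trDf <- data.frame(trX, check.names = FALSE)
      teDf <- data.frame(teX, check.names = FALSE)
      for (m in models) {
        pred <- switch(m,
          svm = as.character(stats::predict(
            e1071::svm(trX, trY, kernel = "radial"), teX)),
          naive_bayes = as.character(stats::predict(
            e1071::naiveBayes(trDf, trY), teDf)),
          knn = as.character(class::knn(trX, teX, trY, k = 5)),
          adaboost = predictAdaboost(fitAdaboost(trX, trY), teX),
          xgboost = {
            bst <- xgboost::xgboost(trX, trY, nrounds = 30,
                                    max_depth = 4, learning_rate = 0.3,
                                    nthreads = 1, verbosity = 0)
            as.character(stats::predict(bst, teX, type = "class"))
          },
          rf = {
            d <- trDf; d$.class <- trY
            ff <- ranger::ranger(dependent.variable.name = ".class",
                                 data = d, num.trees = 26,
                                 max.depth = 16, seed = seed + s,
                                 num.threads = 1)
            as.character(stats::predict(ff, teDf)$predictions)
          },
          rf_nres = {
            d <- trDf; d$.class <- trY
            ff <- ranger::ranger(
              dependent.variable.name = ".class", data = d,
              num.trees = 26, max.depth = 16, seed = seed + s,
              num.threads = 1,
              split.select.weights = unname(weights / sum(weights)))
            as.character(stats::predict(ff, teDf)$predictions)
          })
        accs[s, m] <- mean(pred == as.character(teY))
      }
    })
  }
  tab <- data.frame(model = models,
                    mean_accuracy = colMeans(accs),
                    sd_accuracy = apply(accs, 2, stats::sd),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$mean_accuracy), ]
  rownames(tab) <- NULL
  out <- list(table = tab, accuracies = accs)
  if (all(c("rf", "rf_nres") %in% models))
    out$rfDelta <- mean(accs[, "rf_nres"] - accs[, "rf"])
  out
}
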