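# Downstream analysis: whole-glycan embeddings, classification harness,
# and the evaluation metrics (Macro-F1, accuracy, AUPRC).

#' Embed a corpus with a pretrained model
#'
#' Deterministic inference (dropout off): each glycan's [Graph] token state
#' is its feature vector. Glycans whose node count exceeds the identifier
#' bank capacity are skipped and recorded.
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param corpus character vector of IUPAC strings (or data.frame with a
#'   \code{glycan} column).
#' @param batchSize forward batch size (results are independent of it).
#' @return matrix (one row per embedded glycan, d columns) with rownames the
#'   corpus strings and attribute \code{"skipped"} (data.frame input/reason);
#'   attribute \code{"fingerprint"} identifies the producing checkpoint.
#' @export
embedCorpus <- function(model, corpus, batchSize = 32L) {
  if (is.data.frame(corpus)) corpus <- corpus$glycan
  skipped <- data.frame(input = character(0), reason = character(0))
  tgs <- list(); keep <- character(0)
  for (tx in corpus) {
    r <- tryCatch(encodeGlycan(parseIUPAC(tx), model@vocab), glycanError = function(e) e)
    if (!inherits(r, "condition") && r@nNodes > model@config$maxNodes) {
      r <- simpleError(sprintf("glycan exceeds identifier capacity (%d nodes)", r@nNodes))
    }
    if (inherits(r, "condition")) {
      skipped <- rbind(skipped, data.frame(input = tx, reason = conditionMessage(r)))
    } else {
      tgs[[length(tgs) + 1L]] <- r
      keep <- c(keep, tx)
    }
  }
  if (length(tgs) == 0L)
    glycanStop("glycanAnalysisError", "no embeddable glycans in the corpus")
  E <- matrix(0, length(tgs), model@config$d)
  for (b in seq_len(ceiling(length(tgs) / batchSize))) {
    sel <- ((b - 1L) * batchSize + 1L):min(b * batchSize, length(tgs))
    out <- encoderForward(model, tgs[sel])
    E[sel, ] <- out$graphEmbedding
  }
  rownames(E) <- keep
  attr(E, "skipped") <- skipped
  attr(E, "fingerprint") <- sprintf("%d/%d/%d", model@meta$nodeVocabHash,
                                    model@meta$edgeVocabHash, model@config$seed)
  E
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics: Macro-F1, accuracy, AUPRC
#'
#' \code{macroF1} is the unweighted mean of per-class F1 scores over classes
#' present in either vector (a class with no true and no predicted instances
#' is excluded; an undefined per-class F1 counts as 0). \code{auprc} is the
#' area under the precision-recall curve via step interpolation of the
#' precision envelope over recall (the precision at recall r is the maximum
#' precision achievable at recall >= r).
#'
#' @param yTrue true labels (factor/character for classification; 0/1 or
#'   logical for \code{auprc}).
#' @param yPred predicted labels.
#' @param scores numeric scores for the positive class (\code{auprc}).
#' @return a single number in [0, 1].
#' @export
macroF1 <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred))
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  classes <- sort(unique(c(yTrue, yPred)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' @rdname macroF1
#' @export
accuracyScore <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred))
  mean(as.character(yTrue) == as.character(yPred))
}

#' @rdname macroF1
#' @export
auprc <- function(yTrue, scores) {
  stopifnot(length(yTrue) == length(scores))
  y <- as.integer(as.logical(yTrue))
  if (all(y == 0L)) glycanStop("glycanMetricError", "no positive instances")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # thresholds at distinct score values only
  keep <- c(diff(s) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  # precision envelope: max precision at recall >= r, then left step AUC
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

# ---- classification harness ------------------------------------------------

.logU <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

.svmSpace <- function(n) {
  data.frame(kernel = sample(c("radial", "linear"), n, replace = TRUE),
             C = .logU(n, 1e-3, 1e2), gamma = .logU(n, 1e-4, 1e-1),
             stringsAsFactors = FALSE)
}

.gbmSpace <- function(n) {
  data.frame(nrounds = sample(100:1000, n, replace = TRUE),
             eta = .logU(n, 0.01, 0.3),
             num_leaves = sample(20:150, n, replace = TRUE),
             max_depth = sample(5:20, n, replace = TRUE),
             reg_alpha = .logU(n, 1e-2, 1e1),
             reg_lambda = .logU(n, 1e-2, 1e1),
             colsample_bytree = stats::runif(n, 0.6, 1.0),
             subsample = stats::runif(n, 0.6, 1.0))
}

.fitSvm <- function(X, y, hp, classWeights) {
  e1071::svm(X, y, kernel = hp$kernel, cost = hp$C,
             gamma = if (hp$kernel == "radial") hp$gamma else 1 / ncol(X),
             class.weights = classWeights, probability = TRUE, scale = FALSE)
}

.predSvm <- function(fit, X, levels) {
  pr <- stats::predict(fit, X, probability = TRUE)
  probs <- attr(pr, "probabilities")[, levels, drop = FALSE]
  list(labels = as.character(pr), probs = probs)
}

.fitGbm <- function(X, y, hp, classWeights) {
  yl <- as.integer(y) - 1L
  k <- nlevels(y)
  w <- unname(classWeights[as.character(y)])
  params <- list(eta = hp$eta, max_depth = hp$max_depth,
                 max_leaves = hp$num_leaves, tree_method = "hist",
                 grow_policy = "lossguide", alpha = hp$reg_alpha,
                 lambda = hp$reg_lambda, colsample_bytree = hp$colsample_bytree,
                 subsample = hp$subsample, nthread = 1L,
                 objective = if (k == 2L) "binary:logistic" else "multi:softprob")
  if (k > 2L) params$num_class <- k
  xgboost::xgb.train(params,
                     xgboost::xgb.DMatrix(X, label = yl, weight = w),
                     nrounds = hp$nrounds, verbose = 0)
}

.predGbm <- function(fit, X, levels) {
  p <- stats::predict(fit, xgboost::xgb.DMatrix(X))
  k <- length(levels)
  probs <- if (k == 2L) cbind(1 - p, p) else matrix(p, ncol = k, byrow = TRUE)
  colnames(probs) <- levels
  list(labels = levels[max.col(probs, ties.method = "first")], probs = probs)
}

#' Downstream classification harness on embedding features
#'
#' Reproduces the evaluation protocol of the embedding benchmark: on the
#' fixed train/validation/test split, hyperparameters are selected by
#' randomized search (10 iterations for the SVM over RBF/linear kernels with
#' C ~ logU(1e-3, 1e2) and gamma ~ logU(1e-4, 1e-1); 15 iterations for the
#' gradient-boosted trees over the tree-size/learning-rate/regularization
#' ranges listed in \code{\link{trainConfig}}'s vignette) with 3-fold
#' cross-validation on train + validation, class-balanced weighting
#' throughout; the best configuration is refit on train + validation and
#' evaluated once on the test split. The whole procedure is repeated with
#' \code{nSeeds} seeds and metrics are reported as mean and s.d.
#'
#' @param features numeric matrix (rows = instances) such as
#'   \code{\link{embedCorpus}} output.
#' @param labels class labels, one per row.
#' @param split list with integer index vectors \code{train}, \code{val},
#'   \code{test} partitioning the rows.
#' @param taskType \code{"multiclass"} (Macro-F1 + accuracy) or
#'   \code{"binary"} (adds AUPRC; the positive class is the second factor
#'   level).
#' @param classifier \code{"svm"} or \code{"gbm"}.
#' @param nSeeds number of independent repetitions (default 3).
#' @param nIter randomized-search iterations; NULL picks 10 (svm) / 15 (gbm).
#' @param baseSeed base random seed.
#' @return data.frame with one row per metric: mean, sd, and the per-seed
#'   values as a matrix attribute \code{"runs"}.
#' @export
benchmarkClassify <- function(features, labels, split,
                              taskType = c("multiclass", "binary"),
                              classifier = c("svm", "gbm"),
                              nSeeds = 3L, nIter = NULL, baseSeed = 1L) {
  taskType <- match.arg(taskType)
  classifier <- match.arg(classifier)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  idx <- sort(c(split$train, split$val, split$test))
  if (!identical(idx, seq_len(nrow(features))) || anyDuplicated(idx))
    glycanStop("glycanAnalysisError", "split must partition the rows")
  y <- factor(labels)
  if (taskType == "binary" && nlevels(y) != 2L)
    glycanStop("glycanAnalysisError", "binary task needs exactly 2 classes")
  nIter <- nIter %||% if (classifier == "svm") 10L else 15L
  devIdx <- c(split$train, split$val)
  if (any(table(y[devIdx]) == 0L)) {
    missing <- levels(y)[table(y[devIdx]) == 0L]
    glycanStop("glycanAnalysisError",
               "class \"%s\" absent from the training data", missing[1L])
  }
  fitFun <- if (classifier == "svm") .fitSvm else .fitGbm
  predFun <- if (classifier == "svm") .predSvm else .predGbm
  spaceFun <- if (classifier == "svm") .svmSpace else .gbmSpace

  oneRun <- function(seed) {
    withSeed(seed, {
      space <- spaceFun(nIter)
      cw <- length(devIdx) / (nlevels(y) * table(y[devIdx]))
      cw <- stats::setNames(as.numeric(cw), names(cw))
      folds <- sample(rep_len(1:3, length(devIdx)))
      cvScore <- vapply(seq_len(nIter), function(i) {
        hp <- space[i, ]
        accs <- vapply(1:3, function(f) {
          tr <- devIdx[folds != f]; te <- devIdx[folds == f]
          if (any(table(y[tr]) == 0L)) return(NA_real_)
          fit <- fitFun(features[tr, , drop = FALSE], droplevels(y[tr]), hp,
                        cw[levels(droplevels(y[tr]))])
          pr <- predFun(fit, features[te, , drop = FALSE], levels(droplevels(y[tr])))
          macroF1(y[te], pr$labels)
        }, numeric(1))
        mean(accs, na.rm = TRUE)
      }, numeric(1))
      best <- space[which.max(cvScore), ]
      fit <- fitFun(features[devIdx, , drop = FALSE], y[devIdx], best, cw)
      pr <- predFun(fit, features[split$test, , drop = FALSE], levels(y))
      yt <- y[split$test]
      out <- c(macro_f1 = macroF1(yt, pr$labels),
               accuracy = accuracyScore(yt, pr$labels))
      if (taskType == "binary") {
        pos <- levels(y)[2L]
        out <- c(out, auprc = auprc(yt == pos, pr$probs[, pos]))
      }
      out
    })
  }
  runs <- vapply(seq_len(nSeeds), function(k) oneRun(deriveSeed(baseSeed, k)),
                 numeric(if (taskType == "binary") 3L else 2L))
  res <- data.frame(metric = rownames(runs),
                    mean = rowMeans(runs),
                    sd = apply(runs, 1L, stats::sd),
                    classifier = classifier, row.names = NULL)
  attr(res, "runs") <- runs
  res
}

#' PCA + k-means utility for embedding cluster analysis
#'
#' Reduces embeddings to \code{nComp} principal components and clusters with
#' k-means under a fixed seed (inputs for motif-level cluster
#' interpretation).
#'
#' @param features embedding matrix.
#' @param nComp number of principal components (default 50, capped at the
#'   feature rank).
#' @param k number of clusters (default 6).
#' @param seed seed for k-means restarts.
#' @return list(scores, cluster, centers, varianceExplained).
#' @export
pcaKmeans <- function(features, nComp = 50L, k = 6L, seed = 1L) {
  nComp <- min(nComp, ncol(features), nrow(features) - 1L)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = nComp)
  km <- withSeed(deriveSeed(seed, 606L),
                 stats::kmeans(pc$x, centers = k, nstart = 10L))
  list(scores = pc$x, cluster = km$cluster, centers = km$centers,
       varianceExplained = sum(pc$sdev[seq_len(nComp)]^2) / sum(pc$sdev^2))
}

#' Write an embedding matrix / kernel matrix / metrics table as TSV
#'
#' @param x object to write (matrix or data.frame).
#' @param path output path.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}
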