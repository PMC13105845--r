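# Masked-language-model pretraining: loss, AdamW, early stopping, ablations.

#' Training configuration
#'
#' Defaults follow the reference pretraining recipe: AdamW with learning
#' rate 1e-6 and weight decay 0.01, cross-entropy with edge loss weight 0.5,
#' a 90/10 train/validation split with early stopping on mean validation
#' loss (patience 15 epochs for ss/small scales, 30 for medium/large), batch
#' size 32 and gradient clipping at 1.0. The learning rate suits large-corpus
#' pretraining; small toy corpora converge faster with a larger rate (the
#' package vignette uses 2e-3 for the d = 64 model).
#'
#' @param lr AdamW learning rate.
#' @param weightDecay decoupled weight decay (matrices only).
#' @param edgeLossWeight weight of the edge cross-entropy term.
#' @param patience early-stopping patience in epochs; NULL picks 15 or 30 by
#'   model scale.
#' @param valFraction held-out validation fraction in (0, 1).
#' @param maxEpochs,batchSize,clip,seed as usual.
#' @param warmup linear learning-rate warmup over this many optimizer
#'   updates (0 disables).
#' @param refitFull after early stopping, retrain on the full corpus for the
#'   selected epoch count (the returned model is then the refit one and the
#'   log keeps the split run).
#' @return a list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(lr = 1e-6, weightDecay = 0.01, edgeLossWeight = 0.5,
                        patience = NULL, valFraction = 0.10, maxEpochs = 100L,
                        batchSize = 32L, clip = 1.0, seed = 1L,
                        warmup = 100L, refitFull = TRUE) {
  stopifnot(valFraction > 0, valFraction < 1, edgeLossWeight >= 0, lr >= 0)
  structure(list(lr = lr, weightDecay = weightDecay,
                 edgeLossWeight = edgeLossWeight, patience = patience,
                 valFraction = valFraction, maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize), clip = clip,
                 seed = as.integer(seed), warmup = as.integer(warmup),
                 refitFull = refitFull),
            class = "TrainConfig")
}

#' Masked-language-model loss
#'
#' \code{loss = meanCE(masked node positions) + lambda * meanCE(masked,
#' scored edge positions)}; a term with no positions contributes 0, and a
#' plan masking nothing at all yields 0 with a warning.
#'
#' @param nodeLogits,edgeLogits logit matrices from \code{\link{mlmHeads}}
#'   (rows carry a \code{"positions"} attribute).
#' @param plan a \linkS4class{MaskingPlan}.
#' @param edgeLossWeight lambda, default 0.5.
#' @return scalar loss with attributes \code{nodeCE} and \code{edgeCE}
#'   (the two mean cross-entropies).
#' @export
mlmLoss <- function(nodeLogits, edgeLogits, plan, edgeLossWeight = 0.5) {
  ceAt <- function(logits, positions, truth) {
    rows <- match(positions, attr(logits, "positions"))
    if (any(is.na(rows)))
      glycanStop("glycanMaskError", "logits missing for a masked position")
    L <- logits[rows, , drop = FALSE]
    m <- apply(L, 1L, max)
    lse <- m + log(rowSums(exp(L - m)))
    mean(lse - L[cbind(seq_along(rows), truth - 3L)])
  }
  scored <- plan@edgeScored
  nCE <- if (length(plan@nodePositions))
    ceAt(nodeLogits, plan@nodePositions, plan@nodeTruth) else 0
  eCE <- if (any(scored))
    ceAt(edgeLogits, plan@edgePositions[scored], plan@edgeTruth[scored]) else 0
  if (length(plan@nodePositions) == 0L && !any(scored))
    warning("masking plan has no scored positions; loss is 0")
  structure(nCE + edgeLossWeight * eCE, nodeCE = nCE, edgeCE = eCE)
}

# ---- internal batched loss + gradient -------------------------------------

# Softmax cross-entropy over one head for a set of global rows.
# Returns sum of CE, count, top-1 hits, dLogits (unscaled by count).
.headCE <- function(X, W, b, rows, truthCol) {
  k <- length(rows)
  if (k == 0L)
    return(list(sum = 0, n = 0L, hits = 0L, probs = NULL, dLogits = NULL, rows = rows))
  L <- addB(X[rows, , drop = FALSE] %*% W, b)
  m <- rowMax(L)
  E <- exp(L - m)
  P <- E / rowSums(E)
  ce <- (m + log(rowSums(E))) - L[cbind(seq_len(k), truthCol)]
  hits <- sum(max.col(L, ties.method = "first") == truthCol)
  dL <- P
  dL[cbind(seq_len(k), truthCol)] <- dL[cbind(seq_len(k), truthCol)] - 1
  list(sum = sum(ce), n = k, hits = hits, probs = P, dLogits = dL, rows = rows)
}

# Loss (and, optionally, full parameter gradients) for one batch of glycans
# under their masking plans.
.batchLossGrad <- function(params, cfg, bank, tgs, plans, lambda,
                           wantGrad = TRUE, dropout = 0, dropSeed = 0L) {
  ids <- maskedContentIds(tgs, plans)
  ab <- .assembleBatch(tgs, ids, cfg$maxNodes)
  fwd <- .fwdBatch(params, cfg, bank, ab, dropoutP = dropout,
                   dropSeed = dropSeed, keepCache = wantGrad)
  X <- fwd$X
  nodeRows <- integer(0); nodeCol <- integer(0)
  edgeRows <- integer(0); edgeCol <- integer(0)
  for (s in seq_along(tgs)) {
    pl <- .planAsList(plans[[s]])
    off <- ab$offs[s]
    nodeRows <- c(nodeRows, off + pl$nodePos)
    nodeCol <- c(nodeCol, pl$nodeTruth - 3L)
    sc <- pl$scored
    edgeRows <- c(edgeRows, off + pl$edgePos[sc])
    edgeCol <- c(edgeCol, pl$edgeTruth[sc] - 3L)
  }
  hn <- .headCE(X, params$Whn, params$bhn, nodeRows, nodeCol)
  he <- .headCE(X, params$Whe, params$bhe, edgeRows, edgeCol)
  nodeMean <- if (hn$n) hn$sum / hn$n else 0
  edgeMean <- if (he$n) he$sum / he$n else 0
  loss <- nodeMean + lambda * edgeMean
  out <- list(loss = loss,
              nodeSum = hn$sum, nodeN = hn$n, nodeHits = hn$hits,
              edgeSum = he$sum, edgeN = he$n, edgeHits = he$hits)
  if (!wantGrad) return(out)
  dX <- matrix(0, ab$N, cfg$d)
  grads <- list()
  if (hn$n) {
    dLn <- hn$dLogits / hn$n
    dX[hn$rows, ] <- dX[hn$rows, ] + tcrossprod(dLn, params$Whn)
    grads$Whn <- crossprod(X[hn$rows, , drop = FALSE], dLn)
    grads$bhn <- colSums(dLn)
  } else {
    grads$Whn <- matrix(0, cfg$d, ncol(params$Whn)); grads$bhn <- numeric(ncol(params$Whn))
  }
  if (he$n) {
    dLe <- lambda * he$dLogits / he$n
    dX[he$rows, ] <- dX[he$rows, ] + tcrossprod(dLe, params$Whe)
    grads$Whe <- crossprod(X[he$rows, , drop = FALSE], dLe)
    grads$bhe <- colSums(dLe)
  } else {
    grads$Whe <- matrix(0, cfg$d, ncol(params$Whe)); grads$bhe <- numeric(ncol(params$Whe))
  }
  enc <- .bwdBatch(params, cfg, ab, fwd, dX)
  out$grads <- c(enc, grads)
  out
}

# ---- parameter-tree utilities and AdamW -----------------------------------

.treeMap <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1L]])) {
    nm <- names(xs[[1L]])
    out <- vector("list", length(xs[[1L]]))
    names(out) <- nm
    for (i in seq_along(out)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
      out[[i]] <- do.call(.treeMap, c(list(f), lapply(xs, `[[`, key)))
    }
    out
  } else do.call(f, xs)
}

.treeSum <- function(a, f) {
  if (is.list(a)) sum(vapply(a, .treeSum, numeric(1), f)) else f(a)
}

.adamwInit <- function(params) {
  zero <- function(p) p * 0
  list(m = .treeMap(zero, params), v = .treeMap(zero, params), t = 0L)
}

.adamwStep <- function(params, grads, state, lr, wd, clip,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(.treeSum(grads, function(g) sum(g * g)))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  # single fused walk over (params, grads, m, v)
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      nm <- names(p)
      out <- vector("list", length(p)); names(out) <- nm
      for (i in seq_along(p)) {
        key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
        out[[i]] <- step(p[[key]], g[[key]], m[[key]], v[[key]])
      }
      return(out)
    }
    g <- g * scale
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    upd <- (m / c1) / (sqrt(v / c2) + eps)
    if (!is.null(dim(p))) upd <- upd + wd * p      # decoupled decay, matrices only
    list(p = p - lr * upd, m = m, v = v)
  }
  merged <- step(params, grads, state$m, state$v)
  split <- function(x, k) {
    if (is.list(x) && !is.null(names(x)) && identical(sort(names(x)), sort(c("p", "m", "v"))))
      return(x[[k]])
    lapply(x, split, k = k)
  }
  state$m <- split(merged, "m")
  state$v <- split(merged, "v")
  list(params = split(merged, "p"), state = state)
}

# ---- pretraining loop ------------------------------------------------------

#' Pretrain a glycan language model with masked language modeling
#'
#' Splits the corpus 90/10 (configurable) into train/validation, resamples a
#' fresh masking plan per glycan each epoch, optimizes with AdamW under
#' gradient clipping, and stops early when mean validation loss has not
#' improved for \code{patience} epochs; the returned model carries the
#' parameters of the best validation epoch. With
#' \code{train$refitFull = TRUE} the model is afterwards re-initialized and
#' retrained on the full corpus for the selected epoch count.
#'
#' Masking modes: \code{"balanced"} masks nodes and edges at the same ratio
#' (default 0.35/0.35); the ablation modes \code{"node_only"} and
#' \code{"edge_only"} use 0.70/0 and 0/0.70 so the total masked fraction
#' stays comparable.
#'
#' @param corpus character vector of IUPAC-condensed strings (or a
#'   data.frame with a \code{glycan} column).
#' @param config a \code{ModelConfig}.
#' @param train a \code{TrainConfig}.
#' @param mode \code{"balanced"}, \code{"node_only"} or \code{"edge_only"}.
#' @param maskRatio ratio used by the balanced mode (each token type).
#' @param vocab optional prebuilt \linkS4class{Vocabulary}; built from the
#'   corpus when NULL.
#' @param minCount vocabulary frequency cutoff when building.
#' @param verbose print per-epoch losses.
#' @return a trained \linkS4class{GlycanLM}; \code{model@log} holds the
#'   per-epoch train/validation losses and masked-token accuracies, and
#'   \code{model@meta$selectedEpoch} the early-stopping choice.
#' @export
pretrain <- function(corpus, config = modelConfig(), train = trainConfig(),
                     mode = c("balanced", "node_only", "edge_only"),
                     maskRatio = 0.35, vocab = NULL, minCount = 1L,
                     verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.data.frame(corpus)) corpus <- corpus$glycan
  if (length(corpus) == 0L)
    glycanStop("glycanTrainError", "empty corpus")
  ratios <- switch(mode,
                   balanced = c(maskRatio, maskRatio),
                   node_only = c(0.70, 0),
                   edge_only = c(0, 0.70))
  graphs <- lapply(corpus, parseIUPAC)
  if (is.null(vocab)) vocab <- buildVocab(graphs, minCount)
  tgs <- lapply(graphs, encodeGlycan, vocab = vocab)
  model <- initGlycanLM(vocab, config)
  patience <- train$patience %||% if (config$scale %in% c("ss", "small")) 15L else 30L

  nVal <- max(1L, round(train$valFraction * length(tgs)))
  valIdx <- withSeed(deriveSeed(train$seed, 404L),
                     sort(sample(length(tgs), nVal)))
  trIdx <- setdiff(seq_along(tgs), valIdx)
  if (length(trIdx) == 0L)
    glycanStop("glycanTrainError", "no training glycans left after the split")
  valPlans <- lapply(seq_along(valIdx), function(i)
    .trainPlanL(tgs[[valIdx[i]]], ratios[1L], ratios[2L],
                deriveSeed(train$seed, 7777L, i)))

  runEpochs <- function(model, idx, nEpochs, trackVal) {
    params <- model@params
    state <- .adamwInit(params)
    nUpdates <- 0L
    logRows <- list()
    bestLoss <- Inf; bestParams <- params; bestEpoch <- 0L; wait <- 0L
    for (epoch in seq_len(nEpochs)) {
      ord <- withSeed(deriveSeed(train$seed, epoch, 1L), sample(idx))
      plans <- lapply(seq_along(ord), function(i)
        .trainPlanL(tgs[[ord[i]]], ratios[1L], ratios[2L],
                    deriveSeed(train$seed, epoch, 100L + ord[i])))
      agg <- c(nodeSum = 0, nodeN = 0, edgeSum = 0, edgeN = 0)
      for (b in seq_len(ceiling(length(ord) / train$batchSize))) {
        sel <- ((b - 1L) * train$batchSize + 1L):min(b * train$batchSize, length(ord))
        res <- .batchLossGrad(params, config, model@bank,
                              tgs[ord[sel]], plans[sel], train$edgeLossWeight,
                              wantGrad = TRUE, dropout = config$dropout,
                              dropSeed = deriveSeed(train$seed, epoch, 5000L + b))
        if (res$nodeN + res$edgeN == 0L) next
        nUpdates <- nUpdates + 1L
        lrNow <- if (train$warmup > 0L) train$lr * min(1, nUpdates / train$warmup)
                 else train$lr
        st <- .adamwStep(params, res$grads, state, lrNow,
                         train$weightDecay, train$clip)
        params <- st$params; state <- st$state
        agg <- agg + c(res$nodeSum, res$nodeN, res$edgeSum, res$edgeN)
      }
      trainLoss <- (if (agg[2L] > 0) agg[1L] / agg[2L] else 0) +
        train$edgeLossWeight * (if (agg[4L] > 0) agg[3L] / agg[4L] else 0)
      row <- data.frame(epoch = epoch, trainLoss = unname(trainLoss),
                        valLoss = NA_real_, valNodeAcc = NA_real_,
                        valEdgeAcc = NA_real_)
      if (trackVal) {
        vm <- .evalSplit(params, config, model@bank, tgs[valIdx], valPlans,
                         train$edgeLossWeight, train$batchSize)
        row$valLoss <- vm$loss; row$valNodeAcc <- vm$nodeAcc; row$valEdgeAcc <- vm$edgeAcc
        if (vm$loss < bestLoss - 1e-12) {
          bestLoss <- vm$loss; bestParams <- params; bestEpoch <- epoch; wait <- 0L
        } else wait <- wait + 1L
      }
      logRows[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", epoch, trainLoss,
                        if (trackVal) sprintf("%.4f", row$valLoss) else "-"))
      if (trackVal && wait >= patience) break
    }
    list(params = if (trackVal) bestParams else params,
         log = do.call(rbind, logRows),
         bestEpoch = if (trackVal) bestEpoch else nEpochs)
  }

  fit <- runEpochs(model, trIdx, train$maxEpochs, trackVal = TRUE)
  model@params <- fit$params
  model@log <- fit$log
  model@meta$selectedEpoch <- fit$bestEpoch
  model@meta$mode <- mode
  model@meta$ratios <- ratios
  model@meta$refit <- FALSE
  if (train$refitFull && fit$bestEpoch > 0L) {
    fresh <- initGlycanLM(vocab, config)
    refit <- runEpochs(fresh, seq_along(tgs), fit$bestEpoch, trackVal = FALSE)
    model@params <- refit$params
    model@meta$refit <- TRUE
  }
  model
}

# Mean validation loss and masked-token top-1 accuracies under fixed plans.
.evalSplit <- function(params, cfg, bank, tgs, plans, lambda, batchSize) {
  agg <- c(nodeSum = 0, nodeN = 0, nodeHits = 0, edgeSum = 0, edgeN = 0, edgeHits = 0)
  for (b in seq_len(ceiling(length(tgs) / batchSize))) {
    sel <- ((b - 1L) * batchSize + 1L):min(b * batchSize, length(tgs))
    r <- .batchLossGrad(params, cfg, bank, tgs[sel], plans[sel], lambda,
                        wantGrad = FALSE)
    agg <- agg + c(r$nodeSum, r$nodeN, r$nodeHits, r$edgeSum, r$edgeN, r$edgeHits)
  }
  list(loss = (if (agg[2L] > 0) agg[1L] / agg[2L] else 0) +
         lambda * (if (agg[5L] > 0) agg[4L] / agg[5L] else 0),
       nodeAcc = if (agg[2L] > 0) agg[3L] / agg[2L] else NA_real_,
       edgeAcc = if (agg[5L] > 0) agg[6L] / agg[5L] else NA_real_)
}

#' Evaluate masked-token loss and accuracy on a corpus
#'
#' Applies fixed seeded masking plans at the given ratios and reports mean
#' loss and masked top-1 accuracies without touching the parameters (used
#' for validation-style measurements on held-out data).
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param corpus character vector of IUPAC strings.
#' @param nodeRatio,edgeRatio masking ratios.
#' @param seed seed for the plans.
#' @param edgeLossWeight lambda.
#' @return list(loss, nodeAcc, edgeAcc).
#' @export
evaluateMLM <- function(model, corpus, nodeRatio = 0.35, edgeRatio = 0.35,
                        seed = 1L, edgeLossWeight = 0.5) {
  if (is.data.frame(corpus)) corpus <- corpus$glycan
  tgs <- lapply(lapply(corpus, parseIUPAC), encodeGlycan, vocab = model@vocab)
  plans <- lapply(seq_along(tgs), function(i)
    .trainPlanL(tgs[[i]], nodeRatio, edgeRatio, deriveSeed(seed, 8888L, i)))
  .evalSplit(model@params, model@config, model@bank, tgs, plans,
             edgeLossWeight, 32L)
}

#' Token-type attention summary
#'
#' Runs the encoder on a sample of glycans, averages final-layer attention
#' across heads, and aggregates token-to-token mass into a 3x3 block matrix
#' over the types (node, edge, graph): entry (t, c) is the average total
#' attention a type-t token pays to type-c tokens, so every row sums to 1.
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param corpus character vector of IUPAC strings (the sample).
#' @return 3x3 matrix with dimnames node/edge/graph.
#' @export
attentionSummary <- function(model, corpus) {
  if (is.data.frame(corpus)) corpus <- corpus$glycan
  if (length(corpus) == 0L) glycanStop("glycanTrainError", "empty sample")
  tgs <- lapply(lapply(corpus, parseIUPAC), encodeGlycan, vocab = model@vocab)
  out <- encoderForward(model, tgs, returnAttention = TRUE)
  final <- out$attention[[model@config$depth]]
  typeNames <- c("node", "edge", "graph")
  mass <- matrix(0, 3L, 3L, dimnames = list(typeNames, typeNames))
  cnt <- numeric(3L)
  for (s in seq_along(tgs)) {
    A <- Reduce(`+`, final[[s]]) / length(final[[s]])   # head average
    ty <- ifelse(tgs[[s]]@type == 0L, 3L, tgs[[s]]@type)
    for (t in 1:3) {
      rows <- which(ty == t)
      if (!length(rows)) next
      for (cc in 1:3) {
        cols <- which(ty == cc)
        if (length(cols))
          mass[t, cc] <- mass[t, cc] + sum(A[rows, cols, drop = FALSE])
      }
      cnt[t] <- cnt[t] + length(rows)
    }
  }
  sweep(mass, 1L, pmax(cnt, 1), "/")
}
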