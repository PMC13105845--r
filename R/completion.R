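# Ambiguous-sequence completion: candidate ranking and hit@K.

#' Rank candidate tokens for the masked positions of a glycan
#'
#' Runs the encoder on the masked input and, for every masked position,
#' ranks the full content vocabulary of its token type by descending softmax
#' probability (special tokens are never candidates). Ties -- which arise
#' only in degenerate models such as an untrained one with zero-initialized
#' heads -- are broken by a seeded random permutation so that tied candidates
#' carry no systematic order.
#'
#' Only scored positions are ranked: under the all-linkages-masked scenario
#' terminal edges are hidden from the model but excluded from targets.
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param tg a \linkS4class{TokenizedGraph} encoded with the model's vocab.
#' @param plan a \linkS4class{MaskingPlan} for \code{tg}.
#' @param tieSeed seed for random tie-breaking.
#' @return list of \code{RankedPrediction} lists: \code{position},
#'   \code{type} ("node"/"edge"), \code{trueId}, \code{rankedIds} (a
#'   permutation of the content ids, best first), \code{probabilities}
#'   (matching, descending, summing to 1), \code{trueRank}.
#' @export
rankCandidates <- function(model, tg, plan, tieSeed = 1L) {
  if (length(tg@contentId) == 0L)
    glycanStop("glycanCompletionError", "empty tokenized glycan")
  out <- encoderForward(model, tg, maskPlans = plan)
  X <- out$tokenStates[[1L]]
  heads <- mlmHeads(model, X, tg@type)
  pl <- .planAsList(plan)
  preds <- list()
  rankOne <- function(logits, positions, pos, trueId, type, k) {
    row <- match(pos, positions)
    L <- logits[row, ]
    p <- exp(L - max(L)); p <- p / sum(p)
    jitter <- withSeed(deriveSeed(tieSeed, pos, k), stats::runif(length(p)))
    ord <- order(-p, jitter)
    ranked <- ord + 3L                       # content index -> content id
    list(position = pos, type = type, trueId = trueId,
         rankedIds = ranked, probabilities = p[ord],
         trueRank = which(ranked == trueId))
  }
  for (i in seq_along(pl$nodePos))
    preds[[length(preds) + 1L]] <- rankOne(
      heads$nodeLogits, attr(heads$nodeLogits, "positions"),
      pl$nodePos[i], pl$nodeTruth[i], "node", 1L)
  for (i in which(pl$scored))
    preds[[length(preds) + 1L]] <- rankOne(
      heads$edgeLogits, attr(heads$edgeLogits, "positions"),
      pl$edgePos[i], pl$edgeTruth[i], "edge", 2L)
  preds
}

#' hit@K over ranked predictions
#'
#' Micro-averaged over all masked positions (across glycans): the fraction
#' of positions whose true token appears within the top K candidates,
#' reported separately for node and edge targets. Non-decreasing in K by
#' construction.
#'
#' @param predictions list of \code{RankedPrediction}s (possibly concatenated
#'   across glycans), as returned by \code{\link{rankCandidates}}.
#' @param ks positive integer cutoffs, e.g. \code{c(1, 2, 3, 5, 10, 20, 30)}.
#' @param macro if TRUE, average per-glycan hit rates instead (requires a
#'   \code{glycanId} field added by the caller); default micro.
#' @return data.frame with columns \code{targetType}, \code{K},
#'   \code{hitRate}, \code{nTargets}.
#' @export
hitAtK <- function(predictions, ks = c(1L, 2L, 3L, 5L, 10L, 20L, 30L),
                   macro = FALSE) {
  if (length(predictions) == 0L)
    glycanStop("glycanCompletionError", "no predictions to score")
  stopifnot(all(ks >= 1L))
  ranks <- vapply(predictions, function(p) as.numeric(p$trueRank), numeric(1))
  types <- vapply(predictions, `[[`, character(1), "type")
  gids <- vapply(predictions, function(p) as.character(p$glycanId %||% "1"), character(1))
  rows <- list()
  for (tt in c("node", "edge")) {
    sel <- types == tt
    if (!any(sel)) next
    for (K in sort(unique(as.integer(ks)))) {
      hr <- if (macro) {
        mean(tapply(ranks[sel] <= K, gids[sel], mean))
      } else mean(ranks[sel] <= K)
      rows[[length(rows) + 1L]] <- data.frame(
        targetType = tt, K = K, hitRate = hr, nTargets = sum(sel))
    }
  }
  do.call(rbind, rows)
}

#' Run a full completion experiment over a corpus
#'
#' Applies one ambiguity scenario at one monosaccharide masking ratio to
#' every glycan, ranks candidates with the model, and scores hit@K.
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param corpus character vector of IUPAC strings.
#' @param kind scenario, see \code{\link{applyScenario}}.
#' @param monoRatio monosaccharide masking ratio.
#' @param ks hit@K cutoffs.
#' @param seed seed (plans and tie-breaking).
#' @return data.frame: scenario, monoRatio, targetType, K, hitRate, nTargets.
#' @export
completionExperiment <- function(model, corpus,
                                 kind = c("linkages_intact", "linkages_all_masked"),
                                 monoRatio = 0.5,
                                 ks = c(1L, 2L, 3L, 5L, 10L, 20L, 30L),
                                 seed = 1L) {
  kind <- match.arg(kind)
  if (is.data.frame(corpus)) corpus <- corpus$glycan
  tgs <- lapply(lapply(corpus, parseIUPAC), encodeGlycan, vocab = model@vocab)
  preds <- list()
  for (i in seq_along(tgs)) {
    pl <- suppressWarnings(
      applyScenario(tgs[[i]], kind, monoRatio, deriveSeed(seed, 9090L, i)))
    if (length(pl@nodePositions) == 0L && !any(pl@edgeScored)) next
    pr <- rankCandidates(model, tgs[[i]], pl, tieSeed = deriveSeed(seed, 9191L, i))
    for (j in seq_along(pr)) pr[[j]]$glycanId <- i
    preds <- c(preds, pr)
  }
  if (length(preds) == 0L)
    glycanStop("glycanCompletionError", "scenario produced no scored targets")
  res <- hitAtK(preds, ks)
  cbind(data.frame(scenario = kind, monoRatio = monoRatio), res)
}
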