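# Masking plans for MLM training and for the ambiguity scenarios.

.drawPlan <- function(tg, nodeCount, edgePool, edgeCount, seed, scenario,
                      allEdges = FALSE) {
  n <- tg@nNodes; m <- tg@nEdges
  nodePool <- if (n > 0L) 1L + seq_len(n) else integer(0)
  draw <- function(pool, k) sort(pool[sample.int(length(pool), k)])
  withSeed(deriveSeed(seed, 303L), {
    nodePos <- if (nodeCount > 0L) draw(nodePool, nodeCount) else integer(0)
    edgePos <- if (allEdges) edgePool
               else if (edgeCount > 0L) draw(edgePool, edgeCount) else integer(0)
    list(nodePos = nodePos, edgePos = edgePos)
  })
}

# Internal lightweight plan (plain list) used by the training loop, where
# constructing a validated S4 object per glycan per epoch would dominate.
.trainPlanL <- function(tg, nodeRatio, edgeRatio, seed) {
  eligible <- 1L + tg@nNodes + which(!tg@terminalEdge)
  dr <- .drawPlan(tg, round(nodeRatio * tg@nNodes), eligible,
                  round(edgeRatio * length(eligible)), seed, "train")
  list(nodePos = as.integer(dr$nodePos), nodeTruth = tg@contentId[dr$nodePos],
       edgePos = as.integer(dr$edgePos), edgeTruth = tg@contentId[dr$edgePos],
       scored = rep(TRUE, length(dr$edgePos)))
}

# Uniform internal view of a plan (S4 or internal list).
.planAsList <- function(plan) {
  if (is.list(plan)) return(plan)
  list(nodePos = plan@nodePositions, nodeTruth = plan@nodeTruth,
       edgePos = plan@edgePositions, edgeTruth = plan@edgeTruth,
       scored = plan@edgeScored)
}

#' Draw a masking plan for MLM training
#'
#' Masks \code{round(nodeRatio * nNodes)} node tokens chosen uniformly
#' without replacement among all node tokens, and
#' \code{round(edgeRatio * nEligible)} edge tokens among the non-terminal
#' edges (terminal linkages lack two-sided context and are excluded from
#' prediction targets). The [Graph] token is never masked. Deterministic
#' under \code{seed}. At input time masked positions read \code{[MASK]}
#' while identifiers and type stay visible.
#'
#' @param tg a \linkS4class{TokenizedGraph}.
#' @param nodeRatio,edgeRatio masking fractions in [0, 1].
#' @param seed integer seed.
#' @return a \linkS4class{MaskingPlan}.
#' @export
makeMaskingPlan <- function(tg, nodeRatio, edgeRatio, seed = 1L) {
  if (nodeRatio < 0 || nodeRatio > 1 || edgeRatio < 0 || edgeRatio > 1)
    glycanStop("glycanMaskError", "masking ratios must lie in [0, 1]")
  pl <- .trainPlanL(tg, nodeRatio, edgeRatio, seed)
  new("MaskingPlan",
      nodePositions = pl$nodePos, nodeTruth = pl$nodeTruth,
      edgePositions = pl$edgePos, edgeTruth = pl$edgeTruth,
      edgeScored = pl$scored,
      nodeRatio = nodeRatio, edgeRatio = edgeRatio,
      seed = as.integer(seed), scenario = "train")
}

#' Mask a glycan according to an empirical ambiguity scenario
#'
#' Two scenarios mirror the ambiguity patterns of public repositories:
#' \code{"linkages_intact"} leaves every linkage visible and masks 10--90\%
#' of the monosaccharides; \code{"linkages_all_masked"} hides every linkage
#' (terminal ones included, since real ambiguous entries hide them too) and
#' masks 0--90\% of the monosaccharides. Terminal linkages are masked as
#' inputs but never scored as prediction targets (\code{edgeScored} is FALSE
#' for them), keeping the training-time exclusion consistent at evaluation.
#'
#' @param tg a \linkS4class{TokenizedGraph}.
#' @param kind \code{"linkages_intact"} or \code{"linkages_all_masked"}.
#' @param monoRatio monosaccharide masking fraction; the stated grids are
#'   0.1--0.9 (intact) and 0.0--0.9 (all masked) in steps of 0.1 -- an
#'   off-grid ratio draws a warning but proceeds.
#' @param seed integer seed.
#' @return a \linkS4class{MaskingPlan}.
#' @export
applyScenario <- function(tg, kind = c("linkages_intact", "linkages_all_masked"),
                          monoRatio, seed = 1L) {
  kind <- match.arg(kind)
  grid <- if (kind == "linkages_intact") seq(0.1, 0.9, by = 0.1) else seq(0, 0.9, by = 0.1)
  if (min(abs(monoRatio - grid)) > 1e-9)
    warning(sprintf("monoRatio %.3f is off the stated %s grid; proceeding", monoRatio, kind))
  nodeCount <- round(monoRatio * tg@nNodes)
  if (kind == "linkages_intact") {
    dr <- .drawPlan(tg, nodeCount, integer(0), 0L, seed, kind)
    scored <- logical(0)
  } else {
    edgePool <- 1L + tg@nNodes + seq_len(tg@nEdges)
    dr <- .drawPlan(tg, nodeCount, edgePool, 0L, seed, kind, allEdges = TRUE)
    scored <- !tg@terminalEdge
  }
  new("MaskingPlan",
      nodePositions = as.integer(dr$nodePos),
      nodeTruth = tg@contentId[dr$nodePos],
      edgePositions = as.integer(dr$edgePos),
      edgeTruth = tg@contentId[dr$edgePos],
      edgeScored = scored,
      nodeRatio = monoRatio,
      edgeRatio = if (kind == "linkages_intact") 0 else 1,
      seed = as.integer(seed), scenario = kind)
}
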