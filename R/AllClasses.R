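#' @import methods
NULL

#' GlycanGraph: a glycan as a rooted labeled tree
#'
#' A glycan parsed from IUPAC-condensed notation. Nodes are monosaccharide
#' residues (labels kept verbatim, including modifications such as
#' \code{"GalNAc3,4,6Ac3"}), edges are glycosidic linkages directed from the
#' child residue towards its parent, and the root is the reducing-end residue
#' (the rightmost residue of the notation). Node indices are 0-based and
#' follow the left-to-right textual order of residues.
#'
#' @slot nodeLabels character vector; \code{nodeLabels[i + 1]} is the label of
#'   node index \code{i}.
#' @slot childIndex,parentIndex integer vectors (0-based node indices), one
#'   entry per edge, child pointing to parent.
#' @slot edgeLabels character vector of linkage labels, parallel to the edge
#'   index vectors.
#' @slot rootIndex 0-based index of the reducing-end residue.
#'
#' @examples
#' g <- parseIUPAC("Gal(b1-3)GalNAc")
#' nNodes(g)
#' edgeTable(g)
#' @export
setClass("GlycanGraph", representation(
  nodeLabels  = "character",
  childIndex  = "integer",
  parentIndex = "integer",
  edgeLabels  = "character",
  rootIndex   = "integer"
))

setValidity("GlycanGraph", function(object) {
  n <- length(object@nodeLabels)
  m <- length(object@edgeLabels)
  msgs <- character(0)
  if (n == 0L) msgs <- c(msgs, "glycan must contain at least one residue")
  if (length(object@childIndex) != m || length(object@parentIndex) != m)
    msgs <- c(msgs, "edge index vectors and edge labels must have equal length")
  if (m != n - 1L) msgs <- c(msgs, "a rooted tree must satisfy edges = nodes - 1")
  if (length(object@rootIndex) != 1L || is.na(object@rootIndex) ||
      object@rootIndex < 0L || object@rootIndex >= n)
    msgs <- c(msgs, "rootIndex out of range")
  if (any(object@nodeLabels == "") || any(object@edgeLabels == ""))
    msgs <- c(msgs, "empty node or edge label")
  if (any(grepl("[?/]", object@nodeLabels)) || any(grepl("[?/]", object@edgeLabels)))
    msgs <- c(msgs, "ambiguous symbol ('?' or '/') in a validated graph")
  if (m > 0L) {
    if (any(object@childIndex < 0L) || any(object@childIndex >= n) ||
        any(object@parentIndex < 0L) || any(object@parentIndex >= n))
      msgs <- c(msgs, "edge endpoint out of range")
    if (anyDuplicated(object@childIndex))
      msgs <- c(msgs, "a node has more than one parent")
    if (length(msgs) == 0L) {
      if (object@rootIndex %in% object@childIndex)
        msgs <- c(msgs, "root must not have a parent")
      # reachability from root via parent pointers
      par <- rep(NA_integer_, n)
      par[object@childIndex + 1L] <- object@parentIndex
      reached <- logical(n)
      for (i in seq_len(n)) {
        j <- i - 1L
        steps <- 0L
        while (!is.na(j) && !reached[j + 1L] && steps <= n) {
          if (j == object@rootIndex) break
          j <- par[j + 1L]
          steps <- steps + 1L
        }
        if (is.na(j) || steps > n) msgs <- c(msgs, "node not connected to root")
        if (length(msgs)) break
        reached[i] <- TRUE
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Vocabulary: paired token dictionaries
#'
#' Disjoint id spaces for monosaccharide (node) tokens and linkage (edge)
#' tokens. In each space the special tokens \code{[PAD]}, \code{[MASK]},
#' \code{[UNK]}, \code{[GRAPH]} occupy ids 0--3 and content tokens follow
#' from id 4, contiguously, ordered by decreasing corpus frequency (ties
#' alphabetical) so that rebuilding from the same corpus is bit-identical.
#'
#' @slot nodeTokens,edgeTokens character vectors of content tokens in id
#'   order; the id of \code{nodeTokens[k]} is \code{k + 3}.
#' @export
setClass("Vocabulary", representation(
  nodeTokens = "character",
  edgeTokens = "character"
))

setValidity("Vocabulary", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@nodeTokens)) msgs <- c(msgs, "duplicate node token")
  if (anyDuplicated(object@edgeTokens)) msgs <- c(msgs, "duplicate edge token")
  if (any(object@nodeTokens == "") || any(object@edgeTokens == ""))
    msgs <- c(msgs, "empty token string")
  if (length(msgs)) msgs else TRUE
})

#' TokenizedGraph: a glycan as a flat token sequence
#'
#' The unit consumed by the encoder: position 1 is the [Graph] summary token,
#' then the node tokens in node-index order, then the edge tokens in
#' child-index order. A node token at node index v carries endpoints (v, v);
#' an edge token for bond child u -> parent v carries (u, v); the [Graph]
#' token carries the sentinel (-1, -1), which maps to a zero identifier.
#'
#' @slot contentId integer, 0-based ids into the node or edge vocab space
#'   according to \code{type}.
#' @slot type integer: 0 = [Graph], 1 = node, 2 = edge.
#' @slot u,v integer endpoints (0-based node indices; -1 for [Graph]).
#' @slot nNodes,nEdges integer counts.
#' @slot terminalEdge logical per edge token: TRUE when the edge touches a
#'   degree-1 non-root residue (such linkages are excluded from masking
#'   targets because they lack two-sided context).
#' @export
setClass("TokenizedGraph", representation(
  contentId    = "integer",
  type         = "integer",
  u            = "integer",
  v            = "integer",
  nNodes       = "integer",
  nEdges       = "integer",
  terminalEdge = "logical"
))

setValidity("TokenizedGraph", function(object) {
  msgs <- character(0)
  len <- 1L + object@nNodes + object@nEdges
  if (length(object@contentId) != len || length(object@type) != len ||
      length(object@u) != len || length(object@v) != len)
    msgs <- c(msgs, "token vectors must have length 1 + nNodes + nEdges")
  if (length(object@type) && object@type[1L] != 0L)
    msgs <- c(msgs, "position 1 must be the [Graph] token")
  if (sum(object@type == 1L) != object@nNodes || sum(object@type == 2L) != object@nEdges)
    msgs <- c(msgs, "type counts disagree with nNodes/nEdges")
  if (length(object@terminalEdge) != object@nEdges)
    msgs <- c(msgs, "terminalEdge must have one flag per edge token")
  nodesel <- object@type == 1L
  if (any(object@u[nodesel] != object@v[nodesel]))
    msgs <- c(msgs, "node tokens must have endpoints (v, v)")
  if (length(msgs)) msgs else TRUE
})

#' MaskingPlan: which token positions are masked
#'
#' Positions are 1-based indices into the token sequence of the
#' \linkS4class{TokenizedGraph} the plan was drawn for. \code{edgeScored}
#' distinguishes edges masked as inputs from edges that also count as
#' prediction targets: under the all-linkages-masked ambiguity scenario
#' terminal edges are hidden from the model but never scored.
#'
#' @slot nodePositions,edgePositions integer token positions.
#' @slot nodeTruth,edgeTruth integer true content ids at those positions.
#' @slot edgeScored logical, parallel to \code{edgePositions}.
#' @slot nodeRatio,edgeRatio numeric masking fractions used.
#' @slot seed integer seed the draw was made with.
#' @slot scenario character: "train", "linkages_intact" or "linkages_all_masked".
#' @export
setClass("MaskingPlan", representation(
  nodePositions = "integer",
  nodeTruth     = "integer",
  edgePositions = "integer",
  edgeTruth     = "integer",
  edgeScored    = "logical",
  nodeRatio     = "numeric",
  edgeRatio     = "numeric",
  seed          = "integer",
  scenario      = "character"
))

setValidity("MaskingPlan", function(object) {
  msgs <- character(0)
  if (anyDuplicated(c(object@nodePositions, object@edgePositions)))
    msgs <- c(msgs, "a position is masked twice")
  if (any(c(object@nodePositions, object@edgePositions) == 1L))
    msgs <- c(msgs, "the [Graph] token must never be masked")
  if (length(object@nodeTruth) != length(object@nodePositions) ||
      length(object@edgeTruth) != length(object@edgePositions) ||
      length(object@edgeScored) != length(object@edgePositions))
    msgs <- c(msgs, "truth/scored vectors must parallel position vectors")
  if (length(msgs)) msgs else TRUE
})

#' ToyGrammar: probabilistic grammar for synthetic branched glycans
#'
#' Emulates branched glycan trees in IUPAC-condensed notation. The linkage
#' joining a (parent, child) residue pair is a deterministic function of the
#' pair, so a model that can see both endpoints has a Bayes-optimal masked
#' linkage accuracy of 1; child residues are drawn from a per-parent
#' categorical distribution, so masked residues are predictable above chance
#' but not perfectly.
#'
#' @slot monoVocab residue symbols (default 10).
#' @slot linkages distinct linkage symbols (default 8).
#' @slot childSets named list: allowed child residues per parent.
#' @slot childProbs named list: categorical probabilities, parallel to
#'   \code{childSets}, each summing to 1.
#' @slot linkageRule named character: \code{"parent>child"} -> linkage symbol,
#'   total over all allowed pairs.
#' @slot branchProb probability that a non-leaf residue receives two children
#'   rather than one.
#' @slot stopProb probability that a residue below the root receives no
#'   children (before the depth cap applies).
#' @slot maxDepth depth cap (root = depth 1).
#' @export
setClass("ToyGrammar", representation(
  monoVocab   = "character",
  linkages    = "character",
  childSets   = "list",
  childProbs  = "list",
  linkageRule = "character",
  branchProb  = "numeric",
  stopProb    = "numeric",
  maxDepth    = "integer"
))

setValidity("ToyGrammar", function(object) {
  msgs <- character(0)
  if (object@maxDepth < 1L) msgs <- c(msgs, "maxDepth must be >= 1")
  if (object@branchProb < 0 || object@branchProb > 1 ||
      object@stopProb < 0 || object@stopProb >= 1)
    msgs <- c(msgs, "branchProb in [0,1] and stopProb in [0,1) required")
  for (p in names(object@childSets)) {
    kids <- object@childSets[[p]]
    pr <- object@childProbs[[p]]
    if (is.null(pr) || length(pr) != length(kids) || abs(sum(pr) - 1) > 1e-8)
      msgs <- c(msgs, sprintf("child distribution for '%s' must sum to 1", p))
    key <- paste0(p, ">", kids)
    if (!all(key %in% names(object@linkageRule)))
      msgs <- c(msgs, sprintf("linkage rule not total for parent '%s'", p))
  }
  if (length(msgs)) msgs else TRUE
})

# ---- accessors -------------------------------------------------------------

#' @describeIn GlycanGraph number of residues (nodes)
#' @param g a \linkS4class{GlycanGraph}
#' @export
nNodes <- function(g) length(g@nodeLabels)

#' @describeIn GlycanGraph number of glycosidic bonds (edges)
#' @export
nEdges <- function(g) length(g@edgeLabels)

#' @describeIn GlycanGraph residue labels in node-index order
#' @export
nodeLabels <- function(g) g@nodeLabels

#' @describeIn GlycanGraph linkage labels in edge order
#' @export
edgeLabels <- function(g) g@edgeLabels

#' @describeIn GlycanGraph 0-based index of the reducing-end residue
#' @export
rootIndex <- function(g) g@rootIndex

#' @describeIn GlycanGraph edges as a data.frame of
#'   (child, linkage, parent) triples with 0-based indices
#' @export
edgeTable <- function(g) {
  data.frame(child = g@childIndex, linkage = g@edgeLabels,
             parent = g@parentIndex, stringsAsFactors = FALSE)
}

#' Content tokens of a vocabulary
#'
#' @param vocab a \linkS4class{Vocabulary}
#' @param space \code{"node"} or \code{"edge"}
#' @return character vector of content tokens in id order (id = index + 3).
#' @export
contentTokens <- function(vocab, space = c("node", "edge")) {
  space <- match.arg(space)
  if (space == "node") vocab@nodeTokens else vocab@edgeTokens
}

#' Size of one vocabulary space including the four specials
#' @inheritParams contentTokens
#' @export
vocabSize <- function(vocab, space = c("node", "edge")) {
  length(contentTokens(vocab, space)) + 4L
}

# Reserved special-token ids, identical in both vocab spaces.
SPECIALS <- c(PAD = 0L, MASK = 1L, UNK = 2L, GRAPH = 3L)

#' Translate between token strings and content ids
#'
#' @inheritParams contentTokens
#' @param labels character labels to encode
#' @return \code{tokenId}: integer ids (unknown labels map to the UNK id, 2);
#'   \code{tokenLabel}: character labels (\code{"[UNK]"} etc. for specials).
#' @export
tokenId <- function(vocab, labels, space = c("node", "edge")) {
  toks <- contentTokens(vocab, match.arg(space))
  idx <- match(labels, toks)
  ifelse(is.na(idx), SPECIALS[["UNK"]], idx + 3L)
}

#' @rdname tokenId
#' @param ids integer token ids
#' @export
tokenLabel <- function(vocab, ids, space = c("node", "edge")) {
  toks <- contentTokens(vocab, match.arg(space))
  special <- c("[PAD]", "[MASK]", "[UNK]", "[GRAPH]")
  ifelse(ids < 4L, special[ids + 1L], toks[ids - 3L])
}

setMethod("show", "GlycanGraph", function(object) {
  cat(sprintf("GlycanGraph: %d residues, %d linkages, root = %s\n",
              nNodes(object), nEdges(object),
              object@nodeLabels[object@rootIndex + 1L]))
  cat(" ", serializeIUPAC(object), "\n")
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d monosaccharide + %d linkage content tokens (+4 specials each)\n",
              length(object@nodeTokens), length(object@edgeTokens)))
})

setMethod("show", "TokenizedGraph", function(object) {
  cat(sprintf("TokenizedGraph: [Graph] + %d node + %d edge tokens (%d terminal linkages)\n",
              object@nNodes, object@nEdges, sum(object@terminalEdge)))
})

setMethod("show", "MaskingPlan", function(object) {
  cat(sprintf("MaskingPlan (%s): %d node + %d edge positions masked (%d edge targets scored)\n",
              object@scenario, length(object@nodePositions),
              length(object@edgePositions), sum(object@edgeScored)))
})

setMethod("show", "ToyGrammar", function(object) {
  cat(sprintf("ToyGrammar: %d residues, %d linkages, branchProb=%.2f, maxDepth=%d\n",
              length(object@monoVocab), length(object@linkages),
              object@branchProb, object@maxDepth))
})
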