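# Synthetic branched glycans from a probabilistic grammar with
# context-determined tokens, so every pipeline stage is testable offline.

#' Construct a toy glycan grammar
#'
#' The default grammar uses 10 monosaccharide symbols and 8 linkage symbols.
#' Each parent residue admits 4 child residues (a contiguous window of the
#' residue alphabet) drawn from a fixed categorical distribution
#' (0.4/0.3/0.2/0.1), and the linkage joining a (parent, child) pair is a
#' deterministic function of the pair. Consequences: the Bayes-optimal
#' masked-linkage accuracy is 1 when both endpoints are visible, and masked
#' residues are predictable above chance (0.4 from the parent distribution
#' alone, more when the incident linkage is visible) -- the foundation of the
#' learnability experiments. Trees are depth-capped (default 6) with
#' branching probability 0.3, keeping residue counts in the 2--25 range of
#' typical glycans.
#'
#' @param monoVocab residue alphabet.
#' @param linkages linkage alphabet.
#' @param childWindow how many residues each parent admits as children.
#' @param childProbs categorical over the child window (must sum to 1).
#' @param branchProb probability of two children instead of one.
#' @param stopProb probability a non-root residue is a leaf before the depth
#'   cap.
#' @param maxDepth depth cap, root = 1.
#' @return a \linkS4class{ToyGrammar}.
#' @export
toyGrammar <- function(monoVocab = c("Gal", "Glc", "Man", "GalNAc", "GlcNAc",
                                     "ManNAc", "Fuc", "Xyl", "NeuNAc", "NeuGc"),
                       linkages = c("a1-2", "a1-3", "a1-4", "a1-6",
                                    "b1-2", "b1-3", "b1-4", "b1-6"),
                       childWindow = 4L, childProbs = c(0.4, 0.3, 0.2, 0.1),
                       branchProb = 0.3, stopProb = 0.25, maxDepth = 6L) {
  V <- length(monoVocab); L <- length(linkages)
  stopifnot(childWindow <= V, length(childProbs) == childWindow)
  childSets <- list(); childProbsL <- list(); rule <- character(0)
  for (i in seq_len(V)) {
    kidIdx <- ((i - 1L + seq_len(childWindow) - 1L) %% V) + 1L
    p <- monoVocab[i]
    childSets[[p]] <- monoVocab[kidIdx]
    childProbsL[[p]] <- childProbs / sum(childProbs)
    lk <- linkages[(((i - 1L) * V + (kidIdx - 1L)) %% L) + 1L]
    rule[paste0(p, ">", monoVocab[kidIdx])] <- lk
  }
  g <- new("ToyGrammar", monoVocab = monoVocab, linkages = linkages,
           childSets = childSets, childProbs = childProbsL, linkageRule = rule,
           branchProb = branchProb, stopProb = stopProb,
           maxDepth = as.integer(maxDepth))
  validObject(g)
  g
}

# Sample one rooted tree from the grammar; returns a GlycanGraph.
.sampleGlycan <- function(grammar, rootLabel) {
  labs <- rootLabel
  child <- integer(0); parent <- integer(0); elab <- character(0)
  grow <- function(idx, depth) {
    if (depth >= grammar@maxDepth) return(invisible())
    k <- if (depth == 1L) {
      1L + stats::rbinom(1L, 1L, grammar@branchProb)
    } else if (stats::runif(1L) < grammar@stopProb) 0L
    else 1L + stats::rbinom(1L, 1L, grammar@branchProb)
    if (k == 0L) return(invisible())
    p <- labs[idx + 1L]
    kids <- sample(grammar@childSets[[p]], k, replace = TRUE,
                   prob = grammar@childProbs[[p]])
    for (kd in kids) {
      newIdx <- length(labs)
      labs[newIdx + 1L] <<- kd
      child <<- c(child, newIdx)
      parent <<- c(parent, idx)
      elab <<- c(elab, unname(grammar@linkageRule[paste0(p, ">", kd)]))
      grow(newIdx, depth + 1L)
    }
  }
  grow(0L, 1L)
  new("GlycanGraph", nodeLabels = labs, childIndex = child,
      parentIndex = parent, edgeLabels = elab, rootIndex = 0L)
}

#' Generate a synthetic corpus of IUPAC-condensed glycans
#'
#' Samples rooted trees depth-first from the grammar and serializes them.
#' The family label is the root (reducing-end) residue, enabling
#' downstream-classification tests. Deterministic under \code{seed}; every
#' emitted string parses, round-trips, and tokenizes without unknowns
#' against a vocabulary built from the grammar's alphabets.
#'
#' @param grammar a \linkS4class{ToyGrammar}.
#' @param n number of glycans.
#' @param seed integer seed.
#' @return data.frame with columns \code{glycan} (IUPAC string) and
#'   \code{label} (root-residue family).
#' @export
generateCorpus <- function(grammar = toyGrammar(), n = 2000L, seed = 1L) {
  stopifnot(n > 0L)
  validObject(grammar)
  withSeed(deriveSeed(seed, 505L), {
    glycans <- character(n); fam <- character(n)
    roots <- sample(grammar@monoVocab, n, replace = TRUE)
    for (i in seq_len(n)) {
      g <- .sampleGlycan(grammar, roots[i])
      glycans[i] <- serializeIUPAC(g)
      fam[i] <- roots[i]
    }
    data.frame(glycan = glycans, label = fam, stringsAsFactors = FALSE)
  })
}

#' Bundled fixture strings
#'
#' A small deterministic fixture set: literature-standard motif strings
#' (including one pre-expansion ambiguous entry and one residue with a
#' modification suffix kept verbatim as a single token) plus 20
#' grammar-generated glycans.
#'
#' @return data.frame with columns \code{glycan} and \code{source}
#'   (\code{"motif"} or \code{"grammar"}).
#' @export
makeFixtures <- function() {
  motifs <- c("Gal(b1-3)GalNAc",          # mucin-type core 1
              "GlcNAc(b1-6)GalNAc",       # core 6
              "NeuNAc(a2-3/6)Gal",        # ambiguous pre-expansion
              "GalNAc3,4,6Ac3")           # modified residue, single token
  gen <- generateCorpus(toyGrammar(), n = 20L, seed = 42L)$glycan
  data.frame(glycan = c(motifs, gen),
             source = c(rep("motif", length(motifs)), rep("grammar", 20L)),
             stringsAsFactors = FALSE)
}
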