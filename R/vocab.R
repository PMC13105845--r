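# Vocabulary construction, persistence, and graph -> token-sequence encoding.

#' Build paired monosaccharide/linkage vocabularies from a corpus
#'
#' Content tokens are ordered by decreasing corpus frequency (ties broken
#' alphabetically, C locale) so rebuilding from the same corpus is
#' bit-identical. Labels rarer than \code{minCount} are left out and encode
#' as \code{[UNK]}. The two vocab spaces are disjoint: node and edge ids
#' index different dictionaries, feeding two separate classification heads.
#'
#' @param corpus a list of \linkS4class{GlycanGraph} objects, or a character
#'   vector of IUPAC-condensed strings (parsed on the fly).
#' @param minCount minimum corpus frequency for a label to receive an id.
#' @return a \linkS4class{Vocabulary}.
#' @examples
#' v <- buildVocab("Gal(b1-3)GalNAc")
#' tokenId(v, "Gal", "node")
#' @export
buildVocab <- function(corpus, minCount = 1L) {
  if (is.character(corpus)) corpus <- lapply(corpus, parseIUPAC)
  if (length(corpus) == 0L)
    glycanStop("glycanVocabError", "cannot build a vocabulary from an empty corpus")
  nodeCnt <- table(unlist(lapply(corpus, nodeLabels)))
  edgeCnt <- table(unlist(lapply(corpus, edgeLabels)))
  pick <- function(cnt) {
    cnt <- cnt[cnt >= minCount]
    if (length(cnt) == 0L) return(character(0))
    names(cnt)[order(-as.integer(cnt), names(cnt), method = "radix")]
  }
  new("Vocabulary", nodeTokens = pick(nodeCnt), edgeTokens = pick(edgeCnt))
}

#' Persist / reload a vocabulary as plain text
#'
#' Two key-value files (token TAB id), one per vocab space, each with a
#' versioned header line. Reloading reproduces the vocabulary bit-identically.
#'
#' @param vocab a \linkS4class{Vocabulary}.
#' @param nodePath,edgePath output (input) file paths.
#' @export
saveVocab <- function(vocab, nodePath, edgePath) {
  wr <- function(tokens, path, space) {
    ids <- seq_along(tokens) + 3L
    lines <- c(sprintf("#glycanMLM-vocab\tv1\t%s", space),
               paste(c("[PAD]", "[MASK]", "[UNK]", "[GRAPH]"), 0:3, sep = "\t"),
               if (length(tokens)) paste(tokens, ids, sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
  }
  wr(vocab@nodeTokens, nodePath, "node")
  wr(vocab@edgeTokens, edgePath, "edge")
  invisible(vocab)
}

#' @rdname saveVocab
#' @export
loadVocab <- function(nodePath, edgePath) {
  rd <- function(path, space) {
    lines <- readLines(path, encoding = "UTF-8")
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(hdr) != 3L || hdr[1L] != "#glycanMLM-vocab" || hdr[3L] != space)
      glycanStop("glycanVocabError", "\"%s\" is not a %s vocab file", path, space)
    kv <- strsplit(lines[-1L], "\t", fixed = TRUE)
    tok <- vapply(kv, `[[`, character(1), 1L)
    id <- as.integer(vapply(kv, `[[`, character(1), 2L))
    content <- tok[id >= 4L][order(id[id >= 4L])]
    content
  }
  new("Vocabulary", nodeTokens = rd(nodePath, "node"), edgeTokens = rd(edgePath, "edge"))
}

#' Encode a GlycanGraph as a flat token sequence
#'
#' Token order is fixed: the [Graph] summary token first, then node tokens in
#' node-index order, then edge tokens in child-index order. A node token at
#' node index v carries endpoints (v, v); an edge token for bond u -> v
#' carries (u, v). Labels absent from the vocabulary encode as \code{[UNK]}.
#' Edges incident to a non-reducing terminal residue (a degree-1 non-root
#' leaf) are flagged terminal: such linkages have context on one side only
#' and are excluded from masking targets. With \code{rootEdgeTerminal} a
#' degree-1 reducing end also makes its edge terminal, which additionally
#' marks the root-side end edge of a linear chain.
#'
#' @param g a \linkS4class{GlycanGraph}.
#' @param vocab a \linkS4class{Vocabulary}.
#' @param rootEdgeTerminal if TRUE, a degree-1 root also counts as an end;
#'   default FALSE (only non-root leaves).
#' @return a \linkS4class{TokenizedGraph}.
#' @examples
#' v <- buildVocab("Gal(b1-3)GalNAc")
#' encodeGlycan(parseIUPAC("Gal(b1-3)GalNAc"), v)
#' @export
encodeGlycan <- function(g, vocab, rootEdgeTerminal = FALSE) {
  stopifnot(is(g, "GlycanGraph"), is(vocab, "Vocabulary"))
  n <- nNodes(g); m <- nEdges(g)
  ord <- order(g@childIndex)         # edge tokens in child-index order
  child <- g@childIndex[ord]; parent <- g@parentIndex[ord]
  elab <- g@edgeLabels[ord]
  deg <- tabulate(c(child, parent) + 1L, nbins = n)
  isEnd <- if (rootEdgeTerminal) deg == 1L
           else deg == 1L & (seq_len(n) - 1L) != g@rootIndex
  term <- isEnd[child + 1L] | isEnd[parent + 1L]
  tg <- new("TokenizedGraph",
            contentId = c(SPECIALS[["GRAPH"]],
                          as.integer(tokenId(vocab, g@nodeLabels, "node")),
                          as.integer(tokenId(vocab, elab, "edge"))),
            type = c(0L, rep(1L, n), rep(2L, m)),
            u = c(-1L, seq_len(n) - 1L, child),
            v = c(-1L, seq_len(n) - 1L, parent),
            nNodes = as.integer(n), nEdges = as.integer(m),
            terminalEdge = as.logical(term))
  validObject(tg)
  tg
}

#' Decode the token sequence of a TokenizedGraph back to label strings
#'
#' @param tg a \linkS4class{TokenizedGraph}.
#' @param vocab the \linkS4class{Vocabulary} used to encode it.
#' @return character vector of token labels ([Graph] first).
#' @export
decodeTokens <- function(tg, vocab) {
  out <- character(length(tg@contentId))
  out[tg@type == 0L] <- "[GRAPH]"
  out[tg@type == 1L] <- tokenLabel(vocab, tg@contentId[tg@type == 1L], "node")
  out[tg@type == 2L] <- tokenLabel(vocab, tg@contentId[tg@type == 2L], "edge")
  out
}
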