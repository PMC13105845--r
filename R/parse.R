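# IUPAC-condensed parsing and serialization.
#
# Grammar: a glycan is a sequence of residue segments read left (non-reducing
# termini) to right (reducing end); "(L)" between residue A and residue B
# creates the edge A -> B labeled L; a bracketed substring "[...]" preceding
# residue B is an independent sub-glycan whose root attaches to B with its
# trailing linkage. Residue labels are kept verbatim (modifications such as
# "GalNAc3,4,6Ac3" are single tokens).

glycanStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "glycanError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Split an IUPAC string into tokens: residues, "(link)", "[", "]".
# Returns a data.frame(kind, text, offset) with 1-based character offsets.
.iupacTokens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  kind <- character(0); tok <- character(0); off <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") {
        if (chars[j] %in% c("(", "[", "]"))
          glycanStop("glycanParseError",
                     "unbalanced '(' at offset %d in \"%s\"", i, text)
        j <- j + 1L
      }
      if (j > n)
        glycanStop("glycanParseError",
                   "unbalanced '(' at offset %d in \"%s\"", i, text)
      kind <- c(kind, "link")
      tok <- c(tok, paste(chars[seq.int(i + 1L, length.out = j - i - 1L)], collapse = ""))
      off <- c(off, i)
      i <- j + 1L
    } else if (ch == ")") {
      glycanStop("glycanParseError",
                 "unbalanced ')' at offset %d in \"%s\"", i, text)
    } else if (ch == "[" || ch == "]") {
      kind <- c(kind, ch); tok <- c(tok, ch); off <- c(off, i)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !(chars[j] %in% c("(", ")", "[", "]"))) j <- j + 1L
      kind <- c(kind, "residue")
      tok <- c(tok, paste(chars[i:(j - 1L)], collapse = ""))
      off <- c(off, i)
      i <- j
    }
  }
  data.frame(kind = kind, text = tok, offset = off, stringsAsFactors = FALSE)
}

#' Parse a glycan in IUPAC-condensed notation
#'
#' Converts text such as \code{"Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc"}
#' into a \linkS4class{GlycanGraph}: a rooted labeled tree whose
#' (child, linkage, parent) triples are the head--relation--tail triples of
#' the notation, with the reducing-end (rightmost) residue as root. Node
#' indices are assigned 0-based in left-to-right textual order.
#'
#' @param text a single IUPAC-condensed string.
#' @return a \linkS4class{GlycanGraph}.
#' @section Errors: unbalanced brackets, empty residue or linkage tokens, and
#'   dangling linkages signal a condition of class \code{"glycanParseError"};
#'   ambiguous symbols (\code{"?"} or \code{"/"}) signal
#'   \code{"glycanAmbiguityError"} so callers can choose between filtering
#'   and expansion (see \code{\link{curateCorpus}}).
#' @examples
#' g <- parseIUPAC("Gal(b1-3)GalNAc")
#' edgeTable(g)
#' @export
parseIUPAC <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || nchar(text) == 0L)
    glycanStop("glycanParseError", "input must be one non-empty string")
  if (grepl("?", text, fixed = TRUE))
    glycanStop("glycanAmbiguityError",
               "ambiguous symbol '?' in \"%s\"; filter or expand before parsing", text)
  toks <- .iupacTokens(text)

  nodeLab <- character(0)           # by node index + 1
  # a "built" subtree is a list(root = idx, child = int vec, parent = int vec, lab = chr vec)
  pending <- list()                 # list of list(sub, link)
  current <- NULL
  stack <- list()                   # saved (pending, current) for '[' contexts

  attachPending <- function(sub, parentIdx) {
    for (p in pending) {
      sub$child <- c(sub$child, p$sub$child, p$sub$root)
      sub$parent <- c(sub$parent, p$sub$parent, parentIdx)
      sub$lab <- c(sub$lab, p$sub$lab, p$link)
    }
    sub
  }

  for (k in seq_len(nrow(toks))) {
    kind <- toks$kind[k]; tk <- toks$text[k]; offs <- toks$offset[k]
    if (kind == "residue") {
      if (!is.null(current))
        glycanStop("glycanParseError",
                   "residue at offset %d not joined by a linkage in \"%s\"", offs, text)
      if (grepl("/", tk, fixed = TRUE))
        glycanStop("glycanAmbiguityError",
                   "ambiguous symbol '/' in residue \"%s\" of \"%s\"", tk, text)
      idx <- length(nodeLab)        # 0-based index
      nodeLab <- c(nodeLab, tk)
      sub <- list(root = idx, child = integer(0), parent = integer(0), lab = character(0))
      sub <- attachPending(sub, idx)
      pending <- list()
      current <- sub
    } else if (kind == "link") {
      if (tk == "")
        glycanStop("glycanParseError", "empty linkage at offset %d in \"%s\"", offs, text)
      if (grepl("/", tk, fixed = TRUE))
        glycanStop("glycanAmbiguityError",
                   "unresolved linkage alternatives \"%s\" in \"%s\"; expand first", tk, text)
      if (is.null(current))
        glycanStop("glycanParseError",
                   "linkage without a preceding residue at offset %d in \"%s\"", offs, text)
      pending <- c(pending, list(list(sub = current, link = tk)))
      current <- NULL
    } else if (kind == "[") {
      stack <- c(stack, list(list(pending = pending, current = current)))
      pending <- list(); current <- NULL
    } else { # "]"
      if (length(stack) == 0L)
        glycanStop("glycanParseError", "unbalanced ']' at offset %d in \"%s\"", offs, text)
      if (!is.null(current) || length(pending) != 1L)
        glycanStop("glycanParseError",
                   "branch must end with a linkage before ']' at offset %d in \"%s\"", offs, text)
      branch <- pending[[1L]]
      ctx <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pending <- c(ctx$pending, list(branch))
      current <- ctx$current
    }
  }
  if (length(stack) > 0L)
    glycanStop("glycanParseError", "unbalanced '[' in \"%s\"", text)
  if (is.null(current) || length(pending) > 0L)
    glycanStop("glycanParseError", "dangling linkage at end of \"%s\"", text)

  g <- new("GlycanGraph",
           nodeLabels = nodeLab,
           childIndex = as.integer(current$child),
           parentIndex = as.integer(current$parent),
           edgeLabels = current$lab,
           rootIndex = as.integer(current$root))
  validObject(g)
  g
}

#' Serialize a GlycanGraph back to IUPAC-condensed notation
#'
#' Branch order is normalized deterministically: among the children of a
#' residue, the main chain continues through the child whose linkage label is
#' lexicographically greatest (C locale); the remaining children appear in
#' square brackets in lexicographically ascending order. Round trip:
#' \code{parseIUPAC(serializeIUPAC(g))} is isomorphic to \code{g} as a
#' labeled rooted tree.
#'
#' @param g a \linkS4class{GlycanGraph}.
#' @return a single IUPAC-condensed string.
#' @export
serializeIUPAC <- function(g) {
  stopifnot(is(g, "GlycanGraph"))
  validObject(g)
  ser <- function(idx) {
    sel <- which(g@parentIndex == idx)
    if (length(sel) == 0L) return(g@nodeLabels[idx + 1L])
    labs <- g@edgeLabels[sel]
    kids <- g@childIndex[sel]
    # order by (linkage label, child subtree string) for a total, stable rule
    kidStr <- vapply(kids, ser, character(1))
    ord <- order(labs, kidStr, method = "radix")
    mainPos <- ord[length(ord)]                 # lexicographically greatest linkage
    rest <- ord[-length(ord)]
    out <- paste0(kidStr[mainPos], "(", labs[mainPos], ")")
    for (r in rest) out <- paste0(out, "[", kidStr[r], "(", labs[r], ")]")
    paste0(out, g@nodeLabels[idx + 1L])
  }
  ser(g@rootIndex)
}

#' Test whether two GlycanGraphs are isomorphic as labeled rooted trees
#'
#' Compares canonical forms built bottom-up from (residue label, sorted child
#' (linkage, canonical-subtree) pairs), ignoring node numbering and branch
#' order.
#'
#' @param g1,g2 \linkS4class{GlycanGraph} objects.
#' @return TRUE or FALSE.
#' @export
isIsomorphic <- function(g1, g2) {
  canon <- function(g, idx) {
    sel <- which(g@parentIndex == idx)
    if (length(sel) == 0L) return(paste0("<", g@nodeLabels[idx + 1L], ">"))
    parts <- vapply(seq_along(sel), function(i) {
      paste0("(", g@edgeLabels[sel[i]], ":", canon(g, g@childIndex[sel[i]]), ")")
    }, character(1))
    paste0("<", g@nodeLabels[idx + 1L], "|",
           paste(sort(parts, method = "radix"), collapse = ""), ">")
  }
  canon(g1, g1@rootIndex) == canon(g2, g2@rootIndex)
}
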