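# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: label multisets come from flat string scanning,
# the WL oracle materializes uncompressed label strings, AUPRC is computed by
# exhaustive threshold enumeration.

# Node/edge label multisets straight from an IUPAC-condensed string:
# edge labels are the parenthetical substrings, node labels are what remains
# after removing them and splitting on brackets.
stringTokenOracle <- function(s) {
  ed <- regmatches(s, gregexpr("\\(([^()]*)\\)", s))[[1L]]
  ed <- substring(ed, 2L, nchar(ed) - 1L)
  nd <- strsplit(gsub("\\([^()]*\\)", "\x1f", s), "[\x1f\\[\\]]+", perl = TRUE)[[1L]]
  nd <- nd[nzchar(nd)]
  list(nodes = sort(nd), edges = sort(ed))
}

# Brute-force WL subtree kernel: explicit uncompressed label multisets.
bruteForceWL <- function(graphs, h) {
  n <- length(graphs)
  adj <- lapply(graphs, function(g) {
    nb <- vector("list", nNodes(g))
    et <- edgeTable(g)
    for (e in seq_len(nrow(et))) {
      a <- et$child[e] + 1L; b <- et$parent[e] + 1L
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
    nb
  })
  labs <- lapply(graphs, nodeLabels)
  K <- matrix(0, n, n)
  addProducts <- function(K, labs) {
    hists <- lapply(labs, table)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      shared <- intersect(names(hists[[i]]), names(hists[[j]]))
      K[i, j] <- K[i, j] +
        sum(as.numeric(hists[[i]][shared]) * as.numeric(hists[[j]][shared]))
    }
    K
  }
  K <- addProducts(K, labs)
  for (it in seq_len(h)) {
    labs <- lapply(seq_len(n), function(i) {
      lb <- labs[[i]]
      vapply(seq_along(lb), function(v)
        paste0(lb[v], "{", paste(sort(lb[adj[[i]][[v]]]), collapse = ";"), "}"),
        character(1))
    })
    K <- addProducts(K, labs)
  }
  K
}

# AUPRC by exhaustive threshold enumeration: every distinct score is a
# threshold; precision envelope taken by scanning all thresholds per recall.
bruteForceAUPRC <- function(y, scores) {
  y <- as.integer(as.logical(y))
  th <- sort(unique(scores), decreasing = TRUE)
  pr <- t(vapply(th, function(t) {
    pred <- scores >= t
    c(prec = sum(y == 1L & pred) / max(1L, sum(pred)),
      rec = sum(y == 1L & pred) / sum(y))
  }, numeric(2)))
  recs <- pr[, "rec"]
  env <- vapply(seq_along(recs), function(i) max(pr[recs >= recs[i], "prec"]),
                numeric(1))
  ord <- order(recs)
  recs <- recs[ord]; env <- env[ord]
  keep <- !duplicated(recs, fromLast = TRUE)
  recs <- recs[keep]; env <- env[keep]
  sum(diff(c(0, recs)) * env)
}

realGlycanFixtures <- function() {
  readCorpus(system.file("extdata", "real_glycans.txt", package = "glycanMLM"))
}
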