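# Weisfeiler-Lehman subtree kernel on glycan trees.

#' Weisfeiler-Lehman subtree kernel similarity matrix
#'
#' Nodes are labeled by monosaccharide identity; linkage labels do not enter
#' the relabeling and edges contribute adjacency only (undirected). At each
#' of h iterations every node label is replaced by a compressed label built
#' from its current label and the sorted multiset of its neighbors' labels;
#' the unnormalized kernel is the sum over iterations 0..h of the dot
#' products of label-count histograms, and the returned matrix is
#' normalized: K(g, g') = k(g, g') / sqrt(k(g, g) k(g', g')). The result is
#' symmetric with unit diagonal, entries in [0, 1], and positive
#' semidefinite up to numerical tolerance.
#'
#' @param graphs non-empty list of \linkS4class{GlycanGraph} objects (or a
#'   character vector of IUPAC strings).
#' @param h number of WL refinement iterations (default 3).
#' @param normalize return the normalized matrix (default) or raw kernel.
#' @param ids optional identifiers for dimnames.
#' @return similarity matrix with attribute \code{"h"}.
#' @examples
#' K <- wlKernel(c("Gal(b1-3)GalNAc", "Gal(b1-3)GalNAc", "Man"))
#' K[1, 2]   # identical structures: 1
#' @export
wlKernel <- function(graphs, h = 3L, normalize = TRUE, ids = NULL) {
  if (is.character(graphs)) graphs <- lapply(graphs, parseIUPAC)
  if (length(graphs) == 0L)
    glycanStop("glycanKernelError", "need at least one graph")
  n <- length(graphs)
  adj <- lapply(graphs, function(g) {
    if (nNodes(g) == 0L) glycanStop("glycanKernelError", "empty graph")
    nb <- vector("list", nNodes(g))
    for (e in seq_len(nEdges(g))) {
      a <- g@childIndex[e] + 1L; b <- g@parentIndex[e] + 1L
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
    nb
  })
  labels <- lapply(graphs, nodeLabels)
  K <- matrix(0, n, n)
  addHistogramProducts <- function(K, labels) {
    # global compressed relabeling so histograms are comparable across graphs
    all <- unlist(labels)
    lev <- sort(unique(all), method = "radix")
    counts <- lapply(labels, function(lb)
      tabulate(match(lb, lev), nbins = length(lev)))
    Cm <- do.call(rbind, counts)
    K + tcrossprod(Cm)
  }
  K <- addHistogramProducts(K, labels)
  for (it in seq_len(h)) {
    labels <- lapply(seq_len(n), function(i) {
      lb <- labels[[i]]
      vapply(seq_along(lb), function(v) {
        nbl <- sort(lb[adj[[i]][[v]]], method = "radix")
        paste0(lb[v], "|", paste(nbl, collapse = ","))
      }, character(1))
    })
    # compress to short ids so strings do not grow exponentially
    lev <- sort(unique(unlist(labels)), method = "radix")
    labels <- lapply(labels, function(lb) as.character(match(lb, lev) + it * 1e6))
    K <- addHistogramProducts(K, labels)
  }
  if (normalize) {
    dg <- sqrt(diag(K))
    K <- K / tcrossprod(dg)
  }
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  attr(K, "h") <- as.integer(h)
  K
}

#' Average-linkage clustering of a kernel matrix
#'
#' Reporting aid for similarity heatmaps: hierarchical clustering on the
#' 1 - K distance with average linkage.
#'
#' @param K a normalized kernel matrix from \code{\link{wlKernel}}.
#' @return an \code{hclust} object.
#' @export
kernelHclust <- function(K) {
  stats::hclust(stats::as.dist(1 - K), method = "average")
}
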