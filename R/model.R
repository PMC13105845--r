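# Tokenized graph transformer: configuration, parameter initialization, and
# the batched forward pass. Each token embedding is the sum of (i) a content
# embedding looked up by token id, (ii) a linear projection of the
# concatenated ORF identifiers of its endpoints, and (iii) a trainable type
# embedding (node / edge / graph). The [Graph] token is prepended with its
# own trainable content vector and a zero identifier; its final state is the
# whole-glycan embedding. Encoder blocks are post-norm: each sub-layer
# (multi-head self-attention or MLP) is followed by a residual connection and
# LayerNorm.

.SCALES <- list(
  ss     = c(depth = 2L,  d = 64L,  heads = 4L),
  small  = c(depth = 4L,  d = 128L, heads = 4L),
  medium = c(depth = 8L,  d = 256L, heads = 8L),
  large  = c(depth = 12L, d = 512L, heads = 16L)
)

#' Model configuration
#'
#' Four named scales are provided (depth x width x heads): ss = 2x64x4,
#' small = 4x128x4, medium = 8x256x8, large = 12x512x16; any field can be
#' overridden. The MLP hidden width is 4d with GELU activation.
#'
#' @param scale one of "ss", "small", "medium", "large".
#' @param depth,d,heads encoder depth, model width, attention heads
#'   (defaults from \code{scale}; d must be divisible by heads).
#' @param dP identifier dimension of the ORF bank.
#' @param maxNodes largest addressable node index + 1 (must be <= dP).
#' @param dropout dropout fraction applied to sub-layer outputs in training.
#' @param seed seed for parameter initialization and the ORF bank.
#' @return a list of class \code{"ModelConfig"}.
#' @export
modelConfig <- function(scale = "ss", depth = NULL, d = NULL, heads = NULL,
                        dP = 64L, maxNodes = 64L, dropout = 0.1, seed = 1L) {
  if (!scale %in% names(.SCALES))
    glycanStop("glycanConfigError", "unknown scale \"%s\"", scale)
  base <- .SCALES[[scale]]
  cfg <- list(scale = scale,
              depth = as.integer(depth %||% base[["depth"]]),
              d = as.integer(d %||% base[["d"]]),
              heads = as.integer(heads %||% base[["heads"]]),
              dP = as.integer(dP), maxNodes = as.integer(maxNodes),
              dropout = dropout, seed = as.integer(seed))
  if (cfg$d %% cfg$heads != 0L)
    glycanStop("glycanConfigError", "model width %d not divisible by %d heads",
               cfg$d, cfg$heads)
  if (cfg$maxNodes > cfg$dP)
    glycanStop("glycanConfigError", "maxNodes (%d) must not exceed dP (%d)",
               cfg$maxNodes, cfg$dP)
  stopifnot(cfg$depth >= 1L, cfg$dropout >= 0, cfg$dropout < 1)
  structure(cfg, class = "ModelConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A pretrained (or freshly initialized) glycan language model
#'
#' Bundles the encoder configuration, the vocabulary it was built against,
#' the seeded ORF identifier bank, the parameter list, and the training log.
#'
#' @slot config a \code{ModelConfig} list.
#' @slot vocab the \linkS4class{Vocabulary}.
#' @slot bank the ORF identifier matrix (dP x dP).
#' @slot params named list of parameter matrices.
#' @slot log per-epoch training log (empty until pretraining).
#' @slot meta list: seed, vocab fingerprints, epochs trained.
#' @export
setClass("GlycanLM", representation(
  config = "list", vocab = "Vocabulary", bank = "matrix",
  params = "list", log = "data.frame", meta = "list"
))

setMethod("show", "GlycanLM", function(object) {
  cfg <- object@config
  cat(sprintf("GlycanLM [%s]: depth %d, width %d, %d heads; vocab %d/%d content tokens; %s\n",
              cfg$scale, cfg$depth, cfg$d, cfg$heads,
              length(object@vocab@nodeTokens), length(object@vocab@edgeTokens),
              if (nrow(object@log)) sprintf("trained %d epochs", max(object@log$epoch))
              else "untrained"))
})

# Parameter initialization. Weights ~ N(0, 0.02^2); LayerNorm at identity;
# the two MLM heads start at zero so an untrained model emits exactly uniform
# probabilities over each content vocabulary.
.initParams <- function(cfg, nodeVocabSize, edgeVocabSize) {
  withSeed(deriveSeed(cfg$seed, 202L), {
    d <- cfg$d; h <- 4L * d
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    layers <- lapply(seq_len(cfg$depth), function(l) list(
      Wq = g(d, d), bq = numeric(d), Wk = g(d, d), bk = numeric(d),
      Wv = g(d, d), bv = numeric(d), Wo = g(d, d), bo = numeric(d),
      ln1g = rep(1, d), ln1b = numeric(d),
      W1 = g(d, h), b1 = numeric(h), W2 = g(h, d), b2 = numeric(d),
      ln2g = rep(1, d), ln2b = numeric(d)))
    list(
      En = g(nodeVocabSize, d), Ee = g(edgeVocabSize, d),
      gvec = g(1L, d), Wid = g(2L * cfg$dP, d), Etype = g(3L, d),
      layers = layers,
      Whn = matrix(0, d, nodeVocabSize - 4L), bhn = numeric(nodeVocabSize - 4L),
      Whe = matrix(0, d, edgeVocabSize - 4L), bhe = numeric(edgeVocabSize - 4L))
  })
}

#' Initialize a glycan language model
#'
#' @param vocab a \linkS4class{Vocabulary}.
#' @param config a \code{ModelConfig} (see \code{\link{modelConfig}}).
#' @return an untrained \linkS4class{GlycanLM}.
#' @export
initGlycanLM <- function(vocab, config = modelConfig()) {
  stopifnot(is(vocab, "Vocabulary"), inherits(config, "ModelConfig"))
  bank <- orfBank(config$dP, config$seed)
  params <- .initParams(config, vocabSize(vocab, "node"), vocabSize(vocab, "edge"))
  new("GlycanLM", config = unclass(config), vocab = vocab, bank = bank, params = params,
      log = data.frame(), meta = list(
        seed = config$seed,
        nodeVocabHash = stringHash(vocab@nodeTokens),
        edgeVocabHash = stringHash(vocab@edgeTokens)))
}

# ---- batch assembly --------------------------------------------------------

# Flatten a list of TokenizedGraphs (with optional per-graph masked content
# ids) into stacked index vectors. Padding tokens are never materialized:
# sequences keep their own rows and attention is computed per sequence, so
# padding isolation holds by construction.
.assembleBatch <- function(tgs, maskedIds = NULL, maxNodes = 64L) {
  lens <- vapply(tgs, function(t) length(t@contentId), integer(1))
  offs <- c(0L, cumsum(lens))
  ids <- unlist(lapply(seq_along(tgs), function(i)
    if (is.null(maskedIds)) tgs[[i]]@contentId else maskedIds[[i]]))
  u <- unlist(lapply(tgs, slot, "u"))
  v <- unlist(lapply(tgs, slot, "v"))
  type <- unlist(lapply(tgs, slot, "type"))
  if (any(u >= maxNodes) || any(v >= maxNodes))
    glycanStop("glycanCapacityError",
               "glycan has a node index >= maxNodes (%d); enlarge dP/maxNodes", maxNodes)
  list(ids = as.integer(ids), u = as.integer(u), v = as.integer(v),
       type = as.integer(type), lens = lens, offs = offs, N = sum(lens))
}

# Input embeddings for an assembled batch. Returns X0 and the identifier
# feature matrix (needed for the Wid gradient).
.embedBatch <- function(params, cfg, bank, ab) {
  d <- cfg$d; dP <- cfg$dP; N <- ab$N
  X0 <- matrix(0, N, d)
  nodeSel <- ab$type == 1L; edgeSel <- ab$type == 2L; graphSel <- ab$type == 0L
  if (any(nodeSel)) X0[nodeSel, ] <- params$En[ab$ids[nodeSel] + 1L, , drop = FALSE]
  if (any(edgeSel)) X0[edgeSel, ] <- params$Ee[ab$ids[edgeSel] + 1L, , drop = FALSE]
  if (any(graphSel)) X0[graphSel, ] <- rep(params$gvec[1L, ], each = sum(graphSel))
  idf <- matrix(0, N, 2L * dP)
  real <- ab$u >= 0L
  idf[real, seq_len(dP)] <- bank[ab$u[real] + 1L, , drop = FALSE]
  idf[real, dP + seq_len(dP)] <- bank[ab$v[real] + 1L, , drop = FALSE]
  X0 <- X0 + idf %*% params$Wid
  typeRow <- ifelse(ab$type == 0L, 3L, ab$type)   # node=1, edge=2, graph=3
  X0 <- X0 + params$Etype[typeRow, , drop = FALSE]
  list(X0 = X0, idf = idf, typeRow = typeRow)
}

.lnFwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = addB(xhat * rep(gamma, each = nrow(x)), beta), xhat = xhat, inv = inv)
}

.lnBwd <- function(dy, ln, gamma) {
  N <- nrow(dy)
  gm <- rep(gamma, each = N)
  dgamma <- colSums(dy * ln$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * gm
  dx <- ln$inv * (dxhat - rowMeans(dxhat) - ln$xhat * rowMeans(dxhat * ln$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# GELU, tanh form: 0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3))).
.geluC <- sqrt(2 / pi)
.gelu <- function(x) {
  t <- tanh(.geluC * (x + 0.044715 * x^3))
  0.5 * x * (1 + t)
}
.geluGrad <- function(x) {
  inner <- .geluC * (x + 0.044715 * x^3)
  t <- tanh(inner)
  0.5 * (1 + t) + 0.5 * x * (1 - t * t) * .geluC * (1 + 3 * 0.044715 * x^2)
}

# Full forward pass over an assembled batch. dropoutP > 0 draws seeded
# dropout masks (training); keepCache retains everything backward needs;
# keepAttention retains per-(seq, head) attention matrices of every layer.
.fwdBatch <- function(params, cfg, bank, ab, dropoutP = 0, dropSeed = 0L,
                      keepCache = FALSE, keepAttention = FALSE) {
  emb <- .embedBatch(params, cfg, bank, ab)
  X <- emb$X0
  d <- cfg$d; H <- cfg$heads; dh <- d %/% H
  scal <- 1 / sqrt(dh)
  B <- length(ab$lens)
  rowsOf <- lapply(seq_len(B), function(s) (ab$offs[s] + 1L):ab$offs[s + 1L])
  colsOf <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  cache <- if (keepCache) list(emb = emb, layers = vector("list", cfg$depth)) else NULL
  attn <- if (keepAttention) vector("list", cfg$depth) else NULL
  dropMask <- function(nr, nc, k) {
    if (dropoutP <= 0) return(NULL)
    withSeed(deriveSeed(dropSeed, k), {
      matrix((stats::runif(nr * nc) >= dropoutP) / (1 - dropoutP), nr, nc)
    })
  }
  for (l in seq_len(cfg$depth)) {
    P <- params$layers[[l]]
    Xin <- X
    QKV <- addB(Xin %*% cbind(P$Wq, P$Wk, P$Wv), c(P$bq, P$bk, P$bv))
    Q <- QKV[, 1:d, drop = FALSE]
    K <- QKV[, d + (1:d), drop = FALSE]
    V <- QKV[, 2 * d + (1:d), drop = FALSE]
    Hcat <- matrix(0, ab$N, d)
    Alist <- if (keepCache || keepAttention) vector("list", B) else NULL
    for (s in seq_len(B)) {
      rs <- rowsOf[[s]]
      Ah <- if (!is.null(Alist)) vector("list", H) else NULL
      for (h in seq_len(H)) {
        ch <- colsOf[[h]]
        Qs <- Q[rs, ch, drop = FALSE]
        Ks <- K[rs, ch, drop = FALSE]
        A <- softmaxRows(tcrossprod(Qs, Ks) * scal)
        Hcat[rs, ch] <- A %*% V[rs, ch, drop = FALSE]
        if (!is.null(Ah)) Ah[[h]] <- A
      }
      if (!is.null(Alist)) Alist[[s]] <- Ah
    }
    O <- addB(Hcat %*% P$Wo, P$bo)
    mO <- dropMask(ab$N, d, 2L * l)
    if (!is.null(mO)) O <- O * mO
    ln1 <- .lnFwd(Xin + O, P$ln1g, P$ln1b)
    X1 <- ln1$y
    A1 <- addB(X1 %*% P$W1, P$b1)
    H1 <- .gelu(A1)
    M2 <- addB(H1 %*% P$W2, P$b2)
    mM <- dropMask(ab$N, d, 2L * l + 1L)
    if (!is.null(mM)) M2 <- M2 * mM
    ln2 <- .lnFwd(X1 + M2, P$ln2g, P$ln2b)
    X <- ln2$y
    if (keepCache)
      cache$layers[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, Alist = Alist,
                                Hcat = Hcat, mO = mO, ln1 = ln1, X1 = X1,
                                A1 = A1, H1 = H1, mM = mM, ln2 = ln2)
    if (keepAttention) attn[[l]] <- Alist
  }
  list(X = X, cache = cache, attn = attn, rowsOf = rowsOf, colsOf = colsOf)
}

# Backward pass. dX is the gradient at the final token states; returns a
# gradient list with the same shape as params.
.bwdBatch <- function(params, cfg, ab, fwd, dX) {
  d <- cfg$d; H <- cfg$heads; dh <- d %/% H
  scal <- 1 / sqrt(dh)
  B <- length(ab$lens)
  rowsOf <- fwd$rowsOf; colsOf <- fwd$colsOf
  grads <- list(layers = vector("list", cfg$depth))
  for (l in rev(seq_len(cfg$depth))) {
    P <- params$layers[[l]]
    C <- fwd$cache$layers[[l]]
    b2 <- .lnBwd(dX, C$ln2, P$ln2g)
    dM2 <- b2$dx
    dX1 <- b2$dx
    if (!is.null(C$mM)) dM2 <- dM2 * C$mM
    dW2 <- crossprod(C$H1, dM2)
    db2 <- colSums(dM2)
    dH1 <- tcrossprod(dM2, P$W2)
    dA1 <- dH1 * .geluGrad(C$A1)
    dW1 <- crossprod(C$X1, dA1)
    db1 <- colSums(dA1)
    dX1 <- dX1 + tcrossprod(dA1, P$W1)
    b1 <- .lnBwd(dX1, C$ln1, P$ln1g)
    dO <- b1$dx
    dXin <- b1$dx
    if (!is.null(C$mO)) dO <- dO * C$mO
    dWo <- crossprod(C$Hcat, dO)
    dbo <- colSums(dO)
    dHcat <- tcrossprod(dO, P$Wo)
    dQ <- matrix(0, ab$N, d); dK <- matrix(0, ab$N, d); dV <- matrix(0, ab$N, d)
    for (s in seq_len(B)) {
      rs <- rowsOf[[s]]
      for (h in seq_len(H)) {
        ch <- colsOf[[h]]
        A <- C$Alist[[s]][[h]]
        dHs <- dHcat[rs, ch, drop = FALSE]
        Vs <- C$V[rs, ch, drop = FALSE]
        dA <- tcrossprod(dHs, Vs)
        dV[rs, ch] <- crossprod(A, dHs)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rs, ch] <- (dS %*% C$K[rs, ch, drop = FALSE]) * scal
        dK[rs, ch] <- crossprod(dS, C$Q[rs, ch, drop = FALSE]) * scal
      }
    }
    grads$layers[[l]] <- list(
      Wq = crossprod(C$Xin, dQ), bq = colSums(dQ),
      Wk = crossprod(C$Xin, dK), bk = colSums(dK),
      Wv = crossprod(C$Xin, dV), bv = colSums(dV),
      Wo = dWo, bo = dbo,
      ln1g = b1$dgamma, ln1b = b1$dbeta,
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
      ln2g = b2$dgamma, ln2b = b2$dbeta)
    dX <- dXin + tcrossprod(cbind(dQ, dK, dV), cbind(P$Wq, P$Wk, P$Wv))
  }
  # embedding gradients
  emb <- fwd$cache$emb
  grads$Wid <- crossprod(emb$idf, dX)
  et <- rowsum(dX, emb$typeRow, reorder = TRUE)
  full <- matrix(0, 3L, d)
  full[as.integer(rownames(et)), ] <- et
  grads$Etype <- full
  nodeSel <- ab$type == 1L; edgeSel <- ab$type == 2L; graphSel <- ab$type == 0L
  accum <- function(nrows, sel) {
    G <- matrix(0, nrows, d)
    if (any(sel)) {
      rs <- rowsum(dX[sel, , drop = FALSE], ab$ids[sel] + 1L, reorder = TRUE)
      G[as.integer(rownames(rs)), ] <- rs
    }
    G
  }
  grads$En <- accum(nrow(params$En), nodeSel)
  grads$Ee <- accum(nrow(params$Ee), edgeSel)
  grads$gvec <- matrix(colSums(dX[graphSel, , drop = FALSE]), 1L, d)
  grads
}

# ---- public forward surface ------------------------------------------------

#' Input token embeddings for one glycan
#'
#' The pre-encoder embedding matrix: content embedding + projected ORF
#' identifier pair + type embedding per token ([Graph] first).
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param tg a \linkS4class{TokenizedGraph}.
#' @param maskedIds optional integer vector of content ids overriding
#'   \code{tg@contentId} (masked-input view).
#' @return numeric matrix, one row per token, \code{config$d} columns.
#' @export
embedTokens <- function(model, tg, maskedIds = NULL) {
  ab <- .assembleBatch(list(tg), if (is.null(maskedIds)) NULL else list(maskedIds),
                       model@config$maxNodes)
  .embedBatch(model@params, model@config, model@bank, ab)$X0
}

#' Run the encoder
#'
#' Full self-attention over all real tokens of each glycan; deterministic
#' (dropout off) unless \code{dropout} is set. Sequences are processed with
#' per-sequence attention, so tokens of one glycan never influence another
#' and padding isolation holds exactly.
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param tgs a \linkS4class{TokenizedGraph} or a list of them.
#' @param maskPlans optional \linkS4class{MaskingPlan} (or list, parallel to
#'   \code{tgs}) applied to the inputs: masked positions read \code{[MASK]}
#'   while identifiers and type stay visible.
#' @param returnAttention if TRUE, attach per-layer per-head attention
#'   matrices.
#' @param dropout dropout fraction (0 = inference).
#' @param dropSeed seed for dropout masks when \code{dropout > 0}.
#' @return list of class \code{"EncoderOutput"}: \code{tokenStates} (list of
#'   per-glycan matrices), \code{graphEmbedding} (matrix, one row per
#'   glycan), \code{attention} (NULL unless requested).
#' @export
encoderForward <- function(model, tgs, maskPlans = NULL, returnAttention = FALSE,
                           dropout = 0, dropSeed = 0L) {
  single <- is(tgs, "TokenizedGraph")
  if (single) tgs <- list(tgs)
  if (!is.null(maskPlans) && is(maskPlans, "MaskingPlan")) maskPlans <- list(maskPlans)
  ids <- maskedContentIds(tgs, maskPlans)
  ab <- .assembleBatch(tgs, ids, model@config$maxNodes)
  fwd <- .fwdBatch(model@params, model@config, model@bank, ab,
                   dropoutP = dropout, dropSeed = dropSeed,
                   keepAttention = returnAttention)
  B <- length(tgs)
  states <- lapply(seq_len(B), function(s) fwd$X[fwd$rowsOf[[s]], , drop = FALSE])
  ge <- do.call(rbind, lapply(states, function(m) m[1L, , drop = FALSE]))
  structure(list(tokenStates = states, graphEmbedding = ge,
                 attention = fwd$attn, assembled = ab),
            class = "EncoderOutput")
}

# Content ids with MASK substituted at planned positions.
maskedContentIds <- function(tgs, maskPlans) {
  lapply(seq_along(tgs), function(i) {
    ids <- tgs[[i]]@contentId
    if (!is.null(maskPlans) && !is.null(maskPlans[[i]])) {
      pl <- .planAsList(maskPlans[[i]])
      ids[c(pl$nodePos, pl$edgePos)] <- SPECIALS[["MASK"]]
    }
    ids
  })
}

#' MLM classification heads
#'
#' Two linear heads over the disjoint content vocabularies: node positions
#' receive logits over the monosaccharide content vocab, edge positions over
#' the linkage content vocab. Special tokens are not candidates.
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param tokenStates a per-token state matrix (one glycan) from
#'   \code{\link{encoderForward}}.
#' @param type token type vector for those rows (0 graph, 1 node, 2 edge).
#' @return list with \code{nodeLogits} (rows = node-token positions, in
#'   sequence order) and \code{edgeLogits} likewise; each carries a
#'   \code{"positions"} attribute with the token positions.
#' @export
mlmHeads <- function(model, tokenStates, type) {
  p <- model@params
  nodeRows <- which(type == 1L); edgeRows <- which(type == 2L)
  nl <- addB(tokenStates[nodeRows, , drop = FALSE] %*% p$Whn, p$bhn)
  el <- addB(tokenStates[edgeRows, , drop = FALSE] %*% p$Whe, p$bhe)
  attr(nl, "positions") <- nodeRows
  attr(el, "positions") <- edgeRows
  list(nodeLogits = nl, edgeLogits = el)
}
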