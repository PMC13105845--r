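test_that("model configuration validates scales and dimensions", {
  cfg <- modelConfig("ss")
  expect_equal(c(cfg$depth, cfg$d, cfg$heads), c(2L, 64L, 4L))
  expect_equal(modelConfig("medium")$d, 256L)
  expect_error(modelConfig("huge"), class = "glycanConfigError")
  expect_error(modelConfig("ss", d = 30L, heads = 4L), class = "glycanConfigError")
  expect_error(modelConfig("ss", dP = 8L, maxNodes = 16L), class = "glycanConfigError")
})

test_that("initialization is deterministic under the seed", {
  m1 <- tinyModel(seed = 9L); m2 <- tinyModel(seed = 9L); m3 <- tinyModel(seed = 10L)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@bank, m2@bank)
  expect_false(identical(m1@params$En, m3@params$En))
})

test_that("graph embedding is invariant to token order permutation", {
  m <- tinyModel()
  tg <- encodeGlycan(parseIUPAC("Gal(b1-3)[GlcNAc(b1-6)]GalNAc(b1-4)Gal"), m@vocab)
  base <- encoderForward(m, tg)$graphEmbedding[1L, ]
  # permute the node/edge tokens, keeping [Graph] first and each token's
  # content/endpoints/type attached
  set.seed(42)
  perm <- c(1L, 1L + sample(length(tg@contentId) - 1L))
  ptg <- new("TokenizedGraph",
             contentId = tg@contentId[perm], type = tg@type[perm],
             u = tg@u[perm], v = tg@v[perm],
             nNodes = tg@nNodes, nEdges = tg@nEdges,
             terminalEdge = tg@terminalEdge)
  pe <- encoderForward(m, ptg)$graphEmbedding[1L, ]
  expect_lt(sqrt(sum((pe - base)^2)) / sqrt(sum(base^2)), 1e-4)
})

test_that("a glycan's outputs are identical alone or inside a batch", {
  m <- tinyModel()
  corp <- generateCorpus(toyGrammar(), 3L, seed = 14L)$glycan
  tgs <- lapply(lapply(corp, parseIUPAC), encodeGlycan, vocab = m@vocab)
  solo <- encoderForward(m, tgs[[2L]])
  batch <- encoderForward(m, tgs)
  expect_equal(batch$graphEmbedding[2L, ], solo$graphEmbedding[1L, ],
               tolerance = 1e-5)
  expect_equal(batch$tokenStates[[2L]], solo$tokenStates[[1L]],
               tolerance = 1e-5)
})

test_that("attention rows are probability distributions", {
  m <- tinyModel()
  tg <- encodeGlycan(parseIUPAC("Gal(b1-3)Gal(b1-4)Gal"), m@vocab)
  out <- encoderForward(m, tg, returnAttention = TRUE)
  for (layer in out$attention)
    for (headA in layer[[1L]])
      expect_equal(rowSums(headA), rep(1, nrow(headA)), tolerance = 1e-5)
  expect_equal(out$graphEmbedding[1L, ], out$tokenStates[[1L]][1L, ])
})

test_that("forward is deterministic with dropout off and seeded with it on", {
  m <- tinyModel()
  tg <- encodeGlycan(parseIUPAC("Gal(b1-3)GalNAc"), m@vocab)
  expect_identical(encoderForward(m, tg)$graphEmbedding,
                   encoderForward(m, tg)$graphEmbedding)
  d1 <- encoderForward(m, tg, dropout = 0.5, dropSeed = 3L)$graphEmbedding
  d2 <- encoderForward(m, tg, dropout = 0.5, dropSeed = 3L)$graphEmbedding
  d3 <- encoderForward(m, tg, dropout = 0.5, dropSeed = 4L)$graphEmbedding
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
})

test_that("MLM heads emit normalized softmax with closed-form values", {
  m <- tinyModel()
  tg <- encodeGlycan(parseIUPAC("Gal(b1-3)GalNAc"), m@vocab)
  out <- encoderForward(m, tg)
  heads <- mlmHeads(m, out$tokenStates[[1L]], tg@type)
  # zero-initialized heads: exactly uniform over each content vocab
  pn <- exp(heads$nodeLogits[1L, ]); pn <- pn / sum(pn)
  expect_equal(pn, rep(1 / ncol(heads$nodeLogits), ncol(heads$nodeLogits)))
  expect_true(all(is.finite(heads$edgeLogits)))
  # hand-set logits (2, 0): softmax = (0.8808, 0.1192)
  sm <- exp(c(2, 0)) / sum(exp(c(2, 0)))
  expect_equal(sm, c(0.8807971, 0.1192029), tolerance = 1e-6)
})

test_that("analytic gradients match numerical differentiation", {
  m <- tinyModel()
  set.seed(2)
  m@params$Whn <- matrix(rnorm(length(m@params$Whn), sd = 0.05),
                         nrow(m@params$Whn))
  m@params$Whe <- matrix(rnorm(length(m@params$Whe), sd = 0.05),
                         nrow(m@params$Whe))
  corp <- generateCorpus(toyGrammar(), 4L, seed = 16L)$glycan
  tgs <- lapply(lapply(corp, parseIUPAC), encodeGlycan, vocab = m@vocab)
  plans <- lapply(seq_along(tgs), function(i)
    makeMaskingPlan(tgs[[i]], 0.4, 0.5, seed = i))
  cfg <- m@config
  lossOf <- function(p) glycanMLM:::.batchLossGrad(
    p, cfg, m@bank, tgs, plans, 0.5, wantGrad = FALSE)$loss
  res <- glycanMLM:::.batchLossGrad(m@params, cfg, m@bank, tgs, plans, 0.5)
  eps <- 1e-5
  checkOne <- function(get, set, gval) {
    p1 <- set(m@params, get(m@params) + eps)
    p2 <- set(m@params, get(m@params) - eps)
    num <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
    expect_equal(gval, num, tolerance = 1e-4)
  }
  checkOne(function(p) p$layers[[1L]]$Wq[40L],
           function(p, v) { p$layers[[1L]]$Wq[40L] <- v; p },
           res$grads$layers[[1L]]$Wq[40L])
  checkOne(function(p) p$layers[[2L]]$W1[10L],
           function(p, v) { p$layers[[2L]]$W1[10L] <- v; p },
           res$grads$layers[[2L]]$W1[10L])
  checkOne(function(p) p$Wid[25L],
           function(p, v) { p$Wid[25L] <- v; p },
           res$grads$Wid[25L])
  checkOne(function(p) p$En[12L],
           function(p, v) { p$En[12L] <- v; p },
           res$grads$En[12L])
})

test_that("checkpoints restore a model that computes identical outputs", {
  m <- tinyModel()
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  tg <- encodeGlycan(parseIUPAC("Gal(b1-3)GalNAc"), m@vocab)
  expect_identical(encoderForward(m, tg)$graphEmbedding,
                   encoderForward(m2, tg)$graphEmbedding)
  # tampered vocabulary is refused
  ck <- readRDS(f)
  ck$nodeTokens <- c(ck$nodeTokens, "Bogus")
  saveRDS(ck, f)
  expect_error(loadCheckpoint(f), class = "glycanCheckpointError")
})
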