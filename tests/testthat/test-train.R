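smallCorpus <- function() generateCorpus(toyGrammar(), 60L, seed = 23L)$glycan

test_that("a zero learning rate leaves parameters untouched", {
  m <- pretrain(smallCorpus(), modelConfig("ss", seed = 2L),
                trainConfig(lr = 0, maxEpochs = 1L, seed = 2L, warmup = 0L,
                            refitFull = FALSE))
  fresh <- initGlycanLM(buildVocab(smallCorpus()), modelConfig("ss", seed = 2L))
  expect_equal(m@params, fresh@params, tolerance = 1e-12)
})

test_that("identical seeds give identical loss curves and parameters", {
  run <- function() pretrain(smallCorpus(), modelConfig("ss", seed = 5L),
                             trainConfig(lr = 2e-3, maxEpochs = 3L, seed = 5L,
                                         refitFull = FALSE))
  m1 <- run(); m2 <- run()
  expect_identical(m1@log, m2@log)
  expect_identical(m1@params, m2@params)
  m3 <- pretrain(smallCorpus(), modelConfig("ss", seed = 5L),
                 trainConfig(lr = 2e-3, maxEpochs = 3L, seed = 6L,
                             refitFull = FALSE))
  expect_false(identical(m1@log$trainLoss, m3@log$trainLoss))
})

test_that("training reduces loss and the log tracks both splits", {
  m <- pretrain(generateCorpus(toyGrammar(), 300L, seed = 23L)$glycan,
                modelConfig("ss", seed = 4L),
                toyTrainConfig(maxEpochs = 10L, seed = 4L, warmup = 50L))
  expect_named(m@log, c("epoch", "trainLoss", "valLoss", "valNodeAcc", "valEdgeAcc"))
  expect_lt(min(m@log$valLoss), m@log$valLoss[1L])
  expect_gt(m@meta$selectedEpoch, 0L)
  expect_false(m@meta$refit)
})

test_that("refitting on the full corpus reuses the selected epoch count", {
  m <- pretrain(smallCorpus(), modelConfig("ss", seed = 4L),
                trainConfig(lr = 2e-3, maxEpochs = 3L, seed = 4L,
                            refitFull = TRUE))
  expect_true(m@meta$refit)
  expect_equal(nrow(m@log), 3L)
})

test_that("ablation modes train with the stated single-modality ratios", {
  m <- pretrain(smallCorpus(), modelConfig("ss", seed = 6L),
                toyTrainConfig(maxEpochs = 2L, seed = 6L), mode = "node_only")
  expect_equal(m@meta$ratios, c(0.70, 0))
  # the edge head receives no gradient: it stays at its zero initialization
  expect_true(all(m@params$Whe == 0))
  m2 <- pretrain(smallCorpus(), modelConfig("ss", seed = 6L),
                 toyTrainConfig(maxEpochs = 2L, seed = 6L), mode = "edge_only")
  expect_equal(m2@meta$ratios, c(0, 0.70))
  expect_true(all(m2@params$Whn == 0))
  expect_false(all(m2@params$Whe == 0))
})

test_that("attention summary is a 3x3 row-stochastic type matrix", {
  m <- tinyModel()
  sample6 <- generateCorpus(toyGrammar(), 6L, seed = 26L)$glycan
  A <- attentionSummary(m, sample6)
  expect_equal(dim(A), c(3L, 3L))
  expect_equal(rowSums(A), c(node = 1, edge = 1, graph = 1), tolerance = 1e-5)

  # uniform-attention stub (zeroed queries): each block entry equals the
  # average share of tokens of the column type
  mu <- m
  for (l in seq_along(mu@params$layers)) {
    mu@params$layers[[l]]$Wq[] <- 0
    mu@params$layers[[l]]$bq[] <- 0
  }
  one <- sample6[1L]
  tg <- encodeGlycan(parseIUPAC(one), m@vocab)
  Au <- attentionSummary(mu, one)
  tot <- length(tg@contentId)
  expected <- c(tg@nNodes, tg@nEdges, 1L) / tot
  for (t in 1:3) expect_equal(unname(Au[t, ]), expected, tolerance = 1e-9)
})

test_that("held-out MLM evaluation is deterministic and seed-sensitive", {
  m <- tinyModel()
  held <- generateCorpus(toyGrammar(), 20L, seed = 29L)$glycan
  e1 <- evaluateMLM(m, held, 0.35, 0.35, seed = 1L)
  e2 <- evaluateMLM(m, held, 0.35, 0.35, seed = 1L)
  expect_identical(e1, e2)
  # untrained model with zero heads: loss is exactly ln Vn + 0.5 ln Ve
  Vn <- length(contentTokens(m@vocab, "node"))
  Ve <- length(contentTokens(m@vocab, "edge"))
  expect_equal(unname(e1$loss), log(Vn) + 0.5 * log(Ve), tolerance = 1e-9)
})
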