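test_that("vocabularies are built with specials on the lowest ids", {
  v <- buildVocab("Gal(b1-3)GalNAc")
  expect_true(all(c("Gal", "GalNAc") %in% contentTokens(v, "node")))
  expect_true("b1-3" %in% contentTokens(v, "edge"))
  expect_equal(vocabSize(v, "node"), 2L + 4L)
  expect_true(all(tokenId(v, c("Gal", "GalNAc"), "node") >= 4L))
  expect_equal(unname(tokenId(v, "Xyl", "node")), 2L)       # UNK
  expect_equal(tokenLabel(v, 0:3, "node"),
               c("[PAD]", "[MASK]", "[UNK]", "[GRAPH]"))
  expect_error(buildVocab(list()), class = "glycanVocabError")
})

test_that("minCount excludes rare labels, which encode as UNK", {
  corp <- c("Gal(b1-3)GalNAc", "Gal(b1-3)GalNAc", "Xyl(b1-2)GalNAc")
  v <- buildVocab(corp, minCount = 2L)
  expect_false("Xyl" %in% contentTokens(v, "node"))
  expect_false("b1-2" %in% contentTokens(v, "edge"))
  tg <- encodeGlycan(parseIUPAC("Xyl(b1-2)GalNAc"), v)
  expect_equal(tg@contentId[2L], 2L)                         # UNK node
  expect_equal(tg@contentId[4L], 2L)                         # UNK edge
})

test_that("toy-grammar vocabulary has the grammar's alphabet sizes", {
  corp <- generateCorpus(toyGrammar(), 500L, seed = 2L)
  v <- buildVocab(corp$glycan)
  expect_equal(vocabSize(v, "node"), 10L + 4L)
  expect_equal(vocabSize(v, "edge"), 8L + 4L)
})

test_that("vocabulary persistence is bit-identical", {
  v <- buildVocab(generateCorpus(toyGrammar(), 100L, seed = 4L)$glycan)
  np <- withr::local_tempfile(); ep <- withr::local_tempfile()
  saveVocab(v, np, ep)
  v2 <- loadVocab(np, ep)
  expect_identical(contentTokens(v, "node"), contentTokens(v2, "node"))
  expect_identical(contentTokens(v, "edge"), contentTokens(v2, "edge"))
  expect_error(loadVocab(ep, np), class = "glycanVocabError")  # swapped spaces
})

test_that("encoding follows the fixed token ordering with endpoints", {
  v <- buildVocab("Gal(b1-3)GalNAc")
  tg <- encodeGlycan(parseIUPAC("Gal(b1-3)GalNAc"), v)
  expect_equal(length(tg@contentId), 4L)                     # [Graph] 2 nodes 1 edge
  expect_equal(tg@type, c(0L, 1L, 1L, 2L))
  expect_equal(tg@u, c(-1L, 0L, 1L, 0L))
  expect_equal(tg@v, c(-1L, 0L, 1L, 1L))                     # edge child 0 -> parent 1
  expect_equal(decodeTokens(tg, v), c("[GRAPH]", "Gal", "GalNAc", "b1-3"))

  single <- encodeGlycan(parseIUPAC("Man"), buildVocab("Man"))
  expect_equal(length(single@contentId), 2L)
  expect_length(single@terminalEdge, 0L)
})

test_that("terminal flags mark exactly the leaf-incident linkages", {
  v <- buildVocab("Gal(b1-3)Gal(b1-4)Gal")
  chain3 <- encodeGlycan(parseIUPAC("Gal(b1-3)Gal(b1-4)Gal"), v)
  expect_equal(chain3@terminalEdge, c(TRUE, FALSE))          # only leaf edge
  two <- encodeGlycan(parseIUPAC("Gal(b1-3)Gal"), v)
  expect_equal(two@terminalEdge, TRUE)
  branched <- encodeGlycan(
    parseIUPAC("Gal(b1-3)[Gal(b1-4)Gal(b1-6)]Gal(b1-3)Gal"),
    buildVocab("Gal(b1-3)[Gal(b1-4)Gal(b1-6)]Gal(b1-3)Gal"))
  # leaves: the two non-root degree-1 ends
  expect_equal(sum(branched@terminalEdge), 2L)
})

test_that("decoding recovers labels for in-vocabulary corpora", {
  corp <- generateCorpus(toyGrammar(), 50L, seed = 6L)
  v <- buildVocab(corp$glycan)
  for (s in corp$glycan[1:10]) {
    g <- parseIUPAC(s)
    tg <- encodeGlycan(g, v)
    expect_equal(decodeTokens(tg, v)[2:(1 + nNodes(g))], nodeLabels(g))
    expect_false(any(tg@contentId[-1L] == 2L))               # no UNK
  }
})

test_that("encoding is injective across distinct structures", {
  corp <- unique(generateCorpus(toyGrammar(), 200L, seed = 8L)$glycan)
  v <- buildVocab(corp)
  keys <- vapply(corp, function(s) {
    tg <- encodeGlycan(parseIUPAC(s), v)
    paste(c(tg@contentId, tg@u, tg@v), collapse = ",")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})
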