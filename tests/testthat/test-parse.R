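test_that("worked examples parse to the expected trees", {
  g <- parseIUPAC("Gal(b1-3)GalNAc")
  expect_equal(nNodes(g), 2L)
  expect_equal(nEdges(g), 1L)
  expect_equal(sort(nodeLabels(g)), c("Gal", "GalNAc"))
  expect_equal(edgeLabels(g), "b1-3")
  expect_equal(nodeLabels(g)[rootIndex(g) + 1L], "GalNAc")
  et <- edgeTable(g)
  expect_equal(nodeLabels(g)[et$child + 1L], "Gal")   # child -> parent triple
  expect_equal(nodeLabels(g)[et$parent + 1L], "GalNAc")

  g1 <- parseIUPAC("GalNAc")
  expect_equal(nNodes(g1), 1L)
  expect_equal(nEdges(g1), 0L)
  expect_equal(nodeLabels(g1)[rootIndex(g1) + 1L], "GalNAc")

  # branched pentasaccharide: the b1-4 Man carries both arm Mans
  g5 <- parseIUPAC("Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc")
  expect_equal(nNodes(g5), 5L)
  expect_equal(nEdges(g5), 4L)
  et <- edgeTable(g5)
  core <- which(nodeLabels(g5) == "Man" &
                  tabulate(et$parent + 1L, nNodes(g5)) == 2L) - 1L
  expect_length(core, 1L)
  arms <- sort(et$linkage[et$parent == core])
  expect_equal(arms, c("a1-3", "a1-6"))
  expect_true(core %in% et$child)                      # core Man has a parent
  expect_equal(nodeLabels(g5)[rootIndex(g5) + 1L], "GlcNAc")
  # node indices follow textual order, 0-based
  expect_equal(nodeLabels(g5), c("Man", "Man", "Man", "GlcNAc", "GlcNAc"))
  expect_equal(rootIndex(g5), 4L)
})

test_that("parse errors carry offsets and ambiguity has its own class", {
  expect_error(parseIUPAC("Gal(b1-3"), class = "glycanParseError")
  expect_error(parseIUPAC("Gal(b1-3"), "offset 4")
  expect_error(parseIUPAC("Galb1-3)Gal"), class = "glycanParseError")
  expect_error(parseIUPAC("Man(a1-3)[Man(a1-6)Man"), class = "glycanParseError")
  expect_error(parseIUPAC("Gal()GalNAc"), class = "glycanParseError")
  expect_error(parseIUPAC("Gal(b1-3)"), class = "glycanParseError")
  expect_error(parseIUPAC("(b1-3)Gal"), class = "glycanParseError")
  expect_error(parseIUPAC(""), class = "glycanParseError")
  expect_error(parseIUPAC("NeuNAc(a2-?)Gal"), class = "glycanAmbiguityError")
  expect_error(parseIUPAC("NeuNAc(a2-3/6)Gal"), class = "glycanAmbiguityError")
})

test_that("modified residues stay verbatim single tokens", {
  g <- parseIUPAC("GalNAc3,4,6Ac3")
  expect_equal(nodeLabels(g), "GalNAc3,4,6Ac3")
  g2 <- parseIUPAC("Gal(b1-3)GalNAc3,4,6Ac3")
  expect_equal(sort(nodeLabels(g2)), c("Gal", "GalNAc3,4,6Ac3"))
})

test_that("serialization round-trips to an isomorphic tree on generated corpora", {
  corp <- generateCorpus(toyGrammar(), 200L, seed = 21L)
  for (s in corp$glycan) {
    g <- parseIUPAC(s)
    g2 <- parseIUPAC(serializeIUPAC(g))
    expect_true(isIsomorphic(g, g2))
  }
  # serialization is canonical: a second round trip is a fixed point
  s1 <- serializeIUPAC(parseIUPAC(corp$glycan[5L]))
  expect_identical(serializeIUPAC(parseIUPAC(s1)), s1)
  expect_identical(serializeIUPAC(parseIUPAC("Gal(b1-3)GalNAc")), "Gal(b1-3)GalNAc")
})

test_that("tree invariants hold for every parsed glycan", {
  corp <- generateCorpus(toyGrammar(), 100L, seed = 33L)
  for (s in corp$glycan[1:50]) {
    g <- parseIUPAC(s)
    expect_equal(nEdges(g), nNodes(g) - 1L)
    expect_false(rootIndex(g) %in% edgeTable(g)$child)
    expect_true(validObject(g))
  }
})

test_that("label multisets agree with flat string scanning on real glycans", {
  real <- realGlycanFixtures()
  expect_gte(nrow(real), 20L)
  for (s in real$glycan) {
    g <- parseIUPAC(s)
    oracle <- stringTokenOracle(s)
    expect_equal(sort(nodeLabels(g)), oracle$nodes, info = s)
    expect_equal(sort(edgeLabels(g)), oracle$edges, info = s)
  }
})

test_that("serialize rejects structures that are not trees", {
  g <- parseIUPAC("Gal(b1-3)GalNAc")
  bad <- g
  bad@parentIndex <- c(bad@parentIndex, 0L)  # second edge -> not a tree
  bad@childIndex <- c(bad@childIndex, 1L)
  bad@edgeLabels <- c(bad@edgeLabels, "b1-4")
  expect_error(serializeIUPAC(bad))
})
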