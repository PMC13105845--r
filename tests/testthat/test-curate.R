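test_that("wildcard entries are rejected, resolved entries pass through", {
  rep <- curateCorpus(c("NeuNAc(a2-?)Gal", "Gal(b1-3)GalNAc", "NeuNAc(a2-3/6/?)Gal"))
  expect_equal(rep$kept, "Gal(b1-3)GalNAc")
  expect_setequal(rep$rejected$input, c("NeuNAc(a2-?)Gal", "NeuNAc(a2-3/6/?)Gal"))
  expect_match(rep$rejected$reason[1L], "\\?")
  expect_length(rep$expansions, 0L)
})

test_that("linkage alternatives expand to the cartesian product", {
  rep <- curateCorpus("NeuNAc(a2-3/6)Gal")
  expect_equal(rep$expansions[["NeuNAc(a2-3/6)Gal"]],
               c("NeuNAc(a2-3)Gal", "NeuNAc(a2-6)Gal"))
  # two ambiguous linkages multiply: 2 x 3 = 6 variants
  rep2 <- curateCorpus("Gal(b1-3/4)GlcNAc(b1-2/3/6)Man")
  v <- rep2$expansions[[1L]]
  expect_length(v, 6L)
  expect_true(all(grepl("^Gal\\(b1-[34]\\)GlcNAc\\(b1-[236]\\)Man$", v)))
  expect_false(any(grepl("/", v, fixed = TRUE)))
  # expanded variants parse cleanly
  for (s in v) expect_s4_class(parseIUPAC(s), "GlycanGraph")
})

test_that("expansion count law: k linkages with a_i alternatives give prod(a_i)", {
  set.seed(99)
  monos <- c("Gal", "Man", "GlcNAc", "Fuc", "NeuNAc")
  for (rep_i in 1:20) {
    k <- sample(1:3, 1)
    alts <- sample(2:3, k, replace = TRUE)
    links <- vapply(alts, function(a)
      paste0("b1-", paste(sample(2:9, a), collapse = "/")), character(1))
    s <- paste0(paste0(sample(monos, k, replace = TRUE), "(", links, ")",
                       collapse = ""), "Glc")
    out <- curateCorpus(s, maxVariants = 100L)
    expect_length(out$expansions[[s]], prod(alts))
  }
})

test_that("every input lands in exactly one report section", {
  ins <- c("Gal(b1-3)GalNAc", "NeuNAc(a2-?)Gal", "NeuNAc(a2-3/6)Gal", "Man")
  rep <- curateCorpus(ins)
  all3 <- c(rep$kept, rep$rejected$input, names(rep$expansions))
  expect_setequal(all3, ins)
  expect_equal(length(all3), length(ins))
})

test_that("slash outside a linkage is a validation error, not an expansion", {
  rep <- curateCorpus("Gal/Man(b1-3)Glc")
  expect_equal(nrow(rep$rejected), 1L)
  expect_match(rep$rejected$reason, "outside a linkage")
})

test_that("variant cap truncates with a warning", {
  s <- "Gal(b1-2/3/4/6)Man(a1-2/3/4/6)Glc(b1-2/3/4/6)Xyl"   # 64 variants
  expect_warning(rep <- curateCorpus(s, maxVariants = 16L), "cap")
  expect_lte(length(rep$expansions[[s]]), 16L)
})

test_that("corpus files read and write with comments and labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header comment", "Gal(b1-3)GalNAc\tO", "", "Man"), f)
  rec <- readCorpus(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$glycan, c("Gal(b1-3)GalNAc", "Man"))
  expect_equal(rec$label, c("O", NA))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeCorpus(rec$glycan, f2, labels = c("O", "x"))
  expect_equal(readCorpus(f2)$label, c("O", "x"))

  writeLines(character(0), f2)
  expect_equal(nrow(readCorpus(f2)), 0L)
  expect_error(readCorpus(file.path(tempdir(), "no-such-file.tsv")),
               class = "glycanIOError")
})

test_that("curation reports serialize to the three-section format", {
  rep <- curateCorpus(c("Gal(b1-3)GalNAc", "NeuNAc(a2-?)Gal", "NeuNAc(a2-3/6)Gal"))
  f <- withr::local_tempfile(fileext = ".txt")
  writeCurationReport(rep, f)
  lines <- readLines(f)
  expect_true(all(c("#kept", "#rejected", "#expanded") %in% lines))
  expect_true("NeuNAc(a2-3/6)Gal\tNeuNAc(a2-3)Gal" %in% lines)
})
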