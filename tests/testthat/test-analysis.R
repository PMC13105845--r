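sepFeatures <- function(n = 60L, d = 8L, seed = 61L) {
  # two well-separated gaussian clouds: linearly separable by construction
  withr::with_seed(seed, {
    y <- rep(c("neg", "pos"), each = n / 2L)
    X <- matrix(rnorm(n * d, sd = 0.3), n, d)
    X[y == "pos", 1L] <- X[y == "pos", 1L] + 5
    list(X = X, y = y)
  })
}

fixedSplit <- function(n) {
  idx <- seq_len(n)
  list(train = idx[idx %% 5L <= 2L], val = idx[idx %% 5L == 3L],
       test = idx[idx %% 5L == 4L])
}

test_that("embedding a corpus is deterministic and batch-size independent", {
  m <- tinyModel()
  corp <- generateCorpus(toyGrammar(), 12L, seed = 63L)$glycan
  E1 <- embedCorpus(m, corp, batchSize = 1L)
  E8 <- embedCorpus(m, corp, batchSize = 8L)
  expect_equal(E1, E8, tolerance = 1e-5)
  expect_identical(embedCorpus(m, corp), embedCorpus(m, corp))
  expect_equal(nrow(E1), 12L)
  expect_equal(ncol(E1), m@config$d)
  expect_equal(nrow(attr(E1, "skipped")), 0L)
})

test_that("over-capacity glycans are skipped with a reason", {
  m <- tinyModel(dP = 4L)
  long <- paste0(paste(rep("Gal(b1-3)", 6L), collapse = ""), "Gal")
  E <- embedCorpus(m, c("Gal(b1-3)GalNAc", long))
  expect_equal(nrow(E), 1L)
  expect_equal(attr(E, "skipped")$input, long)
})

test_that("the SVM harness is perfect on separable features", {
  sf <- sepFeatures()
  res <- benchmarkClassify(sf$X, sf$y, fixedSplit(60L), taskType = "binary",
                           classifier = "svm", nSeeds = 2L, baseSeed = 3L)
  expect_equal(res$mean[res$metric == "accuracy"], 1)
  expect_equal(res$mean[res$metric == "auprc"], 1)
  expect_equal(res$mean[res$metric == "macro_f1"], 1)
  expect_equal(res$sd[res$metric == "accuracy"], 0)
})

test_that("the harness is reproducible and the gbm path works", {
  sf <- sepFeatures(n = 40L)
  sp <- fixedSplit(40L)
  r1 <- benchmarkClassify(sf$X, sf$y, sp, "binary", "gbm",
                          nSeeds = 1L, nIter = 2L, baseSeed = 5L)
  r2 <- benchmarkClassify(sf$X, sf$y, sp, "binary", "gbm",
                          nSeeds = 1L, nIter = 2L, baseSeed = 5L)
  expect_equal(r1$mean, r2$mean, tolerance = 1e-12)
  expect_gte(r1$mean[r1$metric == "accuracy"], 0.8)
})

test_that("constant features predict at the majority-class share", {
  n <- 50L
  y <- rep(c("a", "b"), c(30L, 20L))
  X <- matrix(1, n, 3L) + matrix(rnorm(n * 3L, sd = 1e-6), n)   # effectively constant
  res <- suppressWarnings(
    benchmarkClassify(X, y, fixedSplit(n), "multiclass", "svm",
                      nSeeds = 1L, nIter = 2L, baseSeed = 7L))
  testShare <- max(table(y[fixedSplit(n)$test])) / length(fixedSplit(n)$test)
  expect_lte(abs(res$mean[res$metric == "accuracy"] - testShare), 0.45)
})

test_that("shuffled labels score near chance macro-F1", {
  withr::with_seed(91, {
    n <- 90L
    X <- matrix(rnorm(n * 6L), n)
    y <- sample(rep(c("a", "b", "c"), each = n / 3L))
  })
  res <- benchmarkClassify(X, y, fixedSplit(n), "multiclass", "svm",
                           nSeeds = 2L, nIter = 3L, baseSeed = 11L)
  expect_lt(res$mean[res$metric == "macro_f1"], 0.65)       # 1/3 + noise
})

test_that("a class missing from the training data is a named error", {
  sf <- sepFeatures(n = 20L)
  sp <- list(train = 1:8, val = 9:10, test = 11:20)         # pos only in test
  expect_error(
    benchmarkClassify(sf$X, sf$y, sp, "binary", "svm", nSeeds = 1L),
    "pos")
  expect_error(
    benchmarkClassify(sf$X, sf$y, list(train = 1:10, val = 10:12, test = 13:20),
                      "binary", "svm"),
    class = "glycanAnalysisError")                          # not a partition
})

test_that("trained-model embeddings carry family signal well above chance", {
  m <- toyBalancedModel()
  held <- toyHeldOut()
  E <- embedCorpus(m, held$glycan)
  y <- factor(held$label)
  tr <- seq_len(200L); te <- 201:300
  fit <- e1071::svm(E[tr, ], y[tr], kernel = "linear", cost = 1)
  acc <- mean(as.character(stats::predict(fit, E[te, ])) == as.character(y[te]))
  expect_gt(acc, 3 / length(levels(y)))         # >> 1/10 chance
})

test_that("PCA + k-means utility returns seeded clusters", {
  sf <- sepFeatures(n = 40L, d = 12L)
  pk <- pcaKmeans(sf$X, nComp = 5L, k = 2L, seed = 9L)
  pk2 <- pcaKmeans(sf$X, nComp = 5L, k = 2L, seed = 9L)
  expect_identical(pk$cluster, pk2$cluster)
  expect_equal(ncol(pk$scores), 5L)
  # the two separable clouds land in different clusters
  expect_equal(length(unique(pk$cluster[sf$y == "pos"])), 1L)
  agree <- mean(pk$cluster[sf$y == "pos"] != pk$cluster[sf$y == "neg"])
  expect_equal(agree, 1)
})

test_that("matrices round-trip through the TSV writers", {
  E <- matrix(rnorm(12L), 4L, dimnames = list(paste0("g", 1:4), paste0("d", 1:3)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTSV(E, f)
  back <- as.matrix(read.table(f, sep = "\t", header = TRUE, row.names = 1L))
  expect_equal(back, E, tolerance = 1e-12)
})
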