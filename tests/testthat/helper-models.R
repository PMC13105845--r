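# Shared fixtures: the toy study corpus and trained models are expensive, so
# they are built once per session and cached for every test file that needs
# them. Training hyperparameters for the toy experiments (AdamW 4e-3 with
# 150-update warmup on the d = 64 model) are fixed here, once.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

toyStudyCorpus <- function() {
  cached("corpus2000", function() generateCorpus(toyGrammar(), 2000L, seed = 7L))
}

toyHeldOut <- function() {
  cached("heldout", function() generateCorpus(toyGrammar(), 300L, seed = 1234L))
}

toyTrainConfig <- function(maxEpochs = 50L, seed = 7L, warmup = 150L, ...) {
  trainConfig(lr = 4e-3, warmup = warmup, maxEpochs = maxEpochs, seed = seed,
              refitFull = FALSE, ...)
}

# The balanced ss-scale model of the learnability experiment (35%/35%
# masking, 2000 toy glycans, <= 50 epochs).
toyBalancedModel <- function() {
  cached("balanced_ss", function() {
    pretrain(toyStudyCorpus()$glycan, modelConfig("ss", seed = 7L),
             toyTrainConfig(), mode = "balanced")
  })
}

# Smaller matched-condition trio for the masking-mode ablation.
ablationCorpus <- function() {
  cached("corpus600", function() generateCorpus(toyGrammar(), 600L, seed = 11L))
}

ablationModel <- function(mode) {
  cached(paste0("abl_", mode), function() {
    pretrain(ablationCorpus()$glycan, modelConfig("ss", seed = 11L),
             toyTrainConfig(maxEpochs = 20L, seed = 11L), mode = mode)
  })
}

# A tiny untrained model over a tiny vocabulary, for contract tests.
tinyModel <- function(seed = 3L, dropout = 0, dP = 64L) {
  corp <- generateCorpus(toyGrammar(), 30L, seed = 5L)
  vocab <- buildVocab(corp$glycan)
  initGlycanLM(vocab, modelConfig("ss", dP = dP, maxNodes = dP,
                                  dropout = dropout, seed = seed))
}
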