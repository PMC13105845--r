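# Checkpointing: one archive holding config, vocab, seed, and parameters.

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive with the configuration, the full
#' vocabulary, the ORF seed, the parameters, the training log and vocabulary
#' fingerprints. Loading rebuilds the ORF bank from the stored seed and
#' verifies the vocabulary hashes, refusing a checkpoint whose vocab does
#' not match its stored fingerprint.
#'
#' @param model a \linkS4class{GlycanLM}.
#' @param path file path.
#' @return \code{loadCheckpoint} returns the \linkS4class{GlycanLM}.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "GlycanLM"))
  saveRDS(list(format = "glycanMLM-checkpoint-v1",
               config = unclass(model@config),
               nodeTokens = model@vocab@nodeTokens,
               edgeTokens = model@vocab@edgeTokens,
               params = model@params, log = model@log, meta = model@meta),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "glycanMLM-checkpoint-v1"))
    glycanStop("glycanCheckpointError", "\"%s\" is not a glycanMLM checkpoint", path)
  vocab <- new("Vocabulary", nodeTokens = ck$nodeTokens, edgeTokens = ck$edgeTokens)
  if (!identical(ck$meta$nodeVocabHash, stringHash(vocab@nodeTokens)) ||
      !identical(ck$meta$edgeVocabHash, stringHash(vocab@edgeTokens)))
    glycanStop("glycanCheckpointError",
               "checkpoint vocabulary does not match its fingerprint")
  cfg <- ck$config
  new("GlycanLM", config = cfg, vocab = vocab, bank = orfBank(cfg$dP, cfg$seed),
      params = ck$params, log = ck$log, meta = ck$meta)
}
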