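# Small internal helpers: seeded RNG scoping, derived seeds, string hashing.

# Evaluate expr under a given seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic derived seed, kept inside 32-bit integer range.
deriveSeed <- function(base, ...) {
  ks <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# Cheap deterministic string hash (FNV-style) for vocab fingerprints.
stringHash <- function(strings) {
  h <- 216613626
  for (cp in utf8ToInt(paste(strings, collapse = "\x1f"))) {
    h <- (h * 131 + cp) %% 2147483647
  }
  as.integer(h)
}

addB <- function(M, b) M + rep(b, each = nrow(M))

rowMax <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]

softmaxRows <- function(S) {
  E <- exp(S - rowMax(S))
  E / rowSums(E)
}
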