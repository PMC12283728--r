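# Run `expr` under a local, fully specified RNG state without disturbing the
# caller's stream. All stochastic components of the package draw through this.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Deterministic sub-seed derivation so that independent pipeline stages use
# independent, reproducible streams (kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  acc <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
         else as.numeric(p)
    acc <- (acc * 69069 + v + 1) %% 2147483629
  }
  as.integer(acc)
}
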