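# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps every generator a pure function of (inputs, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic 31-bit seed from a master seed and a stage name, so adding
#' or reordering pipeline stages never shifts a sibling stage's random
#' stream. Polynomial string hash modulo the Mersenne prime 2^31 - 1 (R
#' seeds are 32-bit signed integers).
#'
#' @param master Master integer seed.
#' @param stage Stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 1) + 1)
}

fmt_kb <- function(bp) sprintf("%.1f kb", bp / 1000)
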