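`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a character label to a new seed in
#' `[1, 2^31 - 2]`. Used throughout the package so that a single master seed
#' reproducibly spawns independent seeds for every stage, event and simulation
#' run.
#'
#' @param seed Integer master seed.
#' @param label Character label identifying the consumer (e.g. `"run3"`).
#' @return A single integer seed.
#' @examples
#' derive_seed(1L, "generate/guizhou")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label),
            length(label) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps products < 2^53
  h <- as.double(seed) %% m
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  # avoid 0 which set.seed accepts but we reserve as "unset"
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Zipf (power-law) probabilities over ranks 1..n with exponent s.
zipf_probs <- function(n, s = 1.1) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}
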