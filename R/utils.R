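#' @importFrom stats rnorm runif rlnorm rnbinom plnorm qlnorm quantile sd
#'   median pnorm qnorm setNames rbinom coef vcov predict
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom tools md5sum
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package randomness never leaks into (or
# depends on) the global stream.
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: fold integer and character keys into a
# root seed so stages (and features within stages) draw from independent,
# reproducible streams. Result always a positive 32-bit integer.
subSeed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (part in list(...)) {
    if (is.character(part)) {
      part <- sum(utf8ToInt(part) * seq_along(utf8ToInt(part)))
    }
    for (v in as.double(part)) {
      h <- (h * 69069 + v + 1) %% 2147483647
    }
  }
  as.integer(h) + 1L
}

# xor-derived per-resample seed, kept in 32-bit range
xorSeed <- function(seed, i) {
  s <- bitwXor(as.integer(seed) %% 2147483647L, as.integer(i))
  if (s <= 0L) s <- abs(s) + 1L
  s
}

geomMean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
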