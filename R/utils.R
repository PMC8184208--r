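# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed and a stage name.
# Keeps every stage's randomness independent while flowing from one seed.
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((abs(seed) * 7919 + h) %% 2147483629)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# beta <-> M (log2 logit) transforms; base-2 throughout.
logit2 <- function(beta) log2(beta / (1 - beta))

expit2 <- function(m) 1 / (1 + 2^(-m))

# M-scale offset that produces (to first order) a given beta-scale shift at
# baseline beta b0: dBeta/dM = ln(2) * b0 * (1 - b0).
mOffsetForDeltaBeta <- function(deltaBeta, b0) {
  deltaBeta / (log(2) * b0 * (1 - b0))
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
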