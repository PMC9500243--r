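# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards (base-only equivalent of withr::with_seed).
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-item substream seed, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 100003 + as.double(index) * 7919) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable binary cross-entropy with logits: max(x,0) - x*t + log1p(exp(-|x|))
bce_logits <- function(logits, targets) {
  pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pd_log <- function(fmt, ..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}
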