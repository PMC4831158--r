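# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. A NULL seed uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed, stable across platforms and kept
# inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + 7919 * k) %% 2147483647
}

# permutation-test p-value: (1 + hits) / (n + 1), never 0
perm_p <- function(hits, n_perm) (1 + hits) / (n_perm + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
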