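## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic sub-stream seed for unit (i, j) of a master seed, kept
## within the 32-bit integer range so subsets are independently reproducible.
derive_seed <- function(master, i, j = 0L) {
  (as.numeric(master) * 48271 + i * 104729 + j * 7919) %% 2147483629
}
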