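# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Spawn `n` reproducible child seeds (< 2^31) from one master seed.
child_seeds <- function(master, n) {
  with_local_seed(as.integer(master),
                  sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
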