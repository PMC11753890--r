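# internal numeric helpers shared across modules

sigmoid <- function(x) 1 / (1 + exp(-x))

# run f() with an isolated, seeded RNG stream; the caller's global
# .Random.seed is untouched
.with_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  f()
}
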