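## internal helpers

## log-spaced sequence from `from` to `to` (inclusive)
logspace <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

## run `expr` with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards so simulation calls do not perturb it
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
}
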