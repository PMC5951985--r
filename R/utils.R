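# Evaluate `expr` under a locally set RNG seed (global RNG state untouched);
# with seed = NULL the current RNG stream is used.
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("`seed` must be a single integer")
  withr::with_seed(as.integer(seed), eval.parent(substitute(expr)))
}

# largest power of two strictly below x (NA if none >= 1)
largest_pow2_below <- function(x) {
  if (x <= 1) return(NA_integer_)
  p <- 1L
  while (p * 2 < x) p <- p * 2L
  p
}

offdiag_idx <- function(n) which(row(diag(n)) != col(diag(n)))

offdiag_values <- function(m) m[row(m) != col(m)]

# derive a stream of child seeds from one integer seed (all < 2^31)
child_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  run_seeded(seed, sample.int(.Machine$integer.max - 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
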