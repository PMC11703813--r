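# Run code with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds below 2^31, decorrelated across indices.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Direct-form IIR filter y = filter(b, a, x) built on stats::filter's C
# loops (signal::filter's ts bookkeeping is too slow for long waveforms).
iir_filter <- function(flt, x) {
  b <- flt$b / flt$a[1]
  a <- flt$a / flt$a[1]
  nb <- length(b)
  y <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  y <- as.numeric(y)[nb:(nb - 1 + length(x))]
  if (length(a) > 1L) {
    y <- as.numeric(stats::filter(y, -a[-1], method = "recursive"))
  }
  y
}
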