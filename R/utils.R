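## Internal helpers.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
## afterwards so generators are pure functions of (inputs, seed) with no
## hidden global state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Running minimum over a centered window of radius w (vectorized pmin).
.runMin <- function(x, w) {
  n <- length(x)
  out <- x
  for (k in seq_len(w)) {
    out <- pmin(out,
                c(x[-seq_len(k)], rep(Inf, k)),
                c(rep(Inf, k), x[seq_len(n - k)]))
  }
  out
}

## Centered moving average of odd width, edges use the shrunken window.
.smooth <- function(x, width) {
  if (width <= 1) return(x)
  if (width %% 2 == 0) width <- width + 1
  n <- length(x)
  cs <- cumsum(c(0, x))
  r <- (width - 1) / 2
  lo <- pmax(seq_len(n) - r, 1)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## Draw from a truncated normal by resampling (simple, adequate for the mild
## truncations used by the subject generator).
.rnormTrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0
  while (length(bad) && tries < 100) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1
  }
  pmin(pmax(x, lo), hi)
}
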