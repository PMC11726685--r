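#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derived sub-seed kept inside 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131L + k * 10007) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Separable Gaussian smoothing of a 3D array, kernel renormalized at the
## edges so a constant field is preserved exactly.
smooth3d <- function(arr, sigma = 1.5) {
  if (sigma <= 0) return(arr)
  rad <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-rad:rad, sd = sigma)
  d <- dim(arr)
  conv1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1L, i - rad):min(n, i + rad)
      wk <- w[j - i + rad + 1L]
      out[i] <- sum(x[j] * wk) / sum(wk)
    }
    out
  }
  for (axis in 1:3) {
    arr <- apply(arr, setdiff(1:3, axis), conv1)
    ## apply() puts the worked axis first; rotate back
    arr <- aperm(arr, order(c(axis, setdiff(1:3, axis))))
  }
  arr
}
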