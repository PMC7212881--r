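## Small internal helpers shared across modules.

## Round half away from zero, as used for the printed report percentages.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Stable hash of an R object (used to fingerprint texture configurations so
## models refuse feature tables extracted under a different convention).
config_hash <- function(x) {
  rlang::hash(x)
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards. All randomness in the package funnels through
## this so identical seeds give identical output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "mptexture_validation_error")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Derive a stream of child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

## Smooth standard-normal random field of size rows x cols with correlation
## length `corr_len_px`, built by bilinear upsampling of a coarse iid grid.
smooth_field <- function(rows, cols, corr_len_px) {
  corr_len_px <- max(corr_len_px, 1)
  m <- ceiling(rows / corr_len_px) + 2L
  n <- ceiling(cols / corr_len_px) + 2L
  g <- matrix(rnorm(m * n), m, n)
  ri <- seq(1, m, length.out = rows)
  ci <- seq(1, n, length.out = cols)
  r0 <- pmin(floor(ri), m - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), n - 1L); fc <- ci - c0
  a <- g[r0, c0, drop = FALSE]
  b <- g[r0 + 1L, c0, drop = FALSE]
  cc <- g[r0, c0 + 1L, drop = FALSE]
  d <- g[r0 + 1L, c0 + 1L, drop = FALSE]
  out <- a * ((1 - fr) %o% (1 - fc)) + b * (fr %o% (1 - fc)) +
    cc * ((1 - fr) %o% fc) + d * (fr %o% fc)
  s <- stats::sd(out)
  if (s > 0) out <- out / s
  out
}
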