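# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards.  All stochastic operations in the package funnel
# through this so a single scan seed yields bit-reproducible output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# independent streams per stage ("flats", "scan", "slab:5:0", ...).  Kept
# below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587)
}

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Separable 2-D Gaussian smoothing with reflected edges; sigma in pixels,
# per axis (rows, cols).  Used for the ring-error background bias.
gauss_blur2d <- function(x, sigma_r, sigma_c = sigma_r) {
  blur1 <- function(m, sigma) {
    if (sigma <= 0) return(m)
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-r:r) / sigma)^2)
    k <- k / sum(k)
    n <- nrow(m)
    if (r >= n) { # degenerate tiny inputs: clamp padding
      idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    } else {
      idx <- c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)
    }
    mp <- m[idx, , drop = FALSE]
    out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
    matrix(out[(r + 1):(r + n), ], nrow = n)
  }
  t(blur1(t(blur1(x, sigma_r)), sigma_c))
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions
# (1-based).  Out-of-range queries return `fill`.
bilinear <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  out <- rep(fill, length(r))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]
    wr <- r[ok] - r0k; wc <- c[ok] - c0k
    i00 <- cbind(r0k, c0k); i01 <- cbind(r0k, c0k + 1)
    i10 <- cbind(r0k + 1, c0k); i11 <- cbind(r0k + 1, c0k + 1)
    out[ok] <- (1 - wr) * ((1 - wc) * m[i00] + wc * m[i01]) +
      wr * ((1 - wc) * m[i10] + wc * m[i11])
  }
  out
}
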