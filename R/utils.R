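# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_ap <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_ap("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) abort_ap("`%s` must be > 0", name)
  if (nonneg && x < 0) abort_ap("`%s` must be >= 0", name)
  invisible(x)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 for 32-bit R ints.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483629)
}

# Offsets (dy, dx) of pixels whose centre lies within `radius` pixels.
disc_offsets <- function(radius) {
  r <- max(0L, floor(radius))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# Shift a matrix by integer (dy, dx), filling exposed pixels with `fill`.
shift_int <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (abs(dy) >= nr || abs(dx) >= nc) return(out)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

# Translate a matrix by a real-valued (dy, dx) using bilinear interpolation.
# Pixels sampled outside the source are filled with `fill`.
shift_bilinear <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  ry <- seq_len(nr) - dy
  cx <- seq_len(nc) - dx
  y0 <- floor(ry); x0 <- floor(cx)
  fy <- ry - y0;  fx <- cx - x0
  idx <- function(v, n) pmin(pmax(v, 1L), n)
  ok_y <- ry >= 1 & ry <= nr
  ok_x <- cx >= 1 & cx <= nc
  a <- m[idx(y0, nr), idx(x0, nc), drop = FALSE]
  b <- m[idx(y0 + 1, nr), idx(x0, nc), drop = FALSE]
  cc <- m[idx(y0, nr), idx(x0 + 1, nc), drop = FALSE]
  d <- m[idx(y0 + 1, nr), idx(x0 + 1, nc), drop = FALSE]
  out <- a * outer(1 - fy, 1 - fx) + b * outer(fy, 1 - fx) +
    cc * outer(1 - fy, fx) + d * outer(fy, fx)
  out[!ok_y, ] <- fill
  out[, !ok_x] <- fill
  out
}

# Population standard deviation (divides by n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

running_median3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- vapply(2:(n - 1), function(i) {
    stats::median(x[(i - 1):(i + 1)])
  }, numeric(1))
  out
}
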