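# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Restores the caller's .Random.seed so generators are reproducible
# without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Orthonormal basis (e1, e2) completing unit vector n to a right-handed frame.
# For n = +z this returns the identity frame (e1 = +x, e2 = +y).
orthobasis <- function(n) {
  n <- unit(n)
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(ref - sum(ref * n) * n)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2, n = n)
}

# Rotation matrix (columns e1, e2, n): maps local frame coords to world,
# with the local +z axis along n. t(M) maps world to local.
frame_matrix <- function(n) {
  b <- orthobasis(n)
  cbind(b$e1, b$e2, b$n)
}

# Rotation about `axis` by `angle` radians (Rodrigues).
rotation_about <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Truncated normal by rejection (ranges here are always within ~3 sd,
# so rejection is cheap).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (is.finite(lower) && is.finite(upper)) {
    if (upper < lower) stop("upper < lower in truncation range")
    if (upper - lower < 1e-8) return(rep((lower + upper) / 2, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Smallest integer >= n whose prime factors are all in {2, 3, 5}
# (keeps stats::fft fast on arbitrary grids).
next_fft_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Shift array `a` by `k` voxels along dimension `dim`, zero-filling.
shift_array <- function(a, k, dim) {
  if (k == 0L) return(a)
  d <- base::dim(a)
  out <- array(0, d)
  n <- d[dim]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  idx_src <- rep(list(quote(expr = )), 3); idx_src[[dim]] <- src
  idx_dst <- rep(list(quote(expr = )), 3); idx_dst[[dim]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
  out
}

# Separable Gaussian smoothing (sigma in voxels), zero-padded borders.
gauss_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  for (dm in 1:3) {
    acc <- array(0, dim(a))
    for (k in -r:r) acc <- acc + w[k + r + 1] * shift_array(a, k, dm)
    a <- acc
  }
  a
}

# Sub-voxel peak refinement: parabolic interpolation around index i of y.
# Returns fractional index offset in [-0.5, 0.5].
parabolic_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (!is.finite(denom) || abs(denom) < 1e-12) return(0)
  off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  max(-0.5, min(0.5, off))
}

# Trilinear interpolation of 3D array `grid` at continuous 1-based index
# coordinates `pts` (n x 3). Points outside return `fill`.
interp3 <- function(grid, pts, fill = 0) {
  d <- dim(grid)
  px <- pts[, 1]; py <- pts[, 2]; pz <- pts[, 3]
  inside <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  px <- px[inside]; py <- py[inside]; pz <- pz[inside]
  i0 <- pmin(floor(px), d[1] - 1L); j0 <- pmin(floor(py), d[2] - 1L)
  k0 <- pmin(floor(pz), d[3] - 1L)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  g <- function(i, j, k) grid[cbind(i, j, k)]
  v <- g(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(i0 + 1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    g(i0, j0 + 1, k0) * (1 - fx) * fy * (1 - fz) +
    g(i0, j0, k0 + 1) * (1 - fx) * (1 - fy) * fz +
    g(i0 + 1, j0 + 1, k0) * fx * fy * (1 - fz) +
    g(i0 + 1, j0, k0 + 1) * fx * (1 - fy) * fz +
    g(i0, j0 + 1, k0 + 1) * (1 - fx) * fy * fz +
    g(i0 + 1, j0 + 1, k0 + 1) * fx * fy * fz
  out[inside] <- v
  out
}

# Centered FFT frequencies (cycles per nm) for n samples at spacing d.
fft_freqs <- function(n, d) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * d)
  k
}

`%||%` <- function(a, b) if (is.null(a)) b else a
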