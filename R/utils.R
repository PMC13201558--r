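# internal numeric helpers

# vectorized bilinear interpolation of matrix `m` sampled at grid (z, x)
# (rows = z, cols = x); query points (zq, xq) must lie inside the grid hull
.bilinear <- function(m, z, x, zq, xq) {
  nz <- length(z); nx <- length(x)
  dz <- z[2] - z[1]; dx <- x[2] - x[1]
  fi <- (zq - z[1]) / dz
  fj <- (xq - x[1]) / dx
  i0 <- pmin(pmax(floor(fi), 0), nz - 2)
  j0 <- pmin(pmax(floor(fj), 0), nx - 2)
  ti <- fi - i0
  tj <- fj - j0
  i0 <- i0 + 1L; j0 <- j0 + 1L  # 1-based
  idx <- function(i, j) (j - 1L) * nz + i
  m[idx(i0, j0)] * (1 - ti) * (1 - tj) +
    m[idx(i0 + 1L, j0)] * ti * (1 - tj) +
    m[idx(i0, j0 + 1L)] * (1 - ti) * tj +
    m[idx(i0 + 1L, j0 + 1L)] * ti * tj
}

# centered finite differences along rows (z) and columns (x) of a matrix,
# one-sided at the borders; h is the grid step (same units as the output's
# denominator)
.grad_z <- function(m, h) {
  nz <- nrow(m)
  g <- m
  if (nz >= 3) g[2:(nz - 1), ] <- (m[3:nz, ] - m[1:(nz - 2), ]) / (2 * h)
  g[1, ] <- (m[2, ] - m[1, ]) / h
  g[nz, ] <- (m[nz, ] - m[nz - 1, ]) / h
  g
}

.grad_x <- function(m, h) t(.grad_z(t(m), h))

# centered moving average with window w (odd), shrinking symmetrically at the
# ends so the output has the same length; exact passthrough for w <= 1
.moving_average <- function(v, w) {
  n <- length(v)
  if (w <= 1 || n < 3) return(v)
  w <- min(w, if (n %% 2 == 1) n else n - 1)
  half <- (w - 1) %/% 2
  cs <- cumsum(c(0, v))
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(half, i - 1, n - i)
    out[i] <- (cs[i + k + 1] - cs[i - k]) / (2 * k + 1)
  }
  out
}

# longest run of TRUE in a logical vector; returns integer indices (empty if none)
.main_run <- function(flag) {
  r <- rle(flag)
  if (!any(r$values)) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  seq.int(starts[best], ends[best])
}
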