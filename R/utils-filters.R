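# Internal separable filters. All borders use truncation: the kernel is
# clipped to the in-image support and renormalized, so local means/blurs are
# averages over the in-image part of the window only.

# Band matrix applying a 1D Gaussian (sd `sigma`, radius 3*sigma) along a
# dimension of length n, rows renormalized at the borders.
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  A <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    A[cbind(idx[ok], j[ok])] <- k[o + r + 1]
  }
  A / rowSums(A)
}

# Band matrix of truncated window means. For even windows the neighborhood of
# pixel i spans i - floor((w-1)/2) .. i + floor(w/2).
box_band <- function(n, window) {
  r1 <- (window - 1L) %/% 2L
  r2 <- window %/% 2L
  A <- matrix(0, n, n)
  for (o in -r1:r2) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    A[cbind(idx[ok], j[ok])] <- 1
  }
  A / rowSums(A)
}

blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Ay <- gauss_band(nrow(m), sigma)
  Ax <- gauss_band(ncol(m), sigma)
  Ay %*% m %*% t(Ax)
}

local_mean <- function(m, window) {
  Ay <- box_band(nrow(m), window)
  Ax <- box_band(ncol(m), window)
  Ay %*% m %*% t(Ax)
}

# Gaussian blur along the time (3rd) dimension of an H x W x T array.
blur_time <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  At <- gauss_band(d[3], sigma)
  m <- matrix(a, nrow = d[1] * d[2], ncol = d[3])
  array(m %*% t(At), dim = d)
}

# Median of 9 via the classic 3x3 sorting-network decomposition:
# median9 = med3(max of column minima, med3 of column medians, min of maxima).
med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

# 3x3 median filter with edge replication.
median3x3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- m[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  sh <- function(dy, dx) p[seq_len(H) + 1 + dy, seq_len(W) + 1 + dx]
  lo <- vector("list", 3); mi <- vector("list", 3); hi <- vector("list", 3)
  for (dx in -1:1) {
    a <- sh(-1, dx); b <- sh(0, dx); c <- sh(1, dx)
    lo[[dx + 2]] <- pmin(a, b, c)
    mi[[dx + 2]] <- med3(a, b, c)
    hi[[dx + 2]] <- pmax(a, b, c)
  }
  med3(pmax(lo[[1]], lo[[2]], lo[[3]]),
       med3(mi[[1]], mi[[2]], mi[[3]]),
       pmin(hi[[1]], hi[[2]], hi[[3]]))
}

# Centered-difference gradients with replicated edges; gx along x (columns),
# gy along y (rows, y pointing down).
gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  jp <- c(2:W, W); jm <- c(1, 1:(W - 1))
  ip <- c(2:H, H); im <- c(1, 1:(H - 1))
  list(gx = (m[, jp] - m[, jm]) / 2, gy = (m[ip, ] - m[im, ]) / 2)
}

# Sum over non-overlapping w x w blocks; trailing remainder rows/cols dropped.
block_sum <- function(m, w) {
  bh <- nrow(m) %/% w; bw <- ncol(m) %/% w
  m <- m[seq_len(bh * w), seq_len(bw * w), drop = FALSE]
  gr <- rep(seq_len(bh), each = w)
  gc <- rep(seq_len(bw), each = w)
  t(rowsum(t(rowsum(m, gr)), gc))
}

# Map an angle difference to the nematic branch (-pi/2, pi/2].
wrap_nematic <- function(d) {
  d <- (d + pi / 2) %% pi
  d[d == 0] <- pi
  d - pi / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
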