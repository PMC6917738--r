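# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition with plain loops, so they share
# no code with the implementation.

# Exhaustive Euclidean distance transform.
brute_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j]) {
      out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
    }
  }
  out
}

# Per-pixel truncated-window local mean.
brute_local_mean <- function(m, window) {
  H <- nrow(m); W <- ncol(m)
  r1 <- (window - 1) %/% 2; r2 <- window %/% 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    out[i, j] <- mean(m[max(1, i - r1):min(H, i + r2),
                        max(1, j - r1):min(W, j + r2)])
  }
  out
}

# Pairwise nematic correlation by full enumeration.
brute_spatial_corr <- function(x, y, theta, bin, r_max) {
  n <- length(x)
  rs <- c(); cs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (r > 0 && r <= r_max) {
      rs <- c(rs, r); cs <- c(cs, cos(2 * (theta[i] - theta[j])))
    }
  }
  b <- ceiling(rs / bin)
  vapply(seq_len(max(b)), function(k) mean(cs[b == k]), numeric(1))
}

# Mean per-pair Pearson correlation of 3x3-block-mean grids at a lag.
brute_theta_lag <- function(frames, block, lag) {
  T <- dim(frames)[3]
  bh <- nrow(frames) %/% block; bw <- ncol(frames) %/% block
  grid <- function(t) {
    g <- matrix(0, bh, bw)
    for (a in seq_len(bh)) for (b in seq_len(bw)) {
      g[a, b] <- mean(frames[((a - 1) * block + 1):(a * block),
                             ((b - 1) * block + 1):(b * block), t])
    }
    as.vector(g)
  }
  cors <- c()
  for (t in seq_len(T - lag)) cors <- c(cors, cor(grid(t), grid(t + lag)))
  mean(cors)
}

# Exhaustive min-cost max-cardinality assignment (tracks x spots) over all
# injective mappings; edges with cost > link_max forbidden.
brute_assignment <- function(cost) {
  nt <- nrow(cost); ns <- ncol(cost)
  best <- list(n = -1, cost = Inf, asg = rep(NA_integer_, nt))
  asg <- rep(NA_integer_, nt)
  rec <- function(i, used, n, cst) {
    if (i > nt) {
      if (n > best$n || (n == best$n && cst < best$cost - 1e-12)) {
        best <<- list(n = n, cost = cst, asg = asg)
      }
      return(invisible())
    }
    for (s in seq_len(ns)) {
      if (!used[s] && is.finite(cost[i, s])) {
        asg[i] <<- s; used[s] <- TRUE
        rec(i + 1, used, n + 1, cst + cost[i, s])
        used[s] <- FALSE; asg[i] <<- NA_integer_
      }
    }
    rec(i + 1, used, n, cst)
  }
  rec(1, rep(FALSE, ns), 0, 0)
  best
}

# Small helpers for constructing frames.
gaussian_spot_frame <- function(H, pos, amplitude = 50, sigma = 2,
                                background = 10) {
  f <- matrix(background, H, H)
  for (k in seq_len(nrow(pos))) {
    ii <- seq_len(H); jj <- seq_len(H)
    f <- f + amplitude[min(k, length(amplitude))] *
      outer(exp(-(ii - pos[k, 1])^2 / (2 * sigma^2)),
            exp(-(jj - pos[k, 2])^2 / (2 * sigma^2)))
  }
  f
}

ring_image <- function(n = 128, pixel_size = 0.108, period_um = 0.86) {
  ctr <- (n + 1) / 2
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  r <- sqrt((xy$x - ctr)^2 + (xy$y - ctr)^2) * pixel_size
  matrix(sin(2 * pi * r / period_um), n, n)
}

grating_image <- function(n = 96, angle_rad = pi / 6, period_px = 12) {
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix(sin(2 * pi * (xy$x * sin(angle_rad) - xy$y * cos(angle_rad)) /
               period_px), n, n)
}

sidecar_path_for_test <- function(path) {
  paste0(sub("\\.[Tt][Ii][Ff]{1,2}$", "", path), ".json")
}
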