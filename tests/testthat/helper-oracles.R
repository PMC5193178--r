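# Independent brute-force oracles used to validate the histogram
# thresholds, the median filter and clustering recovery.

# Triangle threshold: explicit point-to-line distance (normalized form),
# looping over every candidate bin on the long-tail side of the peak.
oracle_triangle <- function(counts) {
  n <- length(counts)
  nz <- which(counts > 0)
  peak <- which.max(counts)
  low <- nz[1]; high <- nz[length(nz)]
  if (low == high) return(low)
  flipped <- (peak - low) > (high - peak)
  h <- if (flipped) rev(counts) else counts
  p <- if (flipped) n - peak + 1 else peak
  tail_bin <- if (flipped) n - low + 1 else high
  if (tail_bin <= p) {
    t <- p
  } else {
    # line a*x + b*y + c = 0 through (p, h[p]) and (tail_bin, h[tail_bin])
    a <- h[tail_bin] - h[p]
    b <- -(tail_bin - p)
    cc <- -(a * p + b * h[p])
    best <- p; best_d <- -1
    for (bb in p:tail_bin) {
      d <- abs(a * bb + b * h[bb] + cc) / sqrt(a^2 + b^2)
      if (d > best_d) {
        best_d <- d; best <- bb
      }
    }
    t <- best
  }
  if (flipped) n - t + 1 else t
}

# Huang threshold: direct double loop over thresholds and grey levels.
oracle_huang <- function(counts, mids = seq_along(counts)) {
  n <- length(counts)
  nz <- which(counts > 0)
  first <- nz[1]; last <- nz[length(nz)]
  if (first == last) return(first)
  C <- mids[last] - mids[first]
  best_t <- first; best_e <- Inf
  for (t in first:(last - 1)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts[(t + 1):n])
    mu0 <- sum(counts[1:t] * mids[1:t]) / n0
    mu1 <- sum(counts[(t + 1):n] * mids[(t + 1):n]) / n1
    e <- 0
    for (g in seq_len(n)) {
      if (counts[g] == 0) next
      mu <- if (g <= t) mu0 else mu1
      u <- 1 / (1 + abs(mids[g] - mu) / C)
      if (u > 1e-12 && u < 1 - 1e-12) {
        e <- e + counts[g] * (-u * log(u) - (1 - u) * log(1 - u))
      }
    }
    if (e < best_e - 1e-12) {
      best_e <- e; best_t <- t
    }
  }
  best_t
}

# Sliding-window circular median with replicated borders, triple loop.
oracle_median <- function(img, radius = 2) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          if (dx^2 + dy^2 <= radius^2) {
            vals <- c(vals, img[min(max(i + dy, 1), nr),
                                min(max(j + dx, 1), nc)])
          }
        }
      }
      out[i, j] <- median(vals)
    }
  }
  out
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Kendall tau-b by explicit O(n^2) pair counting.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
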