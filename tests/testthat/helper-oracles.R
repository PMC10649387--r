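# Independent brute-force oracles and small fixture builders used across the
# suite. Deliberately written as plain loops, independent of the package's
# vectorised implementations.

random_gray <- function(nr, nc, seed, levels = 0:255) {
  set.seed(seed)
  matrix(sample(levels, nr * nc, replace = TRUE), nr, nc)
}

# Exhaustive Kapur criterion scan over all 256 candidate thresholds.
kapur_oracle <- function(img) {
  counts <- rep(0, 256)
  for (v in as.integer(round(img))) counts[v + 1] <- counts[v + 1] + 1
  p <- counts / sum(counts)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  best_t <- NA_integer_
  best_h <- -Inf
  for (t in 0:254) {
    p1 <- sum(p[1:(t + 1)])
    if (p1 <= 0 || p1 >= 1) next
    h <- ent(p[1:(t + 1)] / p1) + ent(p[(t + 2):256] / (1 - p1))
    if (h > best_h + 1e-12) {
      best_h <- h
      best_t <- t
    }
  }
  list(threshold = best_t, entropy = best_h)
}

# Pair-enumeration GLCM oracle (symmetric accumulation over offsets).
glcm_oracle <- function(lev, mask, levels, offsets) {
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    for (r in seq_len(nrow(lev))) {
      for (c in seq_len(ncol(lev))) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
        if (!mask[r, c] || !mask[r2, c2]) next
        i <- lev[r, c]; j <- lev[r2, c2]
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts
}

# Flood-fill GLSZM oracle: 8-connected zones of equal level within the mask.
glszm_oracle <- function(lev, mask, levels) {
  visited <- matrix(FALSE, nrow(lev), ncol(lev))
  zones <- list()
  for (r0 in seq_len(nrow(lev))) {
    for (c0 in seq_len(ncol(lev))) {
      if (!mask[r0, c0] || visited[r0, c0]) next
      v <- lev[r0, c0]
      queue <- list(c(r0, c0))
      visited[r0, c0] <- TRUE
      size <- 0
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        size <- size + 1
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- cur[1] + dr; c <- cur[2] + dc
          if (r < 1 || r > nrow(lev) || c < 1 || c > ncol(lev)) next
          if (!mask[r, c] || visited[r, c] || lev[r, c] != v) next
          visited[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
      zones[[length(zones) + 1]] <- c(level = v, size = size)
    }
  }
  if (!length(zones)) return(matrix(0, levels, 1))
  zs <- do.call(rbind, zones)
  counts <- matrix(0, levels, max(zs[, "size"]))
  for (k in seq_len(nrow(zs)))
    counts[zs[k, "level"], zs[k, "size"]] <- counts[zs[k, "level"], zs[k, "size"]] + 1
  counts
}

disk_mask <- function(n, r, center = (n + 1) / 2) {
  (row(matrix(0, n, n)) - center)^2 + (col(matrix(0, n, n)) - center)^2 <= r^2
}
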