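# Independent brute-force oracles. These re-derive each operation from its
# definition with naive loops, deliberately sharing no code with the package
# internals.

# scipy-style reflect index, 1-based
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_rank_filter <- function(x, radius, maximum) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  f <- if (maximum) max else min
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius)
      vals <- c(vals, x[oracle_reflect(i + di, H), oracle_reflect(j + dj, W)])
    out[i, j] <- f(vals)
  }
  out
}

oracle_gaussian <- function(x, sigma) {
  H <- nrow(x); W <- ncol(x)
  h <- max(1, ceiling(3 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k2 <- outer(k, k); k2 <- k2 / sum(k2)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (di in -h:h) for (dj in -h:h)
      s <- s + k2[di + h + 1, dj + h + 1] *
        x[oracle_reflect(i + di, H), oracle_reflect(j + dj, W)]
    out[i, j] <- s
  }
  out
}

oracle_bw_open <- function(x, radius) {
  oracle_gaussian(oracle_rank_filter(oracle_rank_filter(x, radius, TRUE),
                                     radius, FALSE), radius)
}

oracle_sd_projection <- function(frames, window) {
  apply(frames[, , window, drop = FALSE], c(1, 2), sd)
}

# Topographic prominence by flood fill. For each strict local maximum m the
# prominence is v(m) minus the highest level t at which the connected
# component of {v >= t} containing m holds a strictly higher pixel (binary
# search over levels; global maximum: v(m) - min(v)). Assumes all pixel values
# distinct (continuous random images).
oracle_prominent_maxima <- function(x, prominence) {
  H <- nrow(x); W <- ncol(x); n <- H * W
  x <- if (max(x) > min(x)) (x - min(x)) / (max(x) - min(x)) * 255 else x * 0
  xv <- as.vector(x)
  # 8-neighborhoods as linear (column-major) indices
  nb <- vector("list", n)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    p <- (j - 1L) * H + i
    q <- integer(0)
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= H && jj >= 1L && jj <= W)
        q <- c(q, (jj - 1L) * H + ii)
    }
    nb[[p]] <- q
  }
  comp_has_higher <- function(p0, t) {
    v <- xv[p0]
    seen <- logical(n)
    stack <- integer(n); top <- 1L; stack[1] <- p0; seen[p0] <- TRUE
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      if (xv[p] > v) return(TRUE)
      for (q in nb[[p]]) {
        if (!seen[q] && xv[q] >= t) {
          seen[q] <- TRUE; top <- top + 1L; stack[top] <- q
        }
      }
    }
    FALSE
  }
  res <- NULL
  levels <- sort(unique(xv))
  for (p in seq_len(n)) {
    if (!all(xv[p] > xv[nb[[p]]])) next  # strict local maximum
    v <- xv[p]
    below <- levels[levels <= v]
    # binary search: largest t whose component still holds a higher pixel
    lo <- 1L; hi <- length(below); saddle <- NA_real_
    if (comp_has_higher(p, below[1])) {
      while (lo < hi) {
        mid <- (lo + hi + 1L) %/% 2L
        if (comp_has_higher(p, below[mid])) lo <- mid else hi <- mid - 1L
      }
      saddle <- below[lo]
    }
    prom <- if (is.na(saddle)) v - min(xv) else v - saddle
    if (prom >= prominence)
      res <- rbind(res, data.frame(row = (p - 1L) %% H + 1L,
                                   col = (p - 1L) %/% H + 1L,
                                   score = v, prominence = prom))
  }
  if (is.null(res)) return(data.frame(row = integer(0), col = integer(0),
                                      score = numeric(0), prominence = numeric(0)))
  res[order(-res$score, res$row, res$col), ]
}

oracle_distance_to_mask <- function(pt, mask) {
  best <- Inf
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j]) best <- min(best, sqrt((i - pt[1])^2 + (j - pt[2])^2))
  best
}

# Triangle rule recomputed with the explicit point-to-line distance formula.
oracle_triangle_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  bin <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  right <- (hi - peak) >= (peak - lo)
  end <- if (right) hi else lo
  p1 <- c(peak, counts[peak]); p2 <- c(end, 0)
  len <- sqrt(sum((p2 - p1)^2))
  best_d <- -1; best_b <- peak
  for (b in (if (right) peak:end else end:peak)) {
    # distance from (b, counts[b]) to the line through p1, p2
    d <- abs((p2[2] - p1[2]) * b - (p2[1] - p1[1]) * counts[b] +
               p2[1] * p1[2] - p2[2] * p1[1]) / len
    if (d > best_d) { best_d <- d; best_b <- b }
  }
  rng[1] + (best_b - 0.5) / n_bins * (rng[2] - rng[1])
}
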