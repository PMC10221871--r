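# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

# 1x1 projection: per-pixel triple loop.
bruteProject <- function(F_, W) {
  d <- dim(F_)
  A <- array(0, dim = c(d[1], d[2], ncol(W)))
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (c in seq_len(ncol(W)))
      A[i, j, c] <- sum(W[, c] * F_[i, j, ])
  A
}

# Global average pooling: explicit double loop per channel.
brutePool <- function(A) {
  d <- dim(A)
  out <- numeric(d[3])
  for (c in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + A[i, j, c]
    out[c] <- s / (d[1] * d[2])
  }
  out
}

# Region score: naive per-box mean over pixels.
bruteScore <- function(S, boxes) {
  vapply(seq_len(nrow(boxes)), function(b) {
    rows <- (boxes$y0[b] + 1):boxes$y1[b]
    cols <- (boxes$x0[b] + 1):boxes$x1[b]
    s <- 0
    for (i in rows) for (j in cols) s <- s + S[i, j]
    s / (length(rows) * length(cols))
  }, numeric(1))
}

bruteIoU <- function(a, b) {
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  inter / ((a$x1 - a$x0) * (a$y1 - a$y0) +
           (b$x1 - b$x0) * (b$y1 - b$y0) - inter)
}

# Greedy NMS: repeat-loop reference keeping row indices.
bruteNMS <- function(regions, thr) {
  pool <- regions
  pool$origin <- seq_len(nrow(pool))
  kept <- pool[0, ]
  while (nrow(pool) > 0) {
    best <- which(pool$score == max(pool$score))[1]
    kept <- rbind(kept, pool[best, ])
    rest <- pool[-best, , drop = FALSE]
    if (nrow(rest) == 0) break
    drop <- vapply(seq_len(nrow(rest)), function(j)
      bruteIoU(pool[best, ], rest[j, ]) > thr, logical(1))
    pool <- rest[!drop, , drop = FALSE]
  }
  kept
}

# Connected components by exhaustive repeated dilation (8-neighbourhood).
bruteLargestComponentBox <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  visited <- matrix(FALSE, H, W)
  best <- NULL; bestSize <- 0
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || visited[i, j]) next
    comp <- matrix(FALSE, H, W)
    comp[i, j] <- TRUE
    repeat {
      grown <- comp
      idx <- which(comp, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        ys <- max(1, idx[r, 1] - 1):min(H, idx[r, 1] + 1)
        xs <- max(1, idx[r, 2] - 1):min(W, idx[r, 2] + 1)
        grown[ys, xs] <- grown[ys, xs] | (mask[ys, xs] > 0)
      }
      if (all(grown == comp)) break
      comp <- grown
    }
    visited <- visited | comp
    size <- sum(comp)
    if (size > bestSize) {
      pos <- which(comp, arr.ind = TRUE)
      best <- c(x0 = min(pos[, 2]) - 1, y0 = min(pos[, 1]) - 1,
                x1 = max(pos[, 2]), y1 = max(pos[, 1]))
      bestSize <- size
    }
  }
  best
}

# Map with Gaussian bumps at given centres/heights.
bumpMap <- function(H, W, centers, heights, sd = 3) {
  m <- matrix(0, H, W)
  for (k in seq_along(heights)) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    m <- m + heights[k] *
      exp(-(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+")) /
            (2 * sd^2))
  }
  m
}
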