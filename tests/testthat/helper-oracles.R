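# Independent brute-force oracles used to validate the implementations.

# Otsu-log oracle: scan every histogram boundary, recomputing the class
# means by direct summation (naive loop, no cumulative shortcuts).
otsu_log_oracle <- function(image, n_bins = 256) {
  eps <- 1 / 65536
  mn <- min(image); mx <- max(image)
  y <- log(eps + (image - mn) / (mx - mn))
  breaks <- seq(min(y), max(y), length.out = n_bins + 1)
  idx <- findInterval(y, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best <- -Inf; best_k <- NA
  for (k in 1:(n_bins - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts[(k + 1):n_bins])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_k <- k }
  }
  t_log <- breaks[best_k + 1]
  mn + (exp(t_log) - eps) * (mx - mn)
}

# Neighbour oracle: direct per-pixel enumeration of Chebyshev distances.
neighbors_oracle <- function(cells, distance = 1) {
  n <- max(cells)
  px <- lapply(seq_len(n), function(k) which(cells == k, arr.ind = TRUE))
  H <- nrow(cells); W <- ncol(cells)
  is_boundary <- function(k) {
    p <- px[[k]]
    apply(p, 1, function(q) {
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- q[1] + dr; c <- q[2] + dc
        if (r < 1 || r > H || c < 1 || c > W) return(TRUE)
        if (cells[r, c] != k) return(TRUE)
      }
      FALSE
    })
  }
  cheb <- function(p, q) max(abs(p[1] - q[1]), abs(p[2] - q[2]))
  out <- data.frame(label = seq_len(n), neighbor_count = 0L, percent_touching = 0)
  for (k in seq_len(n)) {
    bnd <- px[[k]][is_boundary(k), , drop = FALSE]
    nb <- integer(0); touch <- 0L
    for (i in seq_len(nrow(bnd))) {
      close_foreign <- FALSE
      for (m in setdiff(seq_len(n), k)) {
        dmin <- min(apply(px[[m]], 1, function(q) cheb(bnd[i, ], q)))
        if (dmin <= distance) { nb <- union(nb, m); close_foreign <- TRUE }
      }
      if (close_foreign) touch <- touch + 1L
    }
    out$neighbor_count[k] <- length(nb)
    out$percent_touching[k] <- if (nrow(bnd)) 100 * touch / nrow(bnd) else 0
  }
  out
}
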