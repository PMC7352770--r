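# Independent oracles used across test files. These deliberately avoid the
# package's vectorized code paths: maxima detection is an exhaustive
# per-pixel neighbor scan and plateau grouping a stack-based flood fill.

# Exhaustive focus counter: same blur and prominence rule as count_foci(),
# but every pixel is compared against its in-image 8-neighborhood in an
# explicit loop, plateaus are grown by flood fill, and per-nucleus
# background/max are computed with sapply over labels.
oracle_count_foci <- function(gamma, mask, params) {
  g <- EBImage::imageData(EBImage::gblur(EBImage::Image(gamma),
                                         sigma = params$blur_sigma))
  dim(g) <- dim(gamma)
  h <- nrow(g); w <- ncol(g)
  is_max <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      v <- g[r, c]
      ok <- TRUE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1L || rr > h || cc < 1L || cc > w) next
          if (g[rr, cc] > v) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      is_max[r, c] <- ok
    }
  }
  n <- max(mask, 0L)
  counts <- integer(n)
  if (n == 0L) return(counts)
  bg <- sapply(seq_len(n), function(l) min(g[mask == l]))
  mx <- sapply(seq_len(n), function(l) max(g[mask == l]))
  visited <- matrix(FALSE, h, w)
  for (r0 in seq_len(h)) {
    for (c0 in seq_len(w)) {
      if (!is_max[r0, c0] || visited[r0, c0]) next
      stack <- matrix(c(r0, c0), 1L, 2L)
      visited[r0, c0] <- TRUE
      plateau <- matrix(integer(0), 0L, 2L)
      while (nrow(stack) > 0L) {
        p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
        plateau <- rbind(plateau, p)
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr < 1L || rr > h || cc < 1L || cc > w) next
          if (is_max[rr, cc] && !visited[rr, cc]) {
            visited[rr, cc] <- TRUE
            stack <- rbind(stack, c(rr, cc))
          }
        }
      }
      labs <- unique(mask[plateau])
      if (length(labs) != 1L || labs == 0L) next
      v <- g[plateau[1, 1], plateau[1, 2]]
      height <- v - bg[labs]
      if (height > params$maxima_prominence * (mx[labs] - bg[labs]) &&
          height > params$min_abs_prominence)
        counts[labs] <- counts[labs] + 1L
    }
  }
  counts
}

# Fisher-z 95% confidence interval for a population correlation at size n.
fisher_interval <- function(rho, n) {
  z <- atanh(rho)
  tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
}
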