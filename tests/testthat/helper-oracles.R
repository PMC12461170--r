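# Independent brute-force oracles used to check the package's incremental /
# vectorized implementations. These deliberately use the most literal,
# slowest formulation of each definition.

# noise rule: both neighbour distances (within tag) exceed the threshold
oracle_noise_flags <- function(stream, thr = 2.5) {
  flags <- logical(nrow(stream))
  for (i in seq_len(nrow(stream))) {
    same <- which(stream$tag_id == stream$tag_id[i])
    k <- match(i, same)
    if (k == 1 || k == length(same)) next
    d <- function(a, b) sqrt((stream$x[a] - stream$x[b])^2 +
                               (stream$y[a] - stream$y[b])^2)
    flags[i] <- d(i, same[k - 1]) > thr && d(i, same[k + 1]) > thr
  }
  flags
}

# even-odd ray casting, vertex list open (first != last required not)
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Chebyshev-ball dilation by exhaustive distance scan over all cells
oracle_dilate <- function(cells, d, grid) {
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (iy in 0:(grid$n_rows - 1)) for (ix in 0:(grid$n_cols - 1)) {
    for (k in seq_len(nrow(cells))) {
      if (is.na(cells[k, 1])) next
      if (max(abs(ix - cells[k, 1]), abs(iy - cells[k, 2])) <= d) {
        out[iy + 1, ix + 1] <- TRUE
        break
      }
    }
  }
  out & grid$inside
}

# full-history sliding window: cell in shadow at minute t iff t >= T and it
# was uncovered at every one of minutes t-T+1 .. t
oracle_shadow_percent <- function(covered, T_min, inside = NULL) {
  if (is.null(inside)) inside <- rep(TRUE, ncol(covered))
  n <- nrow(covered)
  out <- numeric(n)
  for (t in seq_len(n)) {
    shadow <- logical(ncol(covered))
    if (t >= T_min) {
      win <- covered[(t - T_min + 1):t, , drop = FALSE]
      shadow <- colSums(win) == 0
    }
    out[t] <- 100 * sum(shadow & inside) / sum(inside)
  }
  out
}

oracle_shadow_mask <- function(covered, T_min, t) {
  if (t < T_min) return(rep(FALSE, ncol(covered)))
  colSums(covered[(t - T_min + 1):t, , drop = FALSE]) == 0
}

# dense sampling along the polyline (10^4 points)
oracle_polyline_distance <- function(p, route, n_samples = 1e4) {
  seg <- route[-1, , drop = FALSE] - route[-nrow(route), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  s <- seq(0, sum(len), length.out = n_samples)
  k <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(route) - 1)
  frac <- (s - cum[k]) / len[k]
  pts <- route[k, , drop = FALSE] + seg[k, , drop = FALSE] * frac
  min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
}

# linear-interpolation quantile by explicit order statistics (type 7)
oracle_quantile <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

make_stream <- function(tag, t_sec, x, y,
                        origin = as.POSIXct("2024-08-04 00:00:00",
                                            tz = "UTC")) {
  position_stream(rep_len(tag, length(t_sec)), origin + t_sec, x, y)
}
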