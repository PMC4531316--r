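# geometric fixtures and independent brute-force oracles used across tests

circle_contour <- function(r, cx = 0, cy = 0, n = 256, frame_index = 0L) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cell_contour(cx + r * cos(th), cy + r * sin(th), frame_index)
}

ellipse_contour <- function(a, b, cx = 0, cy = 0, n = 256,
                            frame_index = 0L) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cell_contour(cx + a * cos(th), cy + b * sin(th), frame_index)
}

square_contour <- function(side, cx = 0, cy = 0, pts_per_side = 32L) {
  s <- side / 2
  t <- seq(0, 1, length.out = pts_per_side + 1)[-(pts_per_side + 1)]
  x <- c(cx - s + t * side, rep(cx + s, pts_per_side),
         cx + s - t * side, rep(cx - s, pts_per_side))
  y <- c(rep(cy - s, pts_per_side), cy - s + t * side,
         rep(cy + s, pts_per_side), cy + s - t * side)
  cell_contour(x, y)
}

# frame with one or more disks on a constant background (pixel units)
disk_frame <- function(nr, nc, cx, cy, r, fg = 100, bg = 5) {
  X <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  m <- matrix(bg, nr, nc)
  for (i in seq_along(cx))
    m[(X - cx[i])^2 + (Y - cy[i])^2 <= r[i]^2] <- fg
  m
}

# brute-force point-in-polygon by the crossing-number rule (independent of
# the package's mgcv-based test)
bf_inside <- function(ct, px, py) {
  n <- length(ct$x)
  xs <- ct$x; ys <- ct$y
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  vapply(seq_along(px), function(i) {
    crossing <- (ys > py[i]) != (ye > py[i])
    t <- (py[i] - ys) / (ye - ys)
    xint <- xs + t * (xe - xs)
    sum(crossing & xint > px[i]) %% 2 == 1
  }, logical(1))
}

# brute-force minimal distance from a point to the contour polyline
bf_dist <- function(ct, px, py) {
  n <- length(ct$x)
  ax <- ct$x; ay <- ct$y
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  vapply(seq_along(px), function(i) {
    dmin <- Inf
    for (s in seq_len(n)) {
      dx <- bx[s] - ax[s]; dy <- by[s] - ay[s]
      L2 <- dx^2 + dy^2
      t <- if (L2 == 0) 0 else
        min(max(((px[i] - ax[s]) * dx + (py[i] - ay[s]) * dy) / L2, 0), 1)
      d <- sqrt((px[i] - ax[s] - t * dx)^2 + (py[i] - ay[s] - t * dy)^2)
      if (d < dmin) dmin <- d
    }
    dmin
  }, numeric(1))
}

# random star-shaped simple polygon around (cx, cy)
random_star_polygon <- function(seed, n = 24, r_base = 10, cx = 20,
                                cy = 20) {
  set.seed(seed)
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- r_base * stats::runif(n, 0.6, 1.4)
  cell_contour(cx + r * cos(th), cy + r * sin(th))
}

# brute-force double-loop temporal cross-covariance with full-series means
bf_temporal_cc <- function(S, B, lags, denom) {
  n <- length(S)
  Sc <- S - mean(S); Bc <- B - mean(B)
  vapply(lags, function(k) {
    acc <- 0; cnt <- 0
    for (t in seq_len(n)) {
      u <- t + k
      if (u >= 1 && u <= n) { acc <- acc + Sc[t] * Bc[u]; cnt <- cnt + 1 }
    }
    acc / (cnt - 1) / denom
  }, numeric(1))
}
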