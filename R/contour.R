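#' Closed cell boundary contour
#'
#' A contour is an ordered, closed, simple polyline of sub-pixel boundary
#' points in physical units (micrometers). The closing edge from the last
#' point back to the first is implicit. Contours are always stored
#' counter-clockwise, i.e. with positive shoelace area in the image
#' coordinate frame (x rightward, y downward, pixel centers at integer
#' coordinates, 0-based; micrometers = pixels x pixel size), so that the
#' outward normal at a point travelling along the contour is the rightward
#' rotation of the tangent.
#'
#' @param x,y numeric vectors of equal length (>= 3), coordinates in um.
#' @param frame_index integer frame the contour belongs to.
#' @return An object of class `cell_contour`: a list with elements `x`, `y`
#'   (um) and `frame_index`.
#' @export
cell_contour <- function(x, y, frame_index = 0L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("contour coordinates must be finite")
  # drop an explicit closing point and exact consecutive duplicates
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("contour degenerate after removing duplicates")
  ct <- structure(list(x = as.numeric(x), y = as.numeric(y),
                       frame_index = as.integer(frame_index)),
                  class = "cell_contour")
  ensure_ccw(ct)
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour> frame %d: %d points, perimeter %.2f um, area %.2f um^2\n",
              x$frame_index, length(x$x), contour_perimeter(x),
              abs(contour_area(x))))
  invisible(x)
}

#' Signed (shoelace) area of a contour
#'
#' Positive for the stored counter-clockwise orientation.
#' @param ct a `cell_contour`.
#' @return signed area in um^2.
#' @export
contour_area <- function(ct) {
  x <- ct$x; y <- ct$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ensure_ccw <- function(ct) {
  if (contour_area(ct) < 0) {
    ct$x <- rev(ct$x); ct$y <- rev(ct$y)
  }
  ct
}

#' Contour perimeter
#' @param ct a `cell_contour`.
#' @return perimeter in um (closing edge included).
#' @export
contour_perimeter <- function(ct) sum(segment_lengths(ct))

segment_lengths <- function(ct) {
  x <- ct$x; y <- ct$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sqrt((xn - x)^2 + (yn - y)^2)
}

# cumulative arc length at each vertex, starting at 0 for vertex 1
arc_lengths <- function(ct) {
  c(0, cumsum(segment_lengths(ct)))[seq_along(ct$x)]
}

#' Normalized arc-length parameter of each contour vertex
#' @param ct a `cell_contour`.
#' @return numeric in [0, 1), one value per vertex.
#' @export
arc_params <- function(ct) arc_lengths(ct) / contour_perimeter(ct)

#' Interpolate points at given normalized arc-length parameters
#'
#' @param ct a `cell_contour`.
#' @param params numeric vector of parameters (taken mod 1).
#' @return list with `x`, `y` (um) of the interpolated points.
#' @export
point_at_param <- function(ct, params) {
  per <- contour_perimeter(ct)
  s <- (params %% 1) * per
  verts <- arc_lengths(ct)
  lens <- segment_lengths(ct)
  n <- length(ct$x)
  seg <- findInterval(s, verts, rightmost.closed = FALSE)
  seg[seg < 1] <- 1; seg[seg > n] <- n
  t <- (s - verts[seg]) / lens[seg]
  t[!is.finite(t)] <- 0
  nxt <- ifelse(seg == n, 1L, seg + 1L)
  list(x = ct$x[seg] + t * (ct$x[nxt] - ct$x[seg]),
       y = ct$y[seg] + t * (ct$y[nxt] - ct$y[seg]))
}

#' Redistribute contour points at uniform arc-length spacing
#'
#' Points are placed at n = round(perimeter / spacing) equally spaced
#' arc-length positions starting at the current first point, so the total
#' perimeter is preserved to within the chord-shortening error (< 1% for
#' spacing small relative to the local curvature radius).
#'
#' @param ct a `cell_contour`.
#' @param spacing target point spacing in um (> 0, <= perimeter / 16).
#' @return a resampled `cell_contour`.
#' @export
resample_contour <- function(ct, spacing) {
  per <- contour_perimeter(ct)
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (spacing > per / 16) stop("spacing too coarse: must be <= perimeter/16")
  n <- max(16L, as.integer(round(per / spacing)))
  p <- point_at_param(ct, (seq_len(n) - 1) / n)
  cell_contour(p$x, p$y, ct$frame_index)
}

#' Outward unit normals at contour vertices
#'
#' Tangents by central difference over the closed polyline; outward normal is
#' the tangent rotated toward the exterior (for the stored counter-clockwise
#' orientation in image coordinates this is (ty, -tx)).
#'
#' @param ct a `cell_contour`.
#' @return two-column matrix (nx, ny), unit length.
#' @export
outward_normals <- function(ct) {
  x <- ct$x; y <- ct$y; n <- length(x)
  ip <- c(n, seq_len(n - 1)); im <- c(2:n, 1)
  tx <- x[im] - x[ip]; ty <- y[im] - y[ip]
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  cbind(nx = ty / len, ny = -tx / len)
}

#' Project points onto a contour polyline
#'
#' For each query point returns the nearest point on the closed polyline, its
#' normalized arc-length parameter, and the distance.
#'
#' @param ct a `cell_contour`.
#' @param px,py query point coordinates (um).
#' @return list with `x`, `y`, `param`, `dist`.
#' @export
project_on_contour <- function(ct, px, py) {
  n <- length(ct$x); m <- length(px)
  ax <- ct$x; ay <- ct$y
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2; L2[L2 == 0] <- 1e-300
  verts <- arc_lengths(ct); per <- contour_perimeter(ct)
  best_d2 <- rep(Inf, m); best_x <- best_y <- best_s <- numeric(m)
  for (i in seq_len(n)) {
    t <- ((px - ax[i]) * dx[i] + (py - ay[i]) * dy[i]) / L2[i]
    t[t < 0] <- 0; t[t > 1] <- 1
    qx <- ax[i] + t * dx[i]; qy <- ay[i] + t * dy[i]
    d2 <- (px - qx)^2 + (py - qy)^2
    sel <- d2 < best_d2
    if (any(sel)) {
      best_d2[sel] <- d2[sel]; best_x[sel] <- qx[sel]; best_y[sel] <- qy[sel]
      best_s[sel] <- verts[i] + t[sel] * sqrt(L2[i])
    }
  }
  list(x = best_x, y = best_y, param = (best_s / per) %% 1,
       dist = sqrt(best_d2))
}

#' Test whether points lie inside a contour
#' @param ct a `cell_contour`.
#' @param px,py point coordinates (um).
#' @return logical vector.
#' @export
points_in_contour <- function(ct, px, py) {
  bnd <- cbind(c(ct$x, ct$x[1]), c(ct$y, ct$y[1]))
  mgcv::in.out(bnd, cbind(px, py))
}

#' Symmetric Hausdorff distance between two contours
#'
#' Measured between the closed polylines (each contour's vertices against the
#' other's segments, both directions).
#'
#' @param a,b `cell_contour` objects.
#' @return distance in um.
#' @export
hausdorff_distance <- function(a, b) {
  da <- project_on_contour(b, a$x, a$y)$dist
  db <- project_on_contour(a, b$x, b$y)$dist
  max(max(da), max(db))
}

#' Rotate contour point order so a given point comes first
#'
#' Used to keep the arc-length origin stable across frames: the first frame
#' anchors the origin at the topmost (then leftmost) vertex; each later frame
#' anchors at the vertex closest to the previous frame's origin.
#'
#' @param ct a `cell_contour`.
#' @param origin either `NULL` (topmost-then-leftmost rule) or a length-2
#'   numeric `c(x, y)` whose nearest vertex becomes the first point.
#' @return the rotated `cell_contour`.
#' @export
set_contour_origin <- function(ct, origin = NULL) {
  if (is.null(origin)) {
    i <- which(ct$y == min(ct$y))
    i <- i[which.min(ct$x[i])]
  } else {
    i <- which.min((ct$x - origin[1])^2 + (ct$y - origin[2])^2)
  }
  if (i > 1) {
    idx <- c(i:length(ct$x), seq_len(i - 1))
    ct$x <- ct$x[idx]; ct$y <- ct$y[idx]
  }
  ct
}
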