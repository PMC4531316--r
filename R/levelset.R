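#' Signed Euclidean distance field of a contour
#'
#' Builds the level-set representation of a closed boundary: a grid image
#' phi(x, y) holding the signed Euclidean distance (um) from each pixel
#' center to the contour polyline, negative inside the cell, zero on the
#' boundary, positive outside. The zero level of phi is the contour.
#'
#' Distances are exact (minimum over all polyline segments). When `clamp` is
#' finite, pixels farther than `clamp` from the contour's bounding box are
#' assigned +/- clamp without the exact computation; the near field is still
#' exact. This matters only for speed on large frames.
#'
#' @param ct a `cell_contour` (coordinates in um).
#' @param shape grid dimensions `c(nrow, ncol)` (rows = y, cols = x); if
#'   `NULL`, a grid covering the contour with a 5-cell margin is used.
#' @param grid_spacing grid cell size in um (e.g. the pixel size).
#' @param origin physical coordinates (um) of grid cell (1, 1), default (0,0).
#' @param clamp cap on |phi| for far-field pixels (um); `Inf` = exact
#'   everywhere.
#' @return An object of class `level_set_field`: list with `phi` (matrix,
#'   um), `h` (grid spacing), `origin`.
#' @export
signed_distance <- function(ct, shape = NULL, grid_spacing,
                            origin = c(0, 0), clamp = Inf) {
  h <- grid_spacing
  stopifnot(is.numeric(h), h > 0)
  if (is.null(shape)) {
    margin <- 5 * h
    origin <- c(min(ct$x) - margin, min(ct$y) - margin)
    shape <- c(ceiling((max(ct$y) - min(ct$y) + 2 * margin) / h) + 1,
               ceiling((max(ct$x) - min(ct$x) + 2 * margin) / h) + 1)
  }
  nr <- shape[1]; nc <- shape[2]
  xs <- origin[1] + (seq_len(nc) - 1) * h
  ys <- origin[2] + (seq_len(nr) - 1) * h
  if (min(ct$x) < xs[1] + 3 * h || max(ct$x) > xs[nc] - 3 * h ||
      min(ct$y) < ys[1] + 3 * h || max(ct$y) > ys[nr] - 3 * h)
    stop("contour too close to the grid edge (needs a 3-cell margin)")
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, nc), nr, nc)
  phi <- matrix(clamp, nr, nc)
  if (is.finite(clamp)) {
    near <- X >= min(ct$x) - clamp - 2 * h & X <= max(ct$x) + clamp + 2 * h &
            Y >= min(ct$y) - clamp - 2 * h & Y <= max(ct$y) + clamp + 2 * h
  } else {
    near <- matrix(TRUE, nr, nc)
  }
  px <- X[near]; py <- Y[near]
  pr <- project_on_contour(ct, px, py)
  d <- pr$dist
  inside <- points_in_contour(ct, px, py)
  d[inside] <- -d[inside]
  if (is.finite(clamp)) d <- pmin(pmax(d, -clamp), clamp)
  phi[near] <- d
  structure(list(phi = phi, h = h, origin = origin),
            class = "level_set_field")
}

#' @export
print.level_set_field <- function(x, ...) {
  cat(sprintf("<level_set_field> %d x %d grid, h = %.3g um, phi in [%.2f, %.2f]\n",
              nrow(x$phi), ncol(x$phi), x$h, min(x$phi), max(x$phi)))
  invisible(x)
}

#' Extract the zero-level contour of a level-set field
#'
#' Uses marching-squares contour lines at level 0; the longest closed line is
#' returned, converted to physical um coordinates.
#'
#' @param field a `level_set_field`.
#' @param frame_index frame index to stamp on the contour.
#' @return a `cell_contour`.
#' @export
extract_zero_contour <- function(field, frame_index = 0L) {
  nr <- nrow(field$phi); nc <- ncol(field$phi)
  ys <- field$origin[2] + (seq_len(nr) - 1) * field$h
  xs <- field$origin[1] + (seq_len(nc) - 1) * field$h
  # contourLines treats the first index as "x"; our rows are y
  cl <- grDevices::contourLines(ys, xs, field$phi, levels = 0)
  if (length(cl) == 0) stop("no zero level in field")
  len <- vapply(cl, function(l) {
    sum(sqrt(diff(l$x)^2 + diff(l$y)^2))
  }, numeric(1))
  l <- cl[[which.max(len)]]
  cell_contour(x = l$y, y = l$x, frame_index = frame_index)
}

# shifted copies of a matrix with replicated (Neumann) edges
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# one Godunov upwind step of phi_t + V |grad phi| = 0 (V a static field),
# explicit Euler, time step dt, grid spacing h
upwind_step <- function(phi, V, dt, h) {
  Dmx <- (phi - shift_mat(phi, 0, -1)) / h   # backward x (cols)
  Dpx <- (shift_mat(phi, 0, 1) - phi) / h    # forward x
  Dmy <- (phi - shift_mat(phi, -1, 0)) / h   # backward y (rows)
  Dpy <- (shift_mat(phi, 1, 0) - phi) / h    # forward y
  gp <- sqrt(pmax(Dmx, 0)^2 + pmin(Dpx, 0)^2 +
             pmax(Dmy, 0)^2 + pmin(Dpy, 0)^2)
  gm <- sqrt(pmin(Dmx, 0)^2 + pmax(Dpx, 0)^2 +
             pmin(Dmy, 0)^2 + pmax(Dpy, 0)^2)
  phi - dt * (pmax(V, 0) * gp + pmin(V, 0) * gm)
}

# Sussman PDE reinitialization toward |grad phi| = 1, preserving the zero
# level to first order; n_iter pseudo-time steps of size 0.3 h
reinit_phi <- function(phi, h, n_iter = 8L) {
  S <- phi / sqrt(phi^2 + h^2)
  dt <- 0.3 * h
  for (i in seq_len(n_iter)) {
    Dmx <- (phi - shift_mat(phi, 0, -1)) / h
    Dpx <- (shift_mat(phi, 0, 1) - phi) / h
    Dmy <- (phi - shift_mat(phi, -1, 0)) / h
    Dpy <- (shift_mat(phi, 1, 0) - phi) / h
    gp <- sqrt(pmax(Dmx, 0)^2 + pmin(Dpx, 0)^2 +
               pmax(Dmy, 0)^2 + pmin(Dpy, 0)^2)
    gm <- sqrt(pmin(Dmx, 0)^2 + pmax(Dpx, 0)^2 +
               pmin(Dmy, 0)^2 + pmax(Dpy, 0)^2)
    phi <- phi - dt * (pmax(S, 0) * (gp - 1) + pmin(S, 0) * (gm - 1))
  }
  phi
}

#' Evolve one contour onto the next by the level-set method
#'
#' Propagates the boundary Gamma(t) onto Gamma(t+1) with the Hamilton-Jacobi
#' equation phi_t + V |grad phi| = 0, using the morphing speed
#' V = -phi_next (the signed distance to the target boundary, capped at
#' `v_cap`): points inside the target move outward, points outside move
#' inward, and the front stalls on the target zero level. The step size obeys
#' the CFL condition dt * max|V| = 0.5 h. phi is reinitialized to a signed
#' distance every `reinit_every` steps. Intermediate fronts are recorded and
#' returned as `n_intermediate` contours spaced evenly over the evolution;
#' the last one has converged onto Gamma(t+1) (residual below `0.5 h`).
#'
#' @param contour_t,contour_next `cell_contour`s of consecutive frames.
#' @param n_intermediate number of intermediate contours to return (>= 1).
#' @param grid_spacing grid cell size in um; default: perimeter/256 of the
#'   first contour.
#' @param v_cap speed cap in um (default 10 cells) limiting how far from the
#'   target the full morphing speed applies.
#' @param max_steps maximum number of CFL steps (default 500).
#' @param reinit_every reinitialization period in steps.
#' @param cfl CFL number: the time step is `cfl * grid_spacing / v_cap`
#'   (default 0.5; must be <= 0.5 for stability of the upwind scheme).
#' @return list of `n_intermediate` `cell_contour`s (last one on
#'   Gamma(t+1)), with attributes `residuals` (mean |phi_next| on each
#'   returned front) and `n_steps`.
#' @export
evolve <- function(contour_t, contour_next, n_intermediate = 10L,
                   grid_spacing = NULL, v_cap = NULL, max_steps = 500L,
                   reinit_every = 25L, cfl = 0.5) {
  stopifnot(n_intermediate >= 1, cfl > 0, cfl <= 0.5)
  if (is.null(grid_spacing))
    grid_spacing <- contour_perimeter(contour_t) / 256
  h <- grid_spacing
  if (is.null(v_cap)) v_cap <- 10 * h
  margin <- 6 * h
  x0 <- min(contour_t$x, contour_next$x) - margin
  y0 <- min(contour_t$y, contour_next$y) - margin
  x1 <- max(contour_t$x, contour_next$x) + margin
  y1 <- max(contour_t$y, contour_next$y) + margin
  shape <- c(ceiling((y1 - y0) / h) + 1, ceiling((x1 - x0) / h) + 1)
  origin <- c(x0, y0)
  f_t <- signed_distance(contour_t, shape, h, origin, clamp = v_cap + 4 * h)
  f_n <- signed_distance(contour_next, shape, h, origin,
                         clamp = v_cap + 4 * h)
  phi <- f_t$phi
  phin <- f_n$phi
  V <- -pmin(pmax(phin, -v_cap), v_cap)
  dt <- cfl * h / v_cap
  tol <- 0.5 * h
  keep_every <- max(1L, as.integer(ceiling(max_steps / 150)))
  snaps <- list(phi)  # snapshot at step 0
  snap_steps <- 0L
  step <- 0L
  repeat {
    step <- step + 1L
    phi <- upwind_step(phi, V, dt, h)
    if (step %% reinit_every == 0L) phi <- reinit_phi(phi, h)
    if (step %% keep_every == 0L) {
      snaps[[length(snaps) + 1L]] <- phi
      snap_steps <- c(snap_steps, step)
    }
    near <- abs(phi) < 0.75 * h
    res <- if (any(near)) max(abs(phin[near])) else Inf
    if (res < tol || step >= max_steps) break
  }
  if (res >= tol && step >= max_steps)
    stop(sprintf(
      "level-set evolution did not converge in %d steps (residual %.3g um)",
      max_steps, res))
  if (snap_steps[length(snap_steps)] != step) {
    snaps[[length(snaps) + 1L]] <- phi
    snap_steps <- c(snap_steps, step)
  }
  # pick n_intermediate snapshots evenly spaced in step count, ending at the
  # converged front
  want <- unique(pmax(1, round(seq_len(n_intermediate) / n_intermediate *
                                 step)))
  idx <- vapply(want, function(s) which.min(abs(snap_steps - s)), integer(1))
  idx[length(idx)] <- length(snap_steps)
  idx <- unique(idx)
  out <- vector("list", length(idx))
  residuals <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fld <- structure(list(phi = snaps[[idx[k]]], h = h, origin = origin),
                     class = "level_set_field")
    ck <- extract_zero_contour(fld, frame_index = contour_next$frame_index)
    out[[k]] <- ck
    pr <- project_on_contour(contour_next, ck$x, ck$y)
    residuals[k] <- mean(pr$dist)
  }
  attr(out, "residuals") <- residuals
  attr(out, "n_steps") <- step
  attr(out, "grid_spacing") <- h
  out
}
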