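#' Peripheral sampling band of a contour
#'
#' The band is the set of grid pixels lying inside the cell within a fixed
#' depth of the edge, read off the signed distance map:
#' -depth <= phi < 0.
#'
#' @param ct the frame's `cell_contour`.
#' @param field the `level_set_field` of this contour (same frame).
#' @param depth band depth in um (> 0); default 0.5 um.
#' @return data.frame with columns `row`, `col` (grid indices), `x`, `y`
#'   (um) and `phi` (um) of the band pixels.
#' @export
build_band <- function(ct, field, depth = 0.5) {
  if (!is.numeric(depth) || length(depth) != 1 || depth <= 0)
    stop("band depth must be a positive number")
  sel <- which(field$phi >= -depth & field$phi < 0, arr.ind = TRUE)
  if (nrow(sel) == 0) stop("empty sampling band (depth too small for grid?)")
  data.frame(
    row = sel[, 1], col = sel[, 2],
    x = field$origin[1] + (sel[, 2] - 1) * field$h,
    y = field$origin[2] + (sel[, 1] - 1) * field$h,
    phi = field$phi[sel])
}

#' Partition the band into sampling windows of equal arc width
#'
#' The contour is cut into n = floor(perimeter / width) arc intervals of
#' equal width perimeter/n starting at the contour origin; each band pixel
#' joins the window whose interval contains the arc-length parameter of its
#' nearest contour point.
#'
#' @param ct the frame's `cell_contour`.
#' @param band band pixels from [build_band()].
#' @param width target window arc width in um; default 1.25 um.
#' @return A `sampling_windows` object: list of windows, each with
#'   `window_index`, `arc_start`/`arc_end` (um), `param_start`/`param_end`,
#'   `pixels` (row indices into `band`), `centroid` and `normal`; attributes
#'   carry the contour and band.
#' @export
partition_windows <- function(ct, band, width = 1.25) {
  per <- contour_perimeter(ct)
  if (!is.numeric(width) || width <= 0) stop("window width must be > 0")
  n <- floor(per / width)
  if (n < 8) stop("cell too small for windowing (fewer than 8 windows)")
  bounds <- (seq_len(n) - 1) / n
  windows_from_bounds(ct, band, bounds)
}

#' Build sampling windows from explicit arc-parameter boundaries
#'
#' Workhorse behind [partition_windows()], also used when window boundaries
#' have been propagated from an earlier frame through the correspondence
#' (in which case widths drift slightly and are deliberately not
#' re-equalized, preserving material identity).
#'
#' @param ct the frame's `cell_contour`.
#' @param band band pixels from [build_band()].
#' @param bounds numeric vector of n window start parameters in [0, 1),
#'   circularly increasing; window j spans `[bounds[j], bounds[j+1])`.
#' @return a `sampling_windows` object (see [partition_windows()]).
#' @export
windows_from_bounds <- function(ct, band, bounds) {
  n <- length(bounds)
  per <- contour_perimeter(ct)
  # rotate so bounds are increasing from bounds[1]
  rel <- (bounds - bounds[1]) %% 1
  if (is.unsorted(rel)) stop("window bounds must be circularly increasing")
  pr <- project_on_contour(ct, band$x, band$y)
  prel <- (pr$param - bounds[1]) %% 1
  wi <- findInterval(prel, c(rel, 1), rightmost.closed = FALSE)
  wi[wi > n] <- n
  ends <- c(rel[-1], 1) + bounds[1]
  wins <- vector("list", n)
  for (j in seq_len(n)) {
    pix <- which(wi == j)
    mid <- (rel[j] + (c(rel[-1], 1))[j]) / 2 + bounds[1]
    ctr <- point_at_param(ct, mid)
    nrm <- normal_at_param(ct, mid)
    wins[[j]] <- list(
      window_index = j,
      param_start = bounds[j] %% 1, param_end = ends[j] %% 1,
      arc_start = (bounds[j] %% 1) * per, arc_end = (ends[j] %% 1) * per,
      arc_width = ((c(rel[-1], 1))[j] - rel[j]) * per,
      pixels = pix,
      centroid = c(x = ctr$x, y = ctr$y),
      normal = nrm)
  }
  structure(wins, class = "sampling_windows", contour = ct, band = band,
            n_windows = n)
}

# outward unit normal at arbitrary arc parameters, by finite difference
# along the contour
normal_at_param <- function(ct, params, eps = 1e-3) {
  a <- point_at_param(ct, params - eps)
  b <- point_at_param(ct, params + eps)
  tx <- b$x - a$x; ty <- b$y - a$y
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  c(nx = unname(ty / len), ny = unname(-tx / len))
}

#' @export
print.sampling_windows <- function(x, ...) {
  w <- vapply(x, function(w) w$arc_width, numeric(1))
  cat(sprintf("<sampling_windows> %d windows, arc width %.3f +/- %.3f um, %d band pixels\n",
              length(x), mean(w), stats::sd(w),
              nrow(attr(x, "band"))))
  invisible(x)
}

#' Mean ratio per sampling window
#'
#' Averages the ratio image over each window's band pixels, using only
#' pixels where the ratio is valid; windows with fewer than `min_pixels`
#' valid pixels are reported missing (`NA`), never zero.
#'
#' @param windows a `sampling_windows` object.
#' @param ratio_frame ratio image matrix (same grid as the band's field).
#' @param valid_mask logical matrix of the same shape; `NULL` means all
#'   finite pixels are valid.
#' @param min_pixels minimum number of valid pixels per window (default 3).
#' @return numeric vector of per-window means (NA where missing).
#' @export
sample_ratio <- function(windows, ratio_frame, valid_mask = NULL,
                         min_pixels = 3L) {
  band <- attr(windows, "band")
  if (is.null(valid_mask)) valid_mask <- is.finite(ratio_frame)
  idx <- cbind(band$row, band$col)
  vals <- ratio_frame[idx]
  ok <- valid_mask[idx] & is.finite(vals)
  vapply(windows, function(w) {
    v <- vals[w$pixels]; o <- ok[w$pixels]
    if (sum(o) < min_pixels) NA_real_ else mean(v[o])
  }, numeric(1))
}

#' Per-window normal displacement between two frames
#'
#' Averages the displacement vectors of the correspondence reference points
#' whose source arc parameter falls in each window's interval, then projects
#' the mean vector on the window's outward normal (protrusion positive,
#' retraction negative). Windows containing no reference point get the
#' circular interpolation of their neighbors and are flagged.
#'
#' @param windows a `sampling_windows` object built on the source contour.
#' @param corr the corrected `correspondence_map` spanning this frame pair.
#' @return numeric vector (um) with attribute `interpolated` (logical).
#' @export
window_displacement <- function(windows, corr) {
  sp <- corr$source_params
  disp <- numeric(length(windows))
  empty <- logical(length(windows))
  for (j in seq_along(windows)) {
    w <- windows[[j]]
    rel <- (sp - w$param_start) %% 1
    wspan <- (w$param_end - w$param_start) %% 1
    if (wspan == 0) wspan <- 1
    sel <- rel < wspan
    sel <- sel & !is.na(corr$dx)
    if (!any(sel)) { empty[j] <- TRUE; disp[j] <- NA_real_; next }
    mdx <- mean(corr$dx[sel]); mdy <- mean(corr$dy[sel])
    disp[j] <- mdx * w$normal[1] + mdy * w$normal[2]
  }
  if (any(empty)) disp <- circ_fill_na(disp)
  attr(disp, "interpolated") <- empty
  disp
}

#' Integrate per-frame displacements into boundary translocation
#'
#' Translocation B(w, t) is the cumulative normal displacement of window w
#' since the constraint release: B = 0 at the release frame, forward partial
#' sums after it, and backward partial sums (negative time course) before
#' it, so the release position is the reference.
#'
#' @param disp_mat windows x (frames - 1) matrix; column j is the
#'   displacement from frame j to frame j + 1 (um).
#' @param release_index 0-based index of the release frame.
#' @param frame_times frame times in minutes (release at 0); optional, used
#'   to label the result.
#' @param arc_positions window arc positions (um); optional labels.
#' @return a `st_map` of kind "translocation" (windows x frames, um).
#' @export
integrate_translocation <- function(disp_mat, release_index,
                                    frame_times = NULL,
                                    arc_positions = NULL) {
  disp_mat <- as.matrix(disp_mat)
  n_f <- ncol(disp_mat) + 1L
  r0 <- as.integer(release_index) + 1L  # 1-based release frame
  stopifnot(r0 >= 1, r0 <= n_f)
  B <- matrix(0, nrow(disp_mat), n_f)
  if (r0 < n_f)
    for (t in (r0 + 1L):n_f) B[, t] <- B[, t - 1L] + disp_mat[, t - 1L]
  if (r0 > 1)
    for (t in (r0 - 1L):1L) B[, t] <- B[, t + 1L] - disp_mat[, t]
  if (is.null(frame_times)) frame_times <- seq_len(n_f) - r0
  if (is.null(arc_positions)) arc_positions <- seq_len(nrow(B))
  st_map(B, arc_positions, frame_times, kind = "translocation")
}
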