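#' Detect the closed cell boundary in one intensity frame
#'
#' Pixels are clustered into `k` intensity classes by k-means (initialized
#' deterministically on evenly spaced intensity quantiles); the union of
#' all classes brighter than the darkest class forms the candidate cell
#' mask. The mask is cleaned by a radius-1 morphological closing, holes
#' are filled, and the largest connected component is kept; its outer
#' boundary (marching-squares at the 0.5 level of the mask) is returned as
#' a sub-pixel contour in um, oriented counter-clockwise.
#'
#' The default `k = 3` admits a background class, a dim cell-periphery
#' class and a bright cell-body class; `k = 2` suffices for clean
#' synthetic frames.
#'
#' @param frame intensity matrix (rows = y, cols = x).
#' @param k number of intensity classes (default 3).
#' @param pixel_size um per pixel (contour is returned in um).
#' @param seed RNG seed (the quantile initialization is deterministic, but
#'   the seed guards the k-means fallback path).
#' @param min_area minimal component area in px (default 100).
#' @param frame_index frame index stamped on the contour.
#' @param resample_spacing point spacing of the returned contour in um;
#'   default half a pixel.
#' @return a `cell_contour`.
#' @export
detect_boundary <- function(frame, k = 3L, pixel_size = 1, seed = 1L,
                            min_area = 100L, frame_index = 0L,
                            resample_spacing = NULL) {
  stopifnot(is.matrix(frame), k >= 2)
  v <- as.numeric(frame)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("uniform frame: no object to detect")
  # centers evenly spaced over the intensity range: the darkest class then
  # owns the (dominant) background mode even when the cell covers only a
  # small fraction of the field, and intermediate classes catch the dim
  # cell periphery
  init_range <- rng[1] + (seq_len(k) - 0.5) / k * diff(rng)
  init_mass <- unique(stats::quantile(v, probs = (seq_len(k) - 0.5) / k,
                                      names = FALSE))
  set.seed(seed)
  km <- NULL
  for (init in list(init_range, init_mass)) {
    if (length(init) < k) next
    km <- tryCatch(
      stats::kmeans(matrix(v, ncol = 1), centers = matrix(init, ncol = 1),
                    iter.max = 100L, algorithm = "Lloyd"),
      error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km))
    stop("k-means failed: frame has too few distinct intensities for ",
         k, " classes")
  dark <- which.min(km$centers)
  mask <- matrix(km$cluster != dark, nrow(frame), ncol(frame))
  if (!any(mask)) stop("no pixel assigned to a non-background class")
  # radius-1 closing suppresses single-pixel gaps, then fill holes and
  # keep the largest component
  img <- EBImage::Image(t(mask * 1))  # EBImage is x-major
  img <- EBImage::closing(img, EBImage::makeBrush(3, shape = "box"))
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  tab <- table(lab[lab > 0])
  if (length(tab) == 0) stop("no connected object found")
  biggest <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) < min_area)
    stop(sprintf("largest component (%d px) below the minimum area (%d px)",
                 max(tab), min_area))
  comp <- t(as.matrix(lab) == biggest) * 1  # back to row-major
  # marching squares at 0.5 gives the sub-pixel outer boundary
  cl <- grDevices::contourLines(seq_len(nrow(comp)) - 1,
                                seq_len(ncol(comp)) - 1,
                                comp, levels = 0.5)
  if (length(cl) == 0) stop("no boundary found")
  len <- vapply(cl, function(l) sum(sqrt(diff(l$x)^2 + diff(l$y)^2)),
                numeric(1))
  l <- cl[[which.max(len)]]
  ct <- cell_contour(x = l$y * pixel_size, y = l$x * pixel_size,
                     frame_index = frame_index)
  if (is.null(resample_spacing)) resample_spacing <- pixel_size / 2
  resample_contour(ct, resample_spacing)
}
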