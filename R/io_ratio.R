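#' Two-channel fluorescence time-lapse movie
#'
#' Holds the donor (ECFP) and acceptor (FRET) channels of a biosensor
#' movie together with its physical calibration. Frame times are minutes
#' relative to the constraint release (release at t = 0).
#'
#' @param donor,acceptor lists of equal-shaped numeric matrices (intensity
#'   counts), one per frame.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval minutes per frame (> 0).
#' @param release_index 0-based index of the release frame.
#' @return An object of class `two_channel_movie`.
#' @export
two_channel_movie <- function(donor, acceptor, pixel_size, frame_interval,
                              release_index) {
  if (length(donor) != length(acceptor))
    stop("channel frame counts differ")
  dims <- lapply(c(donor, acceptor), dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("channel frames have mismatched dimensions")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  n <- length(donor)
  release_index <- as.integer(release_index)
  if (release_index < 0 || release_index >= n)
    stop("release_index out of range")
  structure(list(
    donor = donor, acceptor = acceptor,
    pixel_size = pixel_size,
    frame_times = (seq_len(n) - 1 - release_index) * frame_interval,
    frame_interval = frame_interval,
    release_index = release_index),
    class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$donor[[1]])
  cat(sprintf("<two_channel_movie> %d frames of %d x %d px, %.3g um/px, dt = %g min, release at frame %d\n",
              length(x$donor), d[1], d[2], x$pixel_size,
              x$frame_interval, x$release_index))
  invisible(x)
}

#' Load a two-channel movie from multi-page TIFF files
#'
#' Reads the donor and acceptor stacks (16-bit unsigned or 32-bit float
#' multi-page TIFF, one page per frame), keeping native intensity values.
#'
#' @param donor_path,acceptor_path TIFF file paths.
#' @param pixel_size um per pixel.
#' @param frame_interval minutes per frame.
#' @param release_index 0-based release frame index.
#' @return a `two_channel_movie` with
#'   `frame_times = (index - release_index) * frame_interval`.
#' @export
load_stack <- function(donor_path, acceptor_path, pixel_size,
                       frame_interval, release_index) {
  read_pages <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1]
      storage.mode(m) <- "double"
      m
    })
  }
  two_channel_movie(read_pages(donor_path), read_pages(acceptor_path),
                    pixel_size, frame_interval, release_index)
}

#' Write a two-channel movie as multi-page TIFF files
#'
#' Counts are rounded, clipped to [0, 65535] and stored as 16-bit pages,
#' so integer-valued movies round-trip pixel-identically through
#' [load_stack()].
#'
#' @param movie a `two_channel_movie`.
#' @param donor_path,acceptor_path output TIFF paths.
#' @export
write_stack <- function(movie, donor_path, acceptor_path) {
  wr <- function(frames, path) {
    pages <- lapply(frames, function(m) {
      m <- pmin(pmax(round(m), 0), 65535)
      m / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  wr(movie$donor, donor_path)
  wr(movie$acceptor, acceptor_path)
  invisible(c(donor_path, acceptor_path))
}

#' Subtract a per-frame percentile background
#'
#' For every frame and channel, the intensity at the given low percentile
#' of the whole frame is subtracted and negatives are clipped to zero. In
#' these fields of view the cell occupies a minority of pixels, so a low
#' percentile tracks the non-cell background without needing a
#' segmentation first.
#'
#' @param movie a `two_channel_movie`.
#' @param percentile background percentile as a fraction in (0, 0.5);
#'   default 0.05.
#' @return the background-subtracted `two_channel_movie`.
#' @export
subtract_background <- function(movie, percentile = 0.05) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 0.5)
    stop("background percentile must be in (0, 0.5)")
  sub1 <- function(m) {
    bg <- stats::quantile(m, percentile, names = FALSE, na.rm = TRUE)
    pmax(m - bg, 0)
  }
  movie$donor <- lapply(movie$donor, sub1)
  movie$acceptor <- lapply(movie$acceptor, sub1)
  movie
}

#' Estimate a minimum-intensity threshold from the background noise
#'
#' Default ratio masking threshold: 3 times the standard deviation of the
#' sub-percentile (background) pixels of the acceptor channel after
#' subtraction, suppressing unstable ratios in dim pixels.
#'
#' @param movie a background-subtracted `two_channel_movie`.
#' @param percentile the percentile used for the subtraction.
#' @param k multiplier (default 3).
#' @return threshold in intensity counts.
#' @export
default_min_intensity <- function(movie, percentile = 0.05, k = 3) {
  sds <- vapply(movie$acceptor, function(m) {
    cut <- stats::quantile(m, 2 * percentile, names = FALSE)
    stats::sd(m[m <= cut])
  }, numeric(1))
  max(k * stats::median(sds, na.rm = TRUE), .Machine$double.eps)
}

#' Compute the masked donor/acceptor ratio movie
#'
#' ratio = donor / acceptor at pixels where the acceptor intensity is at
#' least `min_intensity`; all other pixels are masked invalid (carried as
#' `NA`, never silently zero).
#'
#' @param movie a `two_channel_movie` (background-subtracted).
#' @param min_intensity acceptor intensity threshold (> 0).
#' @param median_radius optional median-filter radius in px applied to the
#'   ratio frames (0 = no smoothing, the default).
#' @return An object of class `ratio_movie`: `ratio` (list of matrices,
#'   `NA` where invalid), `valid` (list of logical matrices), plus the
#'   movie calibration fields.
#' @export
compute_ratio <- function(movie, min_intensity = NULL, median_radius = 0L) {
  if (is.null(min_intensity)) min_intensity <- default_min_intensity(movie)
  if (!is.numeric(min_intensity) || min_intensity <= 0)
    stop("min_intensity must be > 0")
  ratio <- vector("list", length(movie$donor))
  valid <- vector("list", length(movie$donor))
  for (i in seq_along(movie$donor)) {
    a <- movie$acceptor[[i]]; d <- movie$donor[[i]]
    v <- is.finite(a) & is.finite(d) & a >= min_intensity
    r <- matrix(NA_real_, nrow(a), ncol(a))
    r[v] <- d[v] / a[v]
    if (median_radius > 0) {
      filled <- r; filled[!v] <- stats::median(r[v], na.rm = TRUE)
      r2 <- as.matrix(EBImage::medianFilter(
        filled / max(filled, na.rm = TRUE), median_radius)) *
        max(filled, na.rm = TRUE)
      r[v] <- r2[v]
    }
    ratio[[i]] <- r; valid[[i]] <- v
  }
  structure(list(ratio = ratio, valid = valid,
                 pixel_size = movie$pixel_size,
                 frame_times = movie$frame_times,
                 frame_interval = movie$frame_interval,
                 release_index = movie$release_index,
                 min_intensity = min_intensity),
            class = "ratio_movie")
}

#' @export
print.ratio_movie <- function(x, ...) {
  v <- mean(vapply(x$valid, mean, numeric(1)))
  cat(sprintf("<ratio_movie> %d frames, %.0f%% valid pixels, min acceptor intensity %.3g\n",
              length(x$ratio), 100 * v, x$min_intensity))
  invisible(x)
}

#' Write a ratio movie as 32-bit float TIFFs
#'
#' The ratio stack is written as 32-bit float pages scaled by
#' `1 / scale` so values fit the [0, 1] TIFF float range (invalid pixels
#' as 0), alongside a validity-mask stack (1 = valid).
#'
#' @param rm a `ratio_movie`.
#' @param ratio_path,mask_path output TIFF paths.
#' @param scale divisor applied before writing (default 16).
#' @export
write_ratio_movie <- function(rm, ratio_path, mask_path, scale = 16) {
  pages <- lapply(rm$ratio, function(m) {
    m[!is.finite(m)] <- 0
    pmin(pmax(m / scale, 0), 1)
  })
  tiff::writeTIFF(pages, ratio_path, bits.per.sample = 32)
  masks <- lapply(rm$valid, function(v) (v * 1))
  tiff::writeTIFF(masks, mask_path, bits.per.sample = 8)
  invisible(c(ratio_path, mask_path))
}
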