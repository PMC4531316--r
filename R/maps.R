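#' Spatiotemporal edge map (windows x frames)
#'
#' Container for kymograph-style maps of a quantity sampled in windows
#' along the cell edge over time: the donor/acceptor emission ratio
#' (dimensionless) or the boundary translocation (um).
#'
#' @param values windows x frames numeric matrix; missing entries are `NA`.
#' @param arc_positions window arc positions along the edge (um).
#' @param frame_times frame times in minutes (release at 0).
#' @param kind `"ratio"` or `"translocation"`.
#' @return An object of class `st_map`.
#' @export
st_map <- function(values, arc_positions, frame_times,
                   kind = c("ratio", "translocation")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(arc_positions),
            ncol(values) == length(frame_times))
  structure(list(values = values,
                 arc_positions = as.numeric(arc_positions),
                 frame_times = as.numeric(frame_times),
                 kind = kind),
            class = "st_map")
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf("<st_map: %s> %d windows x %d frames, t = [%g, %g] min, %d missing\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$frame_times), max(x$frame_times),
              sum(is.na(x$values))))
  invisible(x)
}

#' Display a spatiotemporal map
#' @param x a `st_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.st_map <- function(x, ...) {
  graphics::image(x$frame_times, x$arc_positions, t(x$values),
                  xlab = "time since release (min)",
                  ylab = "edge position (um)",
                  main = paste("spatiotemporal map:", x$kind), ...)
  invisible(x)
}

#' Assemble per-frame window samples into a spatiotemporal map
#'
#' Stacks per-frame sample vectors column-wise. Isolated missing samples
#' (a gap of a single frame with both temporal neighbors present) are
#' linearly interpolated in time; longer gaps stay missing.
#'
#' @param per_frame_samples list of equal-length numeric vectors, one per
#'   frame (windows in rows).
#' @param frame_times frame times in minutes.
#' @param arc_positions window arc positions (um).
#' @param kind `"ratio"` or `"translocation"`.
#' @return a `st_map`.
#' @export
assemble_map <- function(per_frame_samples, frame_times, arc_positions,
                         kind = "ratio") {
  lens <- lengths(per_frame_samples)
  if (length(unique(lens)) != 1)
    stop("per-frame sample vectors have inconsistent lengths")
  vals <- do.call(cbind, per_frame_samples)
  n_f <- ncol(vals)
  if (n_f >= 3) {
    for (w in seq_len(nrow(vals))) {
      v <- vals[w, ]
      nas <- which(is.na(v))
      fix <- nas[nas > 1 & nas < n_f]
      fix <- fix[!is.na(v[fix - 1]) & !is.na(v[fix + 1])]
      if (length(fix)) {
        w1 <- (frame_times[fix + 1] - frame_times[fix]) /
          (frame_times[fix + 1] - frame_times[fix - 1])
        vals[w, fix] <- w1 * v[fix - 1] + (1 - w1) * v[fix + 1]
      }
    }
  }
  st_map(vals, arc_positions, frame_times, kind)
}

# maximal circular runs of TRUE in a logical vector; returns a list of
# integer index vectors
circular_runs <- function(lab) {
  n <- length(lab)
  if (all(lab)) return(list(seq_len(n)))
  if (!any(lab)) return(list())
  # rotate so position 1 is FALSE, find linear runs, rotate back
  s <- which(!lab)[1]
  rot <- c(s:n, seq_len(s - 1))
  lr <- rle(lab[rot])
  ends <- cumsum(lr$lengths)
  starts <- ends - lr$lengths + 1
  out <- list()
  for (k in which(lr$values)) {
    idx <- rot[starts[k]:ends[k]]
    out[[length(out) + 1]] <- idx
  }
  out
}

#' Classify edge windows into protrusive (P) and non-protrusive (NP) regions
#'
#' Each window's peak translocation is its maximum over post-release frames.
#' Windows whose peak is at least `threshold_fraction` of the cell's maximal
#' peak are labeled P (the rule is inclusive, so the window attaining the
#' maximum is always P). Circularly contiguous P runs shorter than
#' `min_region_windows` are relabeled NP; remaining runs separated by at
#' most `gap_merge` NP windows are merged; the surviving maximal runs are
#' the P-regions.
#'
#' @param transloc_map a `st_map` of kind "translocation".
#' @param threshold_fraction fraction of the maximal peak (default 0.75).
#' @param min_region_windows minimal region size in windows (default 3).
#' @param gap_merge merge P runs separated by at most this many NP windows
#'   (default 1).
#' @return An object of class `region_labeling`: `window_labels` (factor
#'   P/NP), `regions` (data.frame of start/end window indices and sizes,
#'   circular), `cell_class` ("polarized" iff exactly one region),
#'   `peaks`, `max_peak`.
#' @export
classify_regions <- function(transloc_map, threshold_fraction = 0.75,
                             min_region_windows = 3L, gap_merge = 1L) {
  stopifnot(inherits(transloc_map, "st_map"),
            transloc_map$kind == "translocation")
  post <- transloc_map$frame_times > 0
  if (!any(post)) stop("no post-release frames in map")
  peaks <- apply(transloc_map$values[, post, drop = FALSE], 1, max,
                 na.rm = TRUE)
  peaks[!is.finite(peaks)] <- NA_real_
  M <- max(peaks, na.rm = TRUE)
  if (!is.finite(M) || M <= 0)
    stop("no protrusion: all translocations are <= 0")
  lab <- !is.na(peaks) & peaks >= threshold_fraction * M
  n <- length(lab)
  # drop short runs
  for (run in circular_runs(lab))
    if (length(run) < min_region_windows) lab[run] <- FALSE
  # merge runs separated by small NP gaps
  if (any(lab) && !all(lab)) {
    np_runs <- circular_runs(!lab)
    for (run in np_runs)
      if (length(run) <= gap_merge) lab[run] <- TRUE
  }
  regions <- circular_runs(lab)
  if (length(regions) == 0)
    stop("no P-region found (all candidate runs below the minimal size)")
  reg_df <- data.frame(
    region_id = seq_along(regions),
    start = vapply(regions, function(r) r[1], numeric(1)),
    end = vapply(regions, function(r) r[length(r)], numeric(1)),
    n_windows = lengths(regions))
  structure(list(
    window_labels = factor(ifelse(lab, "P", "NP"), levels = c("P", "NP")),
    regions = reg_df,
    region_windows = regions,
    cell_class = if (length(regions) == 1) "polarized" else "non-polarized",
    peaks = peaks, max_peak = M,
    threshold_fraction = threshold_fraction),
    class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  cat(sprintf("<region_labeling> %d windows, %d P-region(s) -> %s cell; max peak %.2f um\n",
              length(x$window_labels), nrow(x$regions), x$cell_class,
              x$max_peak))
  invisible(x)
}

#' Classify a cell as polarized or non-polarized
#'
#' A cell is polarized iff its edge has exactly one P-region (a single
#' protrusion front); two or more P-regions make it non-polarized.
#'
#' @param labeling a `region_labeling` from [classify_regions()].
#' @return `"polarized"` or `"non-polarized"`.
#' @export
classify_cell <- function(labeling) {
  stopifnot(inherits(labeling, "region_labeling"))
  k <- nrow(labeling$regions)
  if (k == 0) stop("no P-regions: cannot classify cell")
  if (k == 1) "polarized" else "non-polarized"
}

#' Write a spatiotemporal map to CSV
#'
#' Rows are windows (first column the arc position in um), columns the
#' frame times in minutes.
#'
#' @param map a `st_map`.
#' @param path output file.
#' @export
write_st_map <- function(map, path) {
  df <- data.frame(arc_um = map$arc_positions, map$values)
  names(df) <- c("arc_um", sprintf("t_%g_min", map$frame_times))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spatiotemporal map written by [write_st_map()]
#' @param path CSV file.
#' @param kind map kind.
#' @return a `st_map`.
#' @export
read_st_map <- function(path, kind = "ratio") {
  df <- utils::read.csv(path, check.names = FALSE)
  times <- as.numeric(sub("^t_(-?[0-9.]+)_min$", "\\1",
                          names(df)[-1]))
  st_map(as.matrix(df[, -1, drop = FALSE]), df$arc_um, times, kind)
}
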