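#' Point correspondence between consecutive contours
#'
#' Chases each reference point of Gamma(t) through the intermediate
#' level-set contours by nearest-point projection, arriving on Gamma(t+1);
#' the arrival is recorded as a normalized 1-D arc-length parameter on the
#' target contour. Raw matches then pass through [correct_conflicts()],
#' which fills missing matches, removes crossings by circular isotonic
#' projection, and re-assigns direction conflicts.
#'
#' @param contour_t reference contour Gamma(t); its vertices are the
#'   reference points.
#' @param intermediates list of contours produced by [evolve()] for this
#'   frame pair (last one on Gamma(t+1)).
#' @param contour_next target contour Gamma(t+1).
#' @param miss_factor a projection jump larger than `miss_factor` times the
#'   median jump at that stage (with a 0.5 um floor) marks the match as
#'   missing.
#' @param correct apply [correct_conflicts()] before returning (default).
#' @return An object of class `correspondence_map`: list with
#'   `source_params`, `target_params` (normalized arc-length in [0,1)),
#'   `dx`, `dy` (displacement in um from each source point to its match),
#'   `flags` (factor: normal / corrected-missing / corrected-crossing /
#'   corrected-direction), plus the two contours.
#' @export
correspond <- function(contour_t, intermediates, contour_next,
                       miss_factor = 6, correct = TRUE) {
  px <- contour_t$x; py <- contour_t$y
  m <- length(px)
  missing <- rep(FALSE, m)
  chain <- c(intermediates, list(contour_next))
  for (ck in chain) {
    pr <- project_on_contour(ck, px, py)
    med <- stats::median(pr$dist)
    missing <- missing | pr$dist > pmax(miss_factor * med, 0.5)
    px <- pr$x; py <- pr$y
  }
  tp <- pr$param
  tp[missing] <- NA_real_
  map <- structure(list(
    source_params = arc_params(contour_t),
    target_params = tp,
    dx = pr$x - contour_t$x, dy = pr$y - contour_t$y,
    flags = factor(ifelse(missing, "corrected-missing", "normal"),
                   levels = c("normal", "corrected-missing",
                              "corrected-crossing", "corrected-direction")),
    contour_t = contour_t, contour_next = contour_next),
    class = "correspondence_map")
  map$dx[missing] <- NA_real_; map$dy[missing] <- NA_real_
  if (correct) correct_conflicts(map) else map
}

#' @export
print.correspondence_map <- function(x, ...) {
  tb <- table(x$flags)
  cat(sprintf("<correspondence_map> %d reference points; flags: %s\n",
              length(x$source_params),
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

# circular difference t - s wrapped to (-0.5, 0.5]
circ_diff <- function(t, s) {
  d <- (t - s) %% 1
  hi <- which(d > 0.5)
  d[hi] <- d[hi] - 1
  d
}

# linear interpolation of a vector over NA runs, treating the index axis as
# circular
circ_fill_na <- function(v) {
  n <- length(v)
  if (!anyNA(v)) return(v)
  ok <- which(!is.na(v))
  if (length(ok) == 0) stop("no valid values to interpolate from")
  for (i in which(is.na(v))) {
    before <- if (any(ok < i)) max(ok[ok < i]) else max(ok) - n
    after <- if (any(ok > i)) min(ok[ok > i]) else min(ok) + n
    ib <- ((before - 1) %% n) + 1; ia <- ((after - 1) %% n) + 1
    w <- (i - before) / (after - before)
    v[i] <- (1 - w) * v[ib] + w * v[ia]
  }
  v
}

#' Resolve geometric conflicts in a raw correspondence map
#'
#' Applies three corrections in order, flagging every touched point:
#' (a) missing matches are filled by circular linear interpolation of the
#' neighboring target parameters; (b) crossing pairs (locally inverted
#' target order) are replaced by the circular isotonic projection of the
#' target parameters, i.e. the nearest circularly non-decreasing sequence
#' (pool-adjacent-violators); (c) direction conflicts, where the
#' displacement vector points more than 90 degrees away from the locally
#' averaged motion, are re-assigned to the target parameter interpolated
#' from their neighbors. Displacement vectors are recomputed from the
#' corrected parameters.
#'
#' @param map a `correspondence_map` (possibly already corrected; a
#'   conflict-free map is returned unchanged).
#' @param neighborhood half-width (in points) of the circular window used
#'   for the local mean motion in the direction test.
#' @param min_motion direction conflicts are only tested where the local
#'   mean motion exceeds this magnitude (um); sub-pixel jitter of a static
#'   boundary is not a conflict.
#' @return the corrected `correspondence_map`.
#' @export
correct_conflicts <- function(map, neighborhood = 5L, min_motion = 0.25) {
  sp <- map$source_params
  tp <- map$target_params
  n <- length(sp)
  neighborhood <- max(1L, min(as.integer(neighborhood), (n - 1L) %/% 2L))
  flags <- as.character(map$flags)

  # work on the unwrapped offset d = (target - source) mod 1 in (-0.5, 0.5]
  d <- circ_diff(tp, sp)

  # (a) missing matches
  miss <- is.na(d)
  if (any(miss)) {
    d <- circ_fill_na(d)
    flags[miss] <- "corrected-missing"
  }

  # (b) crossings: isotonic projection of the unwrapped parameters
  u <- sp + d
  iso <- stats::isoreg(seq_len(n), u)$yf
  crossed <- abs(iso - u) > 1e-9
  if (any(crossed)) {
    flags[crossed & flags == "normal"] <- "corrected-crossing"
    u <- iso
  }
  tp <- u %% 1

  # (c) direction conflicts against the local mean displacement
  pt <- point_at_param(map$contour_next, tp)
  dx <- pt$x - map$contour_t$x
  dy <- pt$y - map$contour_t$y
  k <- 2L * neighborhood + 1L
  ker <- rep(1 / k, k)
  circ_smooth <- function(v) {
    ext <- c(v[(n - neighborhood + 1):n], v, v[1:neighborhood])
    stats::filter(ext, ker, sides = 2)[(neighborhood + 1):(neighborhood + n)]
  }
  mx <- circ_smooth(dx); my <- circ_smooth(dy)
  mag <- sqrt(mx^2 + my^2)
  bad_dir <- (dx * mx + dy * my) < 0 & mag > min_motion
  if (any(bad_dir)) {
    d2 <- circ_diff(tp, sp)
    d2[bad_dir] <- NA_real_
    d2 <- circ_fill_na(d2)
    u2 <- sp + d2
    u2 <- stats::isoreg(seq_len(n), u2)$yf
    tp <- u2 %% 1
    pt <- point_at_param(map$contour_next, tp)
    dx <- pt$x - map$contour_t$x
    dy <- pt$y - map$contour_t$y
    flags[bad_dir] <- "corrected-direction"
  }

  n_flagged <- sum(flags != "normal")
  if (n_flagged > n / 2)
    stop(sprintf("tracking quality: %d of %d correspondence points needed correction",
                 n_flagged, n))
  map$target_params <- tp
  map$dx <- dx; map$dy <- dy
  map$flags <- factor(flags, levels = levels(map$flags))
  map
}

#' Is a parameter sequence circularly non-decreasing?
#'
#' A sequence on the unit circle is circularly monotone if, reading the
#' wrapped differences around the circle, at most one step wraps past 1.
#'
#' @param params numeric vector of parameters in [0, 1).
#' @return logical.
#' @export
is_circularly_monotone <- function(params) {
  n <- length(params)
  if (n < 3) return(TRUE)
  dd <- diff(c(params, params[1])) %% 1
  # strictly decreasing steps appear as wrapped diffs summing above 1
  abs(sum(dd) - 1) < 1e-9
}

#' Map arc-length parameters through a correspondence
#'
#' Interpolates the source-to-target parameter mapping (circular, piecewise
#' linear between reference points) at arbitrary source parameters. Used to
#' propagate window boundaries from one frame to the next.
#'
#' @param map a corrected `correspondence_map`.
#' @param params source parameters in [0, 1).
#' @return target parameters in [0, 1).
#' @export
map_params <- function(map, params) {
  sp <- map$source_params
  d <- circ_diff(map$target_params, sp)
  # interpolate the offset d over the circular source axis
  ord <- order(sp)
  spo <- sp[ord]; do <- d[ord]
  spx <- c(spo[length(spo)] - 1, spo, spo[1] + 1)
  dx <- c(do[length(do)], do, do[1])
  off <- stats::approx(spx, dx, xout = params %% 1, rule = 2)$y
  (params + off) %% 1
}
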