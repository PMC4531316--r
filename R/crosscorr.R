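#' Global normalization constants for cross-correlation
#'
#' For each window, the time course is centered by its own mean; the
#' normalization constants are the maxima over windows of the centered
#' series' standard deviations, one for the ratio map and one for the
#' translocation map. Dividing every window's covariance by these shared
#' maxima (instead of the window's own standard deviations) down-weights
#' low-change windows, highlighting the regions with large signal and
#' motion changes.
#'
#' With `margin = "time"` the same construction runs on the transposed
#' maps: per-time-step spatial profiles are centered and the maxima over
#' time steps of their spatial standard deviations are returned, as used by
#' the spatial cross-correlation of line scans.
#'
#' @param ratio_map,transloc_map `st_map`s sharing both axes.
#' @param margin `"window"` (temporal CC norms) or `"time"` (spatial).
#' @return An object of class `global_norms`: `sigma_S_max`, `sigma_B_max`,
#'   `mu_S`, `mu_B`, `sd_S`, `sd_B`, `margin`.
#' @export
global_sigmas <- function(ratio_map, transloc_map,
                          margin = c("window", "time")) {
  margin <- match.arg(margin)
  stopifnot(all(dim(ratio_map$values) == dim(transloc_map$values)))
  S <- ratio_map$values; B <- transloc_map$values
  if (margin == "time") { S <- t(S); B <- t(B) }
  row_sd <- function(m) apply(m, 1, stats::sd, na.rm = TRUE)
  row_mu <- function(m) rowMeans(m, na.rm = TRUE)
  sd_S <- row_sd(S); sd_B <- row_sd(B)
  sig_S <- max(sd_S, na.rm = TRUE); sig_B <- max(sd_B, na.rm = TRUE)
  if (!is.finite(sig_S) || !is.finite(sig_B) || sig_S == 0 || sig_B == 0)
    stop("degenerate normalization: all series are constant")
  structure(list(sigma_S_max = sig_S, sigma_B_max = sig_B,
                 mu_S = row_mu(S), mu_B = row_mu(B),
                 sd_S = sd_S, sd_B = sd_B, margin = margin),
            class = "global_norms")
}

#' @export
print.global_norms <- function(x, ...) {
  cat(sprintf("<global_norms per %s> sigma_S_max = %.4g, sigma_B_max = %.4g (%d series)\n",
              x$margin, x$sigma_S_max, x$sigma_B_max, length(x$mu_S)))
  invisible(x)
}

cc_result <- function(offsets, values, unit) {
  fin <- is.finite(values)
  flag <- "ok"
  if (!any(fin)) {
    mv <- NA_real_; mo <- NA_real_
    flag <- "empty"
  } else {
    mv <- min(values[fin])
    cand <- which(fin & values <= mv + 1e-12)
    # ties: smallest |offset|, then positive offset
    cand <- cand[order(abs(offsets[cand]), -sign(offsets[cand]))]
    mo <- offsets[cand[1]]
    if (mv >= 0) flag <- "no-negative-minimum"
  }
  structure(list(offsets = offsets, values = values,
                 min_value = mv, min_offset = mo, flag = flag, unit = unit),
            class = "cc_result")
}

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf("<cc_result> %d offsets (%s); min %.3f at %g%s\n",
              length(x$offsets), x$unit, x$min_value, x$min_offset,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Temporal cross-correlation of ratio and translocation time courses
#'
#' Computes rho(tau) = Cov(S(t), B(t + tau)) / (sigma_S_max * sigma_B_max)
#' on the frame-time lag grid, where each series is centered once by its
#' full-length mean and the covariance at each lag runs over the
#' overlapping samples (truncation, no padding; pairs containing a missing
#' value are dropped). The normalization uses the map-wide maximal
#' standard deviations from [global_sigmas()], not the window's own.
#'
#' Sign convention: a positive `tau` at the minimum means the ratio change
#' precedes the translocation change.
#'
#' @param S,B numeric series of equal length (ratio, translocation).
#' @param norms a `global_norms` (margin "window"); `NULL` uses this pair's
#'   own standard deviations.
#' @param max_lag maximal |lag| in minutes; default half the series span.
#' @param frame_interval minutes per frame (default 1).
#' @param min_overlap lags with fewer overlapping pairs are omitted
#'   (default 5).
#' @return a `cc_result` with offsets in minutes.
#' @export
temporal_cc <- function(S, B, norms = NULL, max_lag = NULL,
                        frame_interval = 1, min_overlap = 5L) {
  n <- length(S)
  stopifnot(length(B) == n, n >= min_overlap)
  if (is.null(max_lag)) max_lag <- (n - 1) / 2 * frame_interval
  K <- floor(max_lag / frame_interval)
  K <- min(K, n - 1L)
  Sc <- S - mean(S, na.rm = TRUE)
  Bc <- B - mean(B, na.rm = TRUE)
  denom <- if (is.null(norms)) {
    stats::sd(S, na.rm = TRUE) * stats::sd(B, na.rm = TRUE)
  } else {
    norms$sigma_S_max * norms$sigma_B_max
  }
  lags <- (-K):K
  vals <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    if (k >= 0) { a <- Sc[seq_len(n - k)]; b <- Bc[seq_len(n - k) + k] }
    else { a <- Sc[seq_len(n + k) - k]; b <- Bc[seq_len(n + k)] }
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < min_overlap) next
    vals[i] <- sum(a[ok] * b[ok]) / (sum(ok) - 1) / denom
  }
  cc_result(lags * frame_interval, vals, unit = "min")
}

#' Spatial cross-correlation of edge line scans
#'
#' Correlates the ratio and translocation profiles along the edge at one
#' time step, as a function of circular window shift:
#' rho(s) = Cov(S(w), B(w + s mod n)) / (sigma_S_max * sigma_B_max), the
#' profiles centered by their own spatial means and the normalization taken
#' from the maxima over time steps of the spatial standard deviations
#' (`global_sigmas(..., margin = "time")`).
#'
#' @param ratio_line,transloc_line equal-length circular vectors over
#'   windows.
#' @param norms_spatial a `global_norms` with margin "time"; `NULL` uses
#'   the two profiles' own standard deviations.
#' @param max_shift maximal |shift| in windows; default floor(n/2).
#' @return a `cc_result` with offsets in windows.
#' @export
spatial_cc <- function(ratio_line, transloc_line, norms_spatial = NULL,
                       max_shift = NULL) {
  n <- length(ratio_line)
  stopifnot(length(transloc_line) == n)
  if (n < 8) stop("need at least 8 windows for spatial cross-correlation")
  if (is.null(max_shift)) max_shift <- floor(n / 2)
  Sc <- ratio_line - mean(ratio_line, na.rm = TRUE)
  Bc <- transloc_line - mean(transloc_line, na.rm = TRUE)
  denom <- if (is.null(norms_spatial)) {
    stats::sd(ratio_line, na.rm = TRUE) * stats::sd(transloc_line, na.rm = TRUE)
  } else {
    norms_spatial$sigma_S_max * norms_spatial$sigma_B_max
  }
  shifts <- (-max_shift):max_shift
  vals <- rep(NA_real_, length(shifts))
  for (i in seq_along(shifts)) {
    s <- shifts[i]
    b <- Bc[((seq_len(n) - 1 + s) %% n) + 1]
    ok <- is.finite(Sc) & is.finite(b)
    if (sum(ok) < 3) next
    vals[i] <- sum(Sc[ok] * b[ok]) / (sum(ok) - 1) / denom
  }
  cc_result(shifts, vals, unit = "windows")
}

#' Cross-correlation map over the whole cell edge
#'
#' Temporal flavor: one temporal CC curve per window, stacked along the
#' edge (rows = windows, columns = lags in minutes). Spatial flavor: one
#' spatial CC curve per time step (rows = time steps, columns = shifts in
#' windows). Rows whose series are entirely missing yield missing rows.
#'
#' @param ratio_map,transloc_map aligned `st_map`s.
#' @param norms matching `global_norms` (margin "window" for temporal,
#'   "time" for spatial); computed if `NULL`.
#' @param max_lag maximal lag (minutes) or shift (windows).
#' @param type `"temporal"` or `"spatial"`.
#' @return An object of class `cc_map`: `values` matrix, `offsets`,
#'   `axis_positions` (arc um or time min), `type`, plus per-row
#'   `min_value`/`min_offset`/`flag`.
#' @export
cc_map <- function(ratio_map, transloc_map, norms = NULL, max_lag = NULL,
                   type = c("temporal", "spatial")) {
  type <- match.arg(type)
  stopifnot(all(dim(ratio_map$values) == dim(transloc_map$values)))
  dtime <- if (length(ratio_map$frame_times) > 1)
    diff(ratio_map$frame_times)[1] else 1
  if (type == "temporal") {
    if (is.null(norms)) norms <- global_sigmas(ratio_map, transloc_map)
    rows <- seq_len(nrow(ratio_map$values))
    ccs <- lapply(rows, function(w) {
      S <- ratio_map$values[w, ]; B <- transloc_map$values[w, ]
      if (all(is.na(S)) || all(is.na(B))) return(NULL)
      temporal_cc(S, B, norms, max_lag, frame_interval = dtime)
    })
    axis <- ratio_map$arc_positions
  } else {
    if (is.null(norms))
      norms <- global_sigmas(ratio_map, transloc_map, margin = "time")
    rows <- seq_len(ncol(ratio_map$values))
    ccs <- lapply(rows, function(t) {
      S <- ratio_map$values[, t]; B <- transloc_map$values[, t]
      if (all(is.na(S)) || all(is.na(B))) return(NULL)
      spatial_cc(S, B, norms, max_shift = max_lag)
    })
    axis <- ratio_map$frame_times
  }
  proto <- ccs[[which(!vapply(ccs, is.null, logical(1)))[1]]]
  offsets <- proto$offsets
  vals <- matrix(NA_real_, length(rows), length(offsets))
  mv <- mo <- rep(NA_real_, length(rows))
  fl <- rep("empty", length(rows))
  for (i in seq_along(ccs)) {
    if (is.null(ccs[[i]])) next
    vals[i, ] <- ccs[[i]]$values
    mv[i] <- ccs[[i]]$min_value
    mo[i] <- ccs[[i]]$min_offset
    fl[i] <- ccs[[i]]$flag
  }
  structure(list(values = vals, offsets = offsets, axis_positions = axis,
                 type = type, min_value = mv, min_offset = mo, flag = fl,
                 unit = proto$unit),
            class = "cc_map")
}

#' @export
print.cc_map <- function(x, ...) {
  cat(sprintf("<cc_map: %s> %d rows x %d offsets (%s); min %.3f\n",
              x$type, nrow(x$values), length(x$offsets), x$unit,
              suppressWarnings(min(x$min_value, na.rm = TRUE))))
  invisible(x)
}

#' Most negative coefficient of a CC curve and its offset
#'
#' Ties are broken by the smallest absolute offset, then by the positive
#' offset. If the curve has no negative coefficient the result carries the
#' flag `"no-negative-minimum"` (the minimum is still reported).
#'
#' @param cc a `cc_result` with at least 3 offsets.
#' @return list with `min_value`, `min_offset`, `flag`.
#' @export
extract_minimum <- function(cc) {
  stopifnot(inherits(cc, "cc_result"), length(cc$offsets) >= 3)
  list(min_value = cc$min_value, min_offset = cc$min_offset, flag = cc$flag)
}
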