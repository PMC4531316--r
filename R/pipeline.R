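#' Pipeline run configuration
#'
#' Collects and validates every tunable parameter of the end-to-end
#' analysis. Defaults follow the package's standard analysis: 5th-percentile
#' background, k = 3 intensity classes on the acceptor channel, 0.5 um
#' sampling-band depth, 1.25 um window width, 75% peak-translocation
#' threshold with 3-window minimal regions, and 5000 bootstrap resamples.
#'
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval minutes per frame (> 0).
#' @param release_index 0-based release frame index.
#' @param background_percentile background percentile in (0, 0.5).
#' @param min_intensity acceptor threshold for valid ratio pixels; `NULL`
#'   = 3 x background SD, estimated from the movie.
#' @param k k-means intensity classes for boundary detection.
#' @param detect_channel `"acceptor"`, `"donor"` or `"sum"`.
#' @param min_area minimal cell area in px.
#' @param ref_spacing contour reference-point spacing in um.
#' @param n_intermediate intermediate level-set contours per frame pair.
#' @param depth sampling-band depth in um.
#' @param width sampling-window arc width in um.
#' @param threshold_fraction P-region peak threshold fraction.
#' @param min_region_windows minimal P-region size in windows.
#' @param gap_merge merge P runs separated by at most this many windows.
#' @param max_lag maximal CC lag in minutes; `NULL` = half the post-release
#'   duration.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for detection and bootstrap.
#' @return a validated `run_config` list.
#' @export
run_config <- function(pixel_size, frame_interval, release_index,
                       background_percentile = 0.05, min_intensity = NULL,
                       k = 3L, detect_channel = c("acceptor", "donor", "sum"),
                       min_area = 100L, ref_spacing = 0.5,
                       n_intermediate = 10L, depth = 0.5, width = 1.25,
                       threshold_fraction = 0.75, min_region_windows = 3L,
                       gap_merge = 1L, max_lag = NULL, n_boot = 5000L,
                       seed = 1L) {
  detect_channel <- match.arg(detect_channel)
  stopifnot(pixel_size > 0, frame_interval > 0, release_index >= 0,
            background_percentile > 0, background_percentile < 0.5,
            k >= 2, depth > 0, width > 0,
            threshold_fraction > 0, threshold_fraction <= 1,
            ref_spacing > 0, n_intermediate >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full edge-tracking and correlation pipeline
#'
#' Stages: load (or take) the two-channel movie; subtract background;
#' compute the masked ratio movie; detect the boundary in every frame;
#' evolve each boundary onto the next by the level-set method and build
#' the corrected point correspondences; partition the frame-0 edge into
#' sampling windows and propagate them through the correspondences; sample
#' the mean window ratio per frame and the per-pair window displacement;
#' integrate displacements into translocation; assemble the
#' spatiotemporal maps; classify P/NP regions and the cell; compute
#' globally normalized temporal and spatial CC maps and their minima; and
#' summarize group statistics.
#'
#' @param config a `run_config`.
#' @param donor_path,acceptor_path multi-page TIFF paths (used when
#'   `movie` is NULL).
#' @param movie optionally an in-memory `two_channel_movie`.
#' @param verbose print per-stage progress.
#' @return An object of class `edge_analysis`.
#' @export
run_pipeline <- function(config, donor_path = NULL, acceptor_path = NULL,
                         movie = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(movie)) {
    say("stage load: %s + %s", donor_path, acceptor_path)
    movie <- load_stack(donor_path, acceptor_path, config$pixel_size,
                        config$frame_interval, config$release_index)
  }
  n_f <- length(movie$donor)
  ps <- movie$pixel_size

  say("stage ratio")
  movie <- subtract_background(movie, config$background_percentile)
  rm <- compute_ratio(movie, config$min_intensity)

  say("stage detect (%d frames)", n_f)
  det_frame <- switch(config$detect_channel,
    acceptor = function(i) movie$acceptor[[i]],
    donor = function(i) movie$donor[[i]],
    sum = function(i) movie$acceptor[[i]] + movie$donor[[i]])
  contours <- vector("list", n_f)
  for (i in seq_len(n_f)) {
    ct <- detect_boundary(det_frame(i), k = config$k, pixel_size = ps,
                          seed = config$seed, min_area = config$min_area,
                          frame_index = i - 1L,
                          resample_spacing = config$ref_spacing)
    if (i == 1) ct <- set_contour_origin(ct)
    else ct <- set_contour_origin(ct, c(contours[[i - 1]]$x[1],
                                        contours[[i - 1]]$y[1]))
    contours[[i]] <- ct
  }

  say("stage track (%d pairs)", n_f - 1)
  corr <- vector("list", n_f - 1)
  for (i in seq_len(n_f - 1)) {
    inter <- evolve(contours[[i]], contours[[i + 1]],
                    n_intermediate = config$n_intermediate,
                    grid_spacing = ps)
    corr[[i]] <- correspond(contours[[i]], inter, contours[[i + 1]])
  }
  flag_counts <- table(unlist(lapply(corr, function(m)
    as.character(m$flags))))

  say("stage sample")
  per0 <- contour_perimeter(contours[[1]])
  n_w <- floor(per0 / config$width)
  if (n_w < 8) stop("cell too small for windowing")
  bounds <- (seq_len(n_w) - 1) / n_w
  arc_positions <- (bounds + 1 / (2 * n_w)) * per0
  ratio_samples <- vector("list", n_f)
  disp_mat <- matrix(NA_real_, n_w, n_f - 1)
  clamp <- max(3 * config$depth, 6 * ps)
  for (i in seq_len(n_f)) {
    fld <- signed_distance(contours[[i]], dim(movie$acceptor[[1]]), ps,
                           origin = c(0, 0), clamp = clamp)
    band <- build_band(contours[[i]], fld, config$depth)
    wins <- windows_from_bounds(contours[[i]], band, bounds)
    ratio_samples[[i]] <- sample_ratio(wins, rm$ratio[[i]], rm$valid[[i]])
    if (i < n_f) {
      disp_mat[, i] <- window_displacement(wins, corr[[i]])
      bounds <- map_params(corr[[i]], bounds)
    }
  }

  say("stage maps")
  ratio_map <- assemble_map(ratio_samples, movie$frame_times,
                            arc_positions, kind = "ratio")
  transloc_map <- integrate_translocation(disp_mat, config$release_index,
                                          movie$frame_times, arc_positions)

  say("stage classify")
  labeling <- classify_regions(transloc_map, config$threshold_fraction,
                               config$min_region_windows, config$gap_merge)

  say("stage correlate")
  max_lag <- config$max_lag
  if (is.null(max_lag)) max_lag <- max(movie$frame_times) / 2
  norms <- global_sigmas(ratio_map, transloc_map)
  cc_t <- cc_map(ratio_map, transloc_map, norms, max_lag, "temporal")
  norms_sp <- global_sigmas(ratio_map, transloc_map, margin = "time")
  cc_s <- cc_map(ratio_map, transloc_map, norms_sp, type = "spatial")

  say("stage stats")
  is_p <- labeling$window_labels == "P"
  neg <- cc_t$flag == "ok"
  lag_stats <- NULL
  if (sum(is_p & neg) >= 2)
    lag_stats <- bootstrap_mean(cc_t$min_offset[is_p & neg],
                                n_boot = config$n_boot, seed = config$seed)
  p_vs_np <- NULL
  if (sum(is_p) >= 2 && sum(!is_p) >= 2)
    p_vs_np <- compare_groups(cc_t$min_value[is_p], cc_t$min_value[!is_p])

  structure(list(
    contours = contours, correspondence = corr,
    flag_counts = flag_counts,
    ratio_map = ratio_map, transloc_map = transloc_map,
    labeling = labeling, cell_class = labeling$cell_class,
    norms = norms, cc_temporal = cc_t, cc_spatial = cc_s,
    lag_stats = lag_stats, p_vs_np_pvalue = p_vs_np,
    config = config,
    manifest = list(n_frames = n_f, n_windows = n_w,
                    pixel_size = ps, seed = config$seed,
                    timestamp_free = TRUE)),
    class = "edge_analysis")
}

#' @export
print.edge_analysis <- function(x, ...) {
  cat(sprintf("<edge_analysis> %d frames, %d windows; cell %s (%d P-region(s))\n",
              x$manifest$n_frames, x$manifest$n_windows, x$cell_class,
              nrow(x$labeling$regions)))
  if (!is.null(x$lag_stats))
    cat(sprintf("  P-window CC lag: mean %.2f min (95%% CI %.2f..%.2f, n=%d)\n",
                x$lag_stats$mean, x$lag_stats$lower, x$lag_stats$upper,
                x$lag_stats$n))
  invisible(x)
}

#' @export
summary.edge_analysis <- function(object, ...) {
  x <- object
  pk <- x$labeling$peaks
  cat("Edge analysis summary\n")
  print(x)
  cat(sprintf("  max window translocation: %.2f um\n", x$labeling$max_peak))
  cat(sprintf("  correspondence flags: %s\n",
              paste(names(x$flag_counts), x$flag_counts, sep = "=",
                    collapse = ", ")))
  if (!is.null(x$p_vs_np_pvalue))
    cat(sprintf("  P vs NP CC-minimum t-test p = %.3g\n", x$p_vs_np_pvalue))
  invisible(list(max_peak = x$labeling$max_peak, peaks = pk,
                 cell_class = x$cell_class))
}

#' Plot the ratio and translocation maps of an analysis
#' @param x an `edge_analysis`.
#' @param ... passed on to [plot.st_map()].
#' @export
plot.edge_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$ratio_map, ...)
  plot(x$transloc_map, ...)
  invisible(x)
}

#' Generate a registered synthetic scenario and write it to disk
#'
#' Image-level scenarios are written as two multi-page TIFFs plus a JSON
#' config and the truth contours as CSV; map-level scenarios are written
#' as ratio/translocation CSV maps plus a JSON truth record. Identical
#' (scenario, seed) invocations write identical files.
#'
#' @param scenario_name a registered scenario name (see [get_scenario()]).
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
run_synthetic <- function(scenario_name, seed, outdir) {
  sc <- get_scenario(scenario_name)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  f <- function(nm) file.path(outdir, nm)
  if (sc$level == "image") {
    gen <- generate_movie(sc, seed)
    write_stack(gen$movie, f("donor.tif"), f("acceptor.tif"))
    cfg <- list(scenario = sc$name, seed = seed,
                pixel_size_um = sc$pixel_size,
                frame_interval_min = sc$frame_interval,
                release_index = sc$release_index)
    jsonlite::write_json(cfg, f("config.json"), auto_unbox = TRUE)
    tr <- do.call(rbind, lapply(seq_along(gen$truth$contours), function(i) {
      ct <- gen$truth$contours[[i]]
      data.frame(frame_index = i - 1L,
                 point_index = seq_along(ct$x) - 1L,
                 x_um = ct$x, y_um = ct$y)
    }))
    utils::write.csv(tr, f("truth_contours.csv"), row.names = FALSE)
    paths <- c(f("donor.tif"), f("acceptor.tif"), f("config.json"),
               f("truth_contours.csv"))
  } else {
    gen <- generate_maps(sc, seed)
    write_st_map(gen$ratio, f("ratio_map.csv"))
    write_st_map(gen$translocation, f("translocation_map.csv"))
    jsonlite::write_json(gen$truth, f("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    paths <- c(f("ratio_map.csv"), f("translocation_map.csv"),
               f("truth.json"))
  }
  invisible(paths)
}

#' Export contours as CSV
#' @param contours list of `cell_contour`s.
#' @param path output CSV.
#' @export
write_contours_csv <- function(contours, path) {
  df <- do.call(rbind, lapply(contours, function(ct)
    data.frame(frame_index = ct$frame_index,
               point_index = seq_along(ct$x) - 1L,
               x_um = ct$x, y_um = ct$y)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a correspondence map as CSV
#' @param corr a `correspondence_map`.
#' @param frame_index frame index of the source contour.
#' @param path output CSV.
#' @export
write_correspondence_csv <- function(corr, frame_index, path) {
  df <- data.frame(frame_index = frame_index,
                   source_param = corr$source_params,
                   target_param = corr$target_params,
                   dx_um = corr$dx, dy_um = corr$dy,
                   flag = as.character(corr$flags))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
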