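#' Registered synthetic scenarios
#'
#' Ground-truthed synthetic inputs at two levels, emulating an endothelial
#' cell released from an elliptic micropatterned constraint (20 um x 80 um
#' well): after the release frame one or more angular sectors protrude
#' while the emission ratio decreases in those sectors with a programmed
#' temporal lead. The translocation and the ratio drop share the same
#' logistic time course g, offset by the lead tau, so tau is exactly the
#' lag recoverable by cross-correlation.
#'
#' * `POL-A` (map level): 64 windows, 50 frames at 1 min, release at frame
#'   10; one sector (windows 21:32, 1-based), max advance 25 um, lead
#'   tau = 10 min, ratio 1.0 -> 0.85 in the sector, noise 5% of range.
#' * `POL-B` (map level, ensemble): 3 cells x 40 windows, tau = 15 min,
#'   per-cell advance jitter +/- 10%, otherwise as POL-A.
#' * `POL-C` (image level): 256 x 320 px at 0.5 um/px, 20 x 80 um ellipse,
#'   25 frames at 2 min, release at frame 3; one end sector advances 30 um
#'   within ~10 min after release (logistic, midpoint 5 min, steepness
#'   1 min); acceptor 1000 counts inside / 50 outside, donor =
#'   ratio x acceptor with ratio 1.0 in the body and 0.85 in the
#'   protruding sector (lead 4 min); Poisson shot noise plus Gaussian read
#'   noise (SD 10 counts).
#' * `NP-A` (map level): three sectors of 8 windows each, tau = 0,
#'   max advance 30 um.
#'
#' @param name scenario name.
#' @return a scenario parameter list.
#' @export
get_scenario <- function(name) {
  reg <- list(
    "POL-A" = list(
      name = "POL-A", level = "map",
      n_windows = 64L, n_frames = 50L, frame_interval = 1,
      release_index = 10L,
      sectors = list(list(windows = 21:32, max_advance = 25)),
      ratio_floor = 0.85,
      advance_midpoint = 15, steepness = 0.4, tau = 10,
      noise_sd = 0.05, n_cells = 1L, jitter = 0),
    "POL-B" = list(
      name = "POL-B", level = "map",
      n_windows = 40L, n_frames = 50L, frame_interval = 1,
      release_index = 10L,
      sectors = list(list(windows = 17:24, max_advance = 25)),
      ratio_floor = 0.85,
      advance_midpoint = 20, steepness = 0.4, tau = 15,
      noise_sd = 0.05, n_cells = 3L, jitter = 0.10),
    "NP-A" = list(
      name = "NP-A", level = "map",
      n_windows = 64L, n_frames = 50L, frame_interval = 1,
      release_index = 10L,
      sectors = list(list(windows = 5:12, max_advance = 30),
                     list(windows = 27:34, max_advance = 30),
                     list(windows = 49:56, max_advance = 30)),
      ratio_floor = 0.85,
      advance_midpoint = 15, steepness = 0.4, tau = 0,
      noise_sd = 0.05, n_cells = 1L, jitter = 0),
    "POL-C" = list(
      name = "POL-C", level = "image",
      shape = c(256L, 320L), pixel_size = 0.5,
      n_frames = 25L, frame_interval = 2, release_index = 3L,
      semi_axes = c(40, 10),   # um: half of 80 x 20 um well
      sector_center = 0, sector_halfwidth = 0.6,  # radians on the +x end
      max_advance = 30, advance_midpoint = 5, steepness = 1,
      ratio_floor = 0.85, tau = 4,
      fg_counts = 1000, bg_counts = 50, read_noise_sd = 10))
  if (!name %in% names(reg)) stop("unknown scenario: ", name)
  reg[[name]]
}

# shared logistic time-course shape
logistic_g <- function(x) 1 / (1 + exp(-x))

#' Generate window-level spatiotemporal maps with known ground truth
#'
#' Builds the ratio and translocation maps of one synthetic cell directly
#' at the window level:
#' B(w, t) = advance(w) g((t - advance_midpoint)/steepness) in sector
#' windows (0 elsewhere) and
#' S(w, t) = 1 - drop(w) g((t - drop_midpoint)/steepness), with
#' drop_midpoint = advance_midpoint - tau, plus i.i.d. Gaussian noise
#' scaled to each map's dynamic range. Identical (scenario, seed, cell)
#' give identical maps.
#'
#' @param scenario a map-level scenario from [get_scenario()] (or a
#'   scenario name).
#' @param seed integer seed for the noise (and the per-cell jitter).
#' @param cell cell number within an ensemble scenario (applies the
#'   per-cell advance jitter); default 1.
#' @return list with `ratio` and `translocation` (`st_map`s) and `truth`
#'   (tau, sector window indices, advances, midpoints).
#' @export
generate_maps <- function(scenario, seed = 1L, cell = 1L) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  if (scenario$level != "map") stop("scenario is not map-level")
  sc <- scenario
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed) + 7919L * (as.integer(cell) - 1L))
  times <- (seq_len(sc$n_frames) - 1 - sc$release_index) * sc$frame_interval
  drop_mid <- sc$advance_midpoint - sc$tau
  gB <- function(t) logistic_g((t - sc$advance_midpoint) / sc$steepness)
  gS <- function(t) logistic_g((t - drop_mid) / sc$steepness)
  B <- matrix(0, sc$n_windows, sc$n_frames)
  S <- matrix(1, sc$n_windows, sc$n_frames)
  drop <- 1 - sc$ratio_floor
  sector_windows <- integer(0)
  advances <- numeric(sc$n_windows)
  for (sec in sc$sectors) {
    adv <- sec$max_advance
    if (sc$jitter > 0) adv <- adv * (1 + sc$jitter * stats::runif(1, -1, 1))
    B[sec$windows, ] <- rep(adv * gB(times), each = length(sec$windows))
    S[sec$windows, ] <- rep(1 - drop * gS(times),
                            each = length(sec$windows))
    sector_windows <- c(sector_windows, sec$windows)
    advances[sec$windows] <- adv
  }
  if (sc$noise_sd > 0) {
    max_adv <- max(vapply(sc$sectors, function(s) s$max_advance,
                          numeric(1)))
    B <- B + matrix(stats::rnorm(length(B), sd = sc$noise_sd * max_adv),
                    nrow(B))
    S <- S + matrix(stats::rnorm(length(S), sd = sc$noise_sd * drop),
                    nrow(S))
  }
  arc <- (seq_len(sc$n_windows) - 0.5) * 1.25  # nominal 1.25-um windows
  list(ratio = st_map(S, arc, times, "ratio"),
       translocation = st_map(B, arc, times, "translocation"),
       truth = list(tau = sc$tau, sector_windows = sort(sector_windows),
                    advances = advances,
                    advance_midpoint = sc$advance_midpoint,
                    drop_midpoint = drop_mid, seed = seed, cell = cell))
}

# analytic boundary of the synthetic cell at time t (um): ellipse offset
# along its outward normals by the sector advance profile
synthetic_boundary <- function(sc, t_min, center, n_theta = 1024L) {
  th <- (seq_len(n_theta) - 1) / n_theta * 2 * pi
  a <- sc$semi_axes[1]; b <- sc$semi_axes[2]
  ex <- center[1] + a * cos(th); ey <- center[2] + b * sin(th)
  nx <- b * cos(th); ny <- a * sin(th)
  nl <- sqrt(nx^2 + ny^2); nx <- nx / nl; ny <- ny / nl
  w <- sectors_weight(th, sc$sector_center, sc$sector_halfwidth)
  A <- sc$max_advance *
    logistic_g((t_min - sc$advance_midpoint) / sc$steepness)
  list(x = ex + A * w * nx, y = ey + A * w * ny, theta = th, w = w, A = A)
}

# profile of one or several protruding sectors (element-wise maximum)
sectors_weight <- function(theta, centers, halfwidths) {
  halfwidths <- rep_len(halfwidths, length(centers))
  w <- numeric(length(theta))
  for (i in seq_along(centers))
    w <- pmax(w, sector_weight(theta, centers[i], halfwidths[i]))
  w
}

# sector advance profile: flat core (the stated advance is attained across
# a finite arc, not at a single point) with smooth cosine-squared shoulders
# so the offset boundary stays simple
sector_weight <- function(theta, center, halfwidth, flat_frac = 0.35) {
  d <- abs((theta - center + pi) %% (2 * pi) - pi)
  core <- flat_frac * halfwidth
  w <- numeric(length(theta))
  w[d <= core] <- 1
  sh <- d > core & d < halfwidth
  w[sh] <- cos(pi * (d[sh] - core) / (2 * (halfwidth - core)))^2
  w
}

#' Render a full two-channel synthetic movie with analytic ground truth
#'
#' The cell region at each frame is the initial ellipse grown outward
#' along its local normals by the sector advance profile. Channels are
#' rendered with area-fraction anti-aliasing at the boundary (a linear
#' one-pixel coverage ramp on the signed distance), so edges are
#' sub-pixel: acceptor = bg + (fg - bg) x coverage, donor =
#' ratio_field x acceptor, with the ratio at the floor value in the
#' protruding sector following the ratio time course. Poisson shot noise
#' and Gaussian read noise are added and counts are rounded to integers
#' (so written movies round-trip exactly).
#'
#' @param scenario an image-level scenario from [get_scenario()] (or its
#'   name).
#' @param seed integer noise seed.
#' @param noise apply noise (default TRUE; FALSE gives clean frames for
#'   geometric tests).
#' @return list with `movie` (a `two_channel_movie`), `truth` (list:
#'   per-frame analytic `contours`, `theta` grid, sector weights `w`,
#'   per-frame advance `A_t`, `tau`, ellipse `center` and `semi_axes`).
#' @export
generate_movie <- function(scenario, seed = 11L, noise = TRUE) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  if (scenario$level != "image") stop("scenario is not image-level")
  sc <- scenario
  nr <- sc$shape[1]; nc <- sc$shape[2]; ps <- sc$pixel_size
  center <- c((nc - 1) / 2 * ps, (nr - 1) / 2 * ps)
  # sector must stay on-image
  if (center[1] + sc$semi_axes[1] + sc$max_advance > (nc - 1) * ps - 4 * ps ||
      center[2] + sc$semi_axes[2] + sc$max_advance > (nr - 1) * ps - 4 * ps)
    stop("sector advance pushes the boundary off-image")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  times <- (seq_len(sc$n_frames) - 1 - sc$release_index) * sc$frame_interval
  drop_mid <- sc$advance_midpoint - sc$tau
  xs <- (seq_len(nc) - 1) * ps; ys <- (seq_len(nr) - 1) * ps
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, nc), nr, nc)
  th_pix <- atan2((Y - center[2]) / sc$semi_axes[2],
                  (X - center[1]) / sc$semi_axes[1])
  w_pix <- sectors_weight(th_pix, sc$sector_center, sc$sector_halfwidth)
  donor <- acceptor <- vector("list", sc$n_frames)
  contours <- vector("list", sc$n_frames)
  A_t <- numeric(sc$n_frames)
  for (i in seq_len(sc$n_frames)) {
    bd <- synthetic_boundary(sc, times[i], center)
    A_t[i] <- bd$A
    ct <- cell_contour(bd$x, bd$y, frame_index = i - 1L)
    contours[[i]] <- ct
    ctr <- resample_contour(ct, 1.0)  # coarser polyline for the distance
    fld <- signed_distance(ctr, c(nr, nc), ps, origin = c(0, 0),
                           clamp = 3)
    cov <- pmin(pmax(0.5 - fld$phi / ps, 0), 1)
    acc <- sc$bg_counts + (sc$fg_counts - sc$bg_counts) * cov
    rfield <- 1 - (1 - sc$ratio_floor) * w_pix *
      logistic_g((times[i] - drop_mid) / sc$steepness)
    don <- rfield * acc
    if (noise) {
      acc <- stats::rpois(length(acc), acc) +
        stats::rnorm(length(acc), sd = sc$read_noise_sd)
      don <- stats::rpois(length(don), don) +
        stats::rnorm(length(don), sd = sc$read_noise_sd)
    }
    acceptor[[i]] <- matrix(pmax(round(acc), 0), nr, nc)
    donor[[i]] <- matrix(pmax(round(don), 0), nr, nc)
  }
  movie <- two_channel_movie(donor, acceptor, ps, sc$frame_interval,
                             sc$release_index)
  bd0 <- synthetic_boundary(sc, times[1], center)
  list(movie = movie,
       truth = list(contours = contours, theta = bd0$theta, w = bd0$w,
                    A_t = A_t, tau = sc$tau, center = center,
                    semi_axes = sc$semi_axes, seed = seed))
}
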