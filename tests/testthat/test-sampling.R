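band_setup <- function(r = 20, depth = 2, h = 0.5, n = 512) {
  ct <- circle_contour(r, r + 5, r + 5, n = n)
  f <- signed_distance(ct, grid_spacing = h)
  list(ct = ct, f = f, band = build_band(ct, f, depth))
}

test_that("the band of a circle has the annulus area", {
  s <- band_setup(r = 20, depth = 2, h = 0.5)
  area <- nrow(s$band) * s$f$h^2
  expect_lt(abs(area - pi * (20^2 - 18^2)) / (pi * (20^2 - 18^2)), 0.1)
  expect_error(build_band(s$ct, s$f, 0), "depth")
  expect_error(build_band(s$ct, s$f, -1), "depth")
})

test_that("band pixels are inside the cell within the depth, by brute force", {
  ct <- random_star_polygon(13)
  f <- signed_distance(ct, grid_spacing = 0.5)
  band <- build_band(ct, f, 1.5)
  idx <- seq(1, nrow(band), length.out = min(60, nrow(band)))
  px <- band$x[idx]; py <- band$y[idx]
  expect_true(all(bf_inside(ct, px, py)))
  expect_true(all(bf_dist(ct, px, py) < 1.5))
})

test_that("windows split the perimeter by the floor rule", {
  # perimeter 10, width 3 -> 3 windows of arc width 10/3
  sq <- square_contour(2.5)
  f <- signed_distance(sq, grid_spacing = 0.05)
  band <- build_band(sq, f, 0.3)
  expect_error(partition_windows(sq, band, 3), "8 windows")
  wins <- partition_windows(sq, band, 1)
  expect_length(wins, 10)
  widths <- vapply(wins, function(w) w$arc_width, numeric(1))
  expect_equal(widths, rep(1, 10), tolerance = 1e-9)
})

test_that("window masks partition the band", {
  s <- band_setup(r = 10, depth = 1, h = 0.25, n = 256)
  wins <- partition_windows(s$ct, s$band, 1.25)
  pix <- unlist(lapply(wins, function(w) w$pixels))
  expect_setequal(pix, seq_len(nrow(s$band)))
  expect_equal(length(pix), length(unique(pix)))
})

test_that("window means sample the ratio field and propagate missingness", {
  s <- band_setup(r = 10, depth = 1, h = 0.25, n = 256)
  wins <- partition_windows(s$ct, s$band, 1.25)
  shape <- dim(s$f$phi)
  uni <- matrix(1.7, shape[1], shape[2])
  expect_equal(sample_ratio(wins, uni), rep(1.7, length(wins)))
  # sector at 0.8: pixels in the +x half-plane through the center
  X <- s$f$origin[1] + (matrix(rep(seq_len(shape[2]), each = shape[1]),
                               shape[1]) - 1) * s$f$h
  Y <- s$f$origin[2] + (matrix(rep(seq_len(shape[1]), shape[2]),
                               shape[1]) - 1) * s$f$h
  ang <- atan2(Y - 15, X - 15)
  fld <- matrix(1.0, shape[1], shape[2])
  fld[abs(ang) < pi / 4] <- 0.8
  m <- sample_ratio(wins, fld)
  ctr_ang <- vapply(wins, function(w)
    atan2(w$centroid[2] - 15, w$centroid[1] - 15), numeric(1))
  core <- abs(ctr_ang) < pi / 4 - 0.15
  outside <- abs(ctr_ang) > pi / 4 + 0.15
  expect_true(all(abs(m[core] - 0.8) < 1e-9))
  expect_true(all(abs(m[outside] - 1.0) < 1e-9))
  # fully invalid window stays missing, not zero
  valid <- matrix(TRUE, shape[1], shape[2])
  for (p in wins[[3]]$pixels)
    valid[s$band$row[p], s$band$col[p]] <- FALSE
  m2 <- sample_ratio(wins, uni, valid)
  expect_true(is.na(m2[3]))
  expect_equal(m2[-3], rep(1.7, length(wins) - 1))
})

test_that("window displacements project motion on the outward normal", {
  a <- circle_contour(10, 15, 15, n = 200)
  b <- circle_contour(12, 15, 15, n = 200, frame_index = 1L)
  inter <- evolve(a, b, n_intermediate = 8, grid_spacing = 0.25)
  cm <- correspond(a, inter, b)
  f <- signed_distance(a, grid_spacing = 0.25)
  band <- build_band(a, f, 1)
  wins <- partition_windows(a, band, 1.25)
  disp <- window_displacement(wins, cm)
  expect_true(all(abs(disp - 2) < 0.3))
  # static boundary: all displacements ~0
  inter0 <- evolve(a, a, n_intermediate = 2, grid_spacing = 0.25)
  cm0 <- correspond(a, inter0, a)
  disp0 <- window_displacement(wins, cm0)
  expect_true(all(abs(disp0) < 0.2))
})

test_that("area change matches perimeter-weighted window displacements", {
  a <- circle_contour(10, 15, 15, n = 200)
  b <- circle_contour(12, 15, 15, n = 200, frame_index = 1L)
  inter <- evolve(a, b, n_intermediate = 8, grid_spacing = 0.25)
  cm <- correspond(a, inter, b)
  f <- signed_distance(a, grid_spacing = 0.25)
  wins <- partition_windows(a, build_band(a, f, 1), 1.25)
  disp <- window_displacement(wins, cm)
  est <- sum(disp * vapply(wins, function(w) w$arc_width, numeric(1)) *
               (1 + disp / (2 * 10)))  # mid-radius arc correction
  dA <- contour_area(b) - contour_area(a)
  expect_lt(abs(est - dA) / dA, 0.1)
})

test_that("translocation is the release-anchored cumulative sum", {
  d <- matrix(1, 1, 4)
  B <- integrate_translocation(d, release_index = 0)
  expect_equal(B$values[1, ], c(0, 1, 2, 3, 4))
  z <- integrate_translocation(matrix(0, 2, 4), 0)
  expect_true(all(z$values == 0))
  # backward partial sums before the release frame
  B2 <- integrate_translocation(matrix(1, 1, 4), release_index = 2)
  expect_equal(B2$values[1, ], c(-2, -1, 0, 1, 2))
  # random table equals brute-force prefix sums
  set.seed(8)
  dm <- matrix(stats::rnorm(5 * 9), 5, 9)
  B3 <- integrate_translocation(dm, release_index = 4)
  for (w in 1:5) {
    expect_equal(B3$values[w, 5], 0)
    for (t in 6:10)
      expect_equal(B3$values[w, t], sum(dm[w, 5:(t - 1)]), tolerance = 1e-12)
    for (t in 1:4)
      expect_equal(B3$values[w, t], -sum(dm[w, t:4]), tolerance = 1e-12)
  }
})

test_that("integrating in two stages equals integrating once", {
  set.seed(9)
  dm <- matrix(stats::rnorm(3 * 8), 3, 8)
  whole <- integrate_translocation(dm, 0)$values
  first <- integrate_translocation(dm[, 1:5, drop = FALSE], 0)$values
  second <- integrate_translocation(dm[, 6:8, drop = FALSE], 0)$values
  stitched <- cbind(first, second[, -1, drop = FALSE] + first[, 6])
  expect_equal(stitched, whole, tolerance = 1e-12)
})
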