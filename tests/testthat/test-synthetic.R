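test_that("noiseless POL-A maps hit their programmed extremes exactly", {
  sc <- get_scenario("POL-A")
  sc$noise_sd <- 0
  g <- generate_maps(sc, seed = 7)
  w <- g$truth$sector_windows
  expect_equal(unname(g$translocation$values[w, 50]), rep(25, length(w)),
               tolerance = 1e-6)
  expect_equal(min(g$ratio$values), 0.85, tolerance = 1e-6)
  expect_true(all(g$translocation$values[setdiff(1:64, w), ] == 0))
})

test_that("map generation is reproducible given (scenario, seed)", {
  g1 <- generate_maps("POL-A", seed = 7)
  g2 <- generate_maps("POL-A", seed = 7)
  expect_identical(g1$ratio$values, g2$ratio$values)
  expect_identical(g1$translocation$values, g2$translocation$values)
  g3 <- generate_maps("POL-A", seed = 8)
  expect_false(identical(g1$ratio$values, g3$ratio$values))
})

test_that("the programmed lead is the CC-recoverable lag in the noiseless limit", {
  sc <- get_scenario("POL-A")
  sc$noise_sd <- 0
  g <- generate_maps(sc, seed = 1)
  nm <- global_sigmas(g$ratio, g$translocation)
  for (w in g$truth$sector_windows) {
    cc <- temporal_cc(g$ratio$values[w, ], g$translocation$values[w, ],
                      nm, max_lag = 19, frame_interval = 1)
    expect_equal(cc$min_offset, g$truth$tau)
  }
})

test_that("unknown scenarios are rejected and levels enforced", {
  expect_error(get_scenario("NOPE"), "unknown scenario")
  expect_error(generate_maps("POL-C", 1), "map-level")
  expect_error(generate_movie("POL-A", 1), "image-level")
})

small_image_scenario <- function(n_frames = 4L) {
  sc <- get_scenario("POL-C")
  sc$shape <- c(96L, 160L)
  sc$semi_axes <- c(25, 8)
  sc$max_advance <- 10
  sc$n_frames <- n_frames
  sc$release_index <- 1L
  sc
}

test_that("the rendered release-frame boundary is the analytic ellipse", {
  sc <- small_image_scenario()
  gen <- generate_movie(sc, seed = 1, noise = FALSE)
  ell <- ellipse_contour(sc$semi_axes[1], sc$semi_axes[2],
                         gen$truth$center[1], gen$truth$center[2], n = 512)
  rel <- gen$truth$contours[[sc$release_index + 1]]
  expect_lt(hausdorff_distance(rel, ell), 0.5 * sc$pixel_size)
})

test_that("the final sector boundary advances by the programmed amount", {
  sc <- small_image_scenario(n_frames = 10L)
  gen <- generate_movie(sc, seed = 1, noise = FALSE)
  last <- gen$truth$contours[[10]]
  tip_x <- max(last$x)
  expect_equal(tip_x - (gen$truth$center[1] + sc$semi_axes[1]),
               sc$max_advance, tolerance = 0.2)
})

test_that("movie rendering is reproducible and integer-valued", {
  sc <- small_image_scenario()
  g1 <- generate_movie(sc, seed = 4)
  g2 <- generate_movie(sc, seed = 4)
  expect_identical(g1$movie$acceptor, g2$movie$acceptor)
  expect_identical(g1$movie$donor, g2$movie$donor)
  expect_true(all(g1$movie$acceptor[[1]] == round(g1$movie$acceptor[[1]])))
})

test_that("boundary detection recovers the truth contours of clean frames", {
  sc <- small_image_scenario()
  gen <- generate_movie(sc, seed = 1, noise = FALSE)
  for (i in c(1, 4)) {
    ct <- detect_boundary(gen$movie$acceptor[[i]], k = 3,
                          pixel_size = sc$pixel_size)
    expect_lt(hausdorff_distance(ct, gen$truth$contours[[i]]),
              sc$pixel_size)
  }
})

test_that("a rendered movie round-trips through TIFF files", {
  sc <- small_image_scenario()
  gen <- generate_movie(sc, seed = 2)
  dp <- tempfile(fileext = ".tif"); ap <- tempfile(fileext = ".tif")
  write_stack(gen$movie, dp, ap)
  back <- load_stack(dp, ap, sc$pixel_size, sc$frame_interval,
                     sc$release_index)
  expect_identical(lapply(back$acceptor, unname),
                   lapply(gen$movie$acceptor, unname))
  expect_identical(lapply(back$donor, unname),
                   lapply(gen$movie$donor, unname))
  unlink(c(dp, ap))
})

test_that("an advance larger than the field of view is a geometry error", {
  sc <- small_image_scenario()
  sc$max_advance <- 100
  expect_error(generate_movie(sc, seed = 1), "off-image")
})
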