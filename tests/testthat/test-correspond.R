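corr_pair <- function(a, b, n_intermediate = 10, h = 0.5, ...) {
  inter <- evolve(a, b, n_intermediate = n_intermediate, grid_spacing = h)
  correspond(a, inter, b, ...)
}

test_that("concentric circles give radial displacements of the radius gap", {
  a <- circle_contour(10, 25, 25, n = 200)
  b <- circle_contour(15, 25, 25, n = 200, frame_index = 1L)
  cm <- corr_pair(a, b)
  len <- sqrt(cm$dx^2 + cm$dy^2)
  expect_true(all(abs(len - 5) < 0.3))
  rad <- cbind(a$x - 25, a$y - 25)
  rad <- rad / sqrt(rowSums(rad^2))
  along <- (cm$dx * rad[, 1] + cm$dy * rad[, 2]) / len
  expect_true(all(along > 0.99))
  expect_true(is_circularly_monotone(cm$target_params))
})

test_that("identical contours map onto themselves", {
  a <- circle_contour(10, 25, 25, n = 128)
  cm <- corr_pair(a, a, n_intermediate = 2)
  expect_true(all(sqrt(cm$dx^2 + cm$dy^2) < 0.3))
  d <- abs(cm$target_params - cm$source_params)
  expect_true(all(pmin(d, 1 - d) < 0.01))
})

test_that("a conflict-free map passes through correction unchanged", {
  a <- circle_contour(10, 25, 25, n = 100)
  b <- circle_contour(12, 25, 25, n = 100, frame_index = 1L)
  cm <- corr_pair(a, b)
  expect_true(all(cm$flags == "normal"))
  again <- correct_conflicts(cm)
  expect_equal(again$target_params, cm$target_params, tolerance = 1e-9)
})

test_that("crossing correction is the circular isotonic projection", {
  # raw target order locally inverted: (0.1, 0.3, 0.2, 0.4) at equally
  # trusted points pools the violators to their mean
  ct <- circle_contour(10, 15, 15, n = 4)
  raw <- structure(list(
    source_params = c(0, 0.25, 0.5, 0.75),
    target_params = c(0.1, 0.3, 0.2, 0.4),
    dx = rep(0, 4), dy = rep(0, 4),
    flags = factor(rep("normal", 4),
                   levels = c("normal", "corrected-missing",
                              "corrected-crossing", "corrected-direction")),
    contour_t = ct, contour_next = ct), class = "correspondence_map")
  fixed <- correct_conflicts(raw, min_motion = Inf)
  expect_equal(fixed$target_params, c(0.1, 0.25, 0.25, 0.4),
               tolerance = 1e-9)
  expect_setequal(as.character(fixed$flags[2:3]), "corrected-crossing")
})

test_that("a missing match is filled midway between its neighbors", {
  ct <- circle_contour(10, 15, 15, n = 8)
  sp <- (0:7) / 8
  tp <- sp + 0.02
  tp[3] <- NA  # between neighbors at 0.27 and 0.395
  raw <- structure(list(
    source_params = sp, target_params = tp,
    dx = rep(0.1, 8), dy = rep(0, 8),
    flags = factor(rep("normal", 8),
                   levels = c("normal", "corrected-missing",
                              "corrected-crossing", "corrected-direction")),
    contour_t = ct, contour_next = ct), class = "correspondence_map")
  raw$flags[3] <- "corrected-missing"
  fixed <- correct_conflicts(raw, min_motion = Inf)
  expect_equal(fixed$target_params[3], (tp[2] + tp[4]) / 2,
               tolerance = 1e-9)
  expect_equal(as.character(fixed$flags[3]), "corrected-missing")
})

test_that("an induced crossing is repaired to a circularly monotone map", {
  a <- ellipse_contour(12, 6, 25, 25, n = 150)
  b <- ellipse_contour(13, 7, 28, 25, n = 150, frame_index = 1L)
  raw <- corr_pair(a, b, correct = FALSE)
  # force crossings near a sharp end
  i <- 10
  raw$target_params[i] <- raw$target_params[i + 3]
  raw$target_params[i + 1] <- raw$target_params[i - 2]
  fixed <- correct_conflicts(raw)
  expect_true(is_circularly_monotone(fixed$target_params))
  expect_true(any(fixed$flags != "normal"))
  # displacement vectors connect source points to their target parameters
  pt <- point_at_param(b, fixed$target_params)
  expect_lt(max(abs(pt$x - (a$x + fixed$dx))), 0.25)
  expect_lt(max(abs(pt$y - (a$y + fixed$dy))), 0.25)
})

test_that("composed correspondences of a translating circle match the direct map", {
  a <- circle_contour(8, 20, 20, n = 150)
  b <- circle_contour(8, 22, 20, n = 150, frame_index = 1L)
  c2 <- circle_contour(8, 24, 20, n = 150, frame_index = 2L)
  m1 <- corr_pair(a, b, h = 0.25)
  m2 <- corr_pair(b, c2, h = 0.25)
  direct <- corr_pair(a, c2, h = 0.25, n_intermediate = 20)
  # chase a's vertices through both maps and compare against the direct
  # two-frame correspondence
  p1 <- map_params(m1, m1$source_params)
  p2 <- map_params(m2, p1)
  end <- point_at_param(c2, p2)
  expect_lt(max(abs(end$x - (a$x + direct$dx))), 0.5)
  expect_lt(max(abs(end$y - (a$y + direct$dy))), 0.5)
})

test_that("correspondence stays monotone on random smooth contour pairs", {
  for (seed in 1:3) {
    set.seed(seed)
    th <- 2 * pi * (0:119) / 120
    r1 <- 10 + 1.5 * sin(3 * th + stats::runif(1, 0, 2 * pi))
    r2 <- 11 + 1.5 * sin(3 * th + stats::runif(1, 0, 2 * pi))
    a <- cell_contour(25 + r1 * cos(th), 25 + r1 * sin(th))
    b <- cell_contour(25.5 + r2 * cos(th), 25 + r2 * sin(th),
                      frame_index = 1L)
    cm <- corr_pair(a, b)
    expect_true(is_circularly_monotone(cm$target_params))
  }
})
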