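test_that("global sigmas are the maxima of per-window centered SDs", {
  S <- rbind(c(1, 1.1, 1.2, 1.1, 1), c(1, 1.3, 1.6, 1.3, 1))
  B <- rbind(c(0, 1, 2, 3, 4), c(0, 0.5, 1, 1.5, 2))
  nm <- global_sigmas(st_map(S, 1:2, 1:5, "ratio"),
                      st_map(B, 1:2, 1:5, "translocation"))
  expect_equal(nm$sigma_S_max, max(apply(S, 1, sd)))
  expect_equal(nm$sigma_B_max, max(apply(B, 1, sd)))
  # identical rows: sigma_max equals the common row SD
  S2 <- rbind(S[1, ], S[1, ])
  nm2 <- global_sigmas(st_map(S2, 1:2, 1:5, "ratio"),
                       st_map(B, 1:2, 1:5, "translocation"))
  expect_equal(nm2$sigma_S_max, sd(S[1, ]))
  # random map equals the brute-force max over per-row SDs
  set.seed(21)
  S3 <- matrix(stats::rnorm(60), 6); B3 <- matrix(stats::rnorm(60), 6)
  nm3 <- global_sigmas(st_map(S3, 1:6, 1:10, "ratio"),
                       st_map(B3, 1:6, 1:10, "translocation"))
  expect_equal(nm3$sigma_S_max,
               max(vapply(1:6, function(i) sd(S3[i, ]), numeric(1))))
  expect_error(global_sigmas(st_map(matrix(1, 2, 5), 1:2, 1:5, "ratio"),
                             st_map(matrix(2, 2, 5), 1:2, 1:5,
                                    "translocation")),
               "degenerate")
})

test_that("perfect anticorrelation has its minimum -1 at zero lag", {
  set.seed(5)
  S <- cumsum(stats::rnorm(30))
  cc <- temporal_cc(S, -S, norms = NULL, max_lag = 10)
  expect_equal(cc$min_offset, 0)
  expect_equal(cc$min_value, -1, tolerance = 1e-9)
})

test_that("a shifted sigmoid pair recovers the shift, matching brute force", {
  t <- 1:40
  S <- 1 / (1 + exp(-(t - 12) / 0.5))
  B <- -1 / (1 + exp(-(t - 16) / 0.5))  # B(t) = -S(t - 4)
  cc <- temporal_cc(S, B, norms = NULL, max_lag = 12)
  expect_equal(cc$min_offset, 4)
  denom <- sd(S) * sd(B)
  bf <- bf_temporal_cc(S, B, -12:12, denom)
  expect_equal(cc$values, bf, tolerance = 1e-10)
})

test_that("brute-force oracle equality holds on random series", {
  set.seed(31)
  for (rep in 1:4) {
    S <- stats::rnorm(20); B <- stats::rnorm(20)
    denom <- 0.7
    nm <- list(sigma_S_max = 0.7, sigma_B_max = 1)
    class(nm) <- "global_norms"
    cc <- temporal_cc(S, B, norms = nm, max_lag = 7)
    bf <- bf_temporal_cc(S, B, -7:7, 0.7)
    expect_equal(cc$values, bf, tolerance = 1e-10)
  }
})

test_that("global normalization scales a low-variance window's curve down", {
  set.seed(6)
  S <- cumsum(stats::rnorm(25)); B <- cumsum(stats::rnorm(25))
  own <- temporal_cc(S, B, norms = NULL, max_lag = 8)
  nm <- list(sigma_S_max = 2 * sd(S), sigma_B_max = sd(B))
  class(nm) <- "global_norms"
  glob <- temporal_cc(S, B, norms = nm, max_lag = 8)
  expect_equal(glob$values, own$values / 2, tolerance = 1e-10)
  expect_true(all(abs(glob$values) <= abs(own$values) + 1e-12))
})

test_that("transpose symmetry: rho_SB(tau) = rho_BS(-tau)", {
  set.seed(7)
  S <- stats::rnorm(24); B <- stats::rnorm(24)
  ab <- temporal_cc(S, B, max_lag = 9)
  ba <- temporal_cc(B, S, max_lag = 9)
  expect_equal(ab$values, rev(ba$values), tolerance = 1e-12)
})

test_that("spatial CC finds co-located anticorrelation and tracks rotations", {
  set.seed(8)
  x <- sin(2 * pi * (0:23) / 24) + 0.1 * stats::rnorm(24)
  cc0 <- spatial_cc(x, -x)
  expect_equal(cc0$min_offset, 0)
  for (k in c(1, 3, 7, -4)) {
    rot <- -x[((seq_along(x) - 1 - k) %% 24) + 1]
    cck <- spatial_cc(x, rot)
    expect_equal(cck$min_offset, k)
  }
  # constant profile: zero coefficients everywhere
  nm <- list(sigma_S_max = 1, sigma_B_max = 1)
  class(nm) <- "global_norms"
  ccc <- spatial_cc(rep(2, 24), x, norms_spatial = nm)
  expect_true(all(abs(ccc$values) < 1e-12))
  expect_error(spatial_cc(x[1:5], x[1:5]), "8 windows")
})

test_that("minimum extraction reports ties and all-positive curves", {
  cc <- structure(list(offsets = c(-2, 0, 2), values = c(-0.2, -0.9, -0.4),
                       min_value = -0.9, min_offset = 0, flag = "ok",
                       unit = "min"), class = "cc_result")
  m <- extract_minimum(cc)
  expect_equal(m$min_value, -0.9)
  expect_equal(m$min_offset, 0)
  # tie at -0.9 on offsets -3 and +3: the positive one wins
  tie <- edgefret:::cc_result(offsets = c(-3, 0, 3),
                              values = c(-0.9, -0.1, -0.9), unit = "min")
  expect_equal(tie$min_offset, 3)
  pos <- edgefret:::cc_result(offsets = c(-1, 0, 1),
                              values = c(0.2, 0.5, 0.3), unit = "min")
  expect_equal(extract_minimum(pos)$flag, "no-negative-minimum")
})

test_that("CC maps stack per-window curves and propagate missing rows", {
  set.seed(9)
  n_w <- 6; n_t <- 30
  S <- matrix(stats::rnorm(n_w * n_t, 1, 0.1), n_w)
  B <- -3 * (S - 1) + matrix(stats::rnorm(n_w * n_t, 0, 0.01), n_w)
  rmap <- st_map(S, 1:n_w, 1:n_t, "ratio")
  tmap <- st_map(B, 1:n_w, 1:n_t, "translocation")
  cm <- cc_map(rmap, tmap, max_lag = 8)
  at0 <- which(cm$offsets == 0)
  for (w in seq_len(n_w))
    expect_equal(which.min(cm$values[w, ]), at0)
  # an all-missing window yields a missing row, not zeros
  S[2, ] <- NA
  cm2 <- cc_map(st_map(S, 1:n_w, 1:n_t, "ratio"), tmap, max_lag = 8)
  expect_true(all(is.na(cm2$values[2, ])))
  expect_false(anyNA(cm2$values[3, ]))
})
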