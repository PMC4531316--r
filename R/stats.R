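#' Bootstrap mean with percentile confidence interval
#'
#' Resamples the values with replacement `n_boot` times (default 5000) and
#' returns the sample mean with the percentile 95% confidence interval of
#' the bootstrap means. Deterministic given the seed.
#'
#' @param values numeric vector (length >= 2).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list with `mean`, `lower`, `upper`, `n`, `n_boot`, `seed`.
#' @export
bootstrap_mean <- function(values, n_boot = 5000L, seed = 1L,
                           conf = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("bootstrap needs at least 2 values")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  boots <- colMeans(matrix(values[idx], nrow = n))
  a <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  list(mean = mean(values), lower = ci[1], upper = ci[2],
       n = n, n_boot = n_boot, seed = seed)
}

#' Welch t-test comparison of two groups
#'
#' Unequal-variance (Welch) t-test. When both groups are constant with
#' equal means the p-value is 1 (no evidence of difference); constant
#' groups with different means give p = 0.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param tails `"two"` or `"one"`.
#' @param direction for one-tailed tests, the hypothesized direction:
#'   `"greater"` tests mean(a) > mean(b), `"less"` the reverse.
#' @return the p-value.
#' @export
compare_groups <- function(a, b, tails = c("two", "one"),
                           direction = c("greater", "less")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  alternative <- if (tails == "two") "two.sided" else direction
  stats::t.test(a, b, alternative = alternative,
                var.equal = FALSE)$p.value
}

#' Normalize a time course by its pre-release baseline
#'
#' Divides the series by the mean of its baseline frames, so the baseline
#' sits at ~1 and post-release values are fold changes.
#'
#' @param series numeric vector.
#' @param baseline_frames indices of the baseline (pre-release) frames.
#' @return the normalized series.
#' @export
normalize_timecourse <- function(series, baseline_frames) {
  if (length(baseline_frames) == 0) stop("empty baseline")
  m <- mean(series[baseline_frames], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("baseline mean must be positive")
  series / m
}
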