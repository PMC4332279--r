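#' Power of the G-squared goodness-of-fit test
#'
#' Under a deviation of Cohen's effect size `w` from the null model, the
#' `G^2` statistic is asymptotically noncentral chi-square with
#' noncentrality `lambda = N * w^2`. Power is the probability that it
#' exceeds the central chi-square critical value at level `alpha`.
#'
#' @param df Degrees of freedom of the test (positive integer).
#' @param alpha Significance level in `(0, 1)`.
#' @param w Cohen's effect size (non-negative); `w = 0` returns `alpha`.
#' @param N Total sample size (positive).
#' @return Power in `[alpha, 1]`. Vectorised over all arguments.
#' @examples
#' gof_power(df = 1, alpha = 0.05, w = 0.3, N = 142)  # 0.947
#' gof_power(df = 1, alpha = 0.05, w = 0.1, N = 142)  # 0.222
#' @export
gof_power <- function(df, alpha, w, N) {
  stopifnot(all(df >= 1), all(alpha > 0 & alpha < 1), all(w >= 0), all(N >= 1))
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = N * w^2, lower.tail = FALSE)
}

#' Minimal sample size for a target power
#'
#' Smallest integer `N` with `gof_power(df, alpha, w, N) >= target_power`,
#' found by doubling the bracket and integer bisection (power is strictly
#' increasing in `N` for `w > 0`).
#'
#' @inheritParams gof_power
#' @param target_power Desired power in `(0, 1)`.
#' @return An integer `N`.
#' @examples
#' required_sample_size(df = 1, alpha = 0.05, w = 0.1, target_power = 0.80)  # 785
#' @export
required_sample_size <- function(df, alpha, w, target_power) {
  stopifnot(df >= 1, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  if (w <= 0) stop("w must be positive: at w = 0 power never exceeds alpha",
                   call. = FALSE)
  if (target_power <= alpha) return(1L)
  hi <- 2L
  while (gof_power(df, alpha, w, hi) < target_power) {
    hi <- hi * 2L
    if (hi > .Machine$integer.max / 2) {
      stop("required sample size exceeds integer range", call. = FALSE)
    }
  }
  lo <- hi %/% 2L
  while (lo + 1L < hi) {
    mid <- (lo + hi) %/% 2L
    if (gof_power(df, alpha, w, mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Tabulate power over a grid of queries
#'
#' @param queries A data frame with columns `df`, `alpha`, `w` and exactly
#'   one of `N` or `target_power` per row (the other `NA`).
#' @return The queries with a filled `power` and `N` column.
#' @export
power_table <- function(queries) {
  queries <- tibble::as_tibble(queries)
  if (!all(c("df", "alpha", "w") %in% names(queries))) {
    stop("queries need columns df, alpha, w and N or target_power", call. = FALSE)
  }
  if (is.null(queries$N)) queries$N <- NA_integer_
  if (is.null(queries$target_power)) queries$target_power <- NA_real_
  if (any(is.na(queries$N) == is.na(queries$target_power))) {
    stop("each query must set exactly one of N / target_power", call. = FALSE)
  }
  purrr::pmap_dfr(queries, function(df, alpha, w, N, target_power, ...) {
    if (is.na(N)) {
      N <- required_sample_size(df, alpha, w, target_power)
    }
    tibble::tibble(df = df, alpha = alpha, w = w, N = as.integer(N),
                   power = gof_power(df, alpha, w, N))
  })
}
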