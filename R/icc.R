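#' Intraclass correlation of a set of expression series
#'
#' Agreement measure for `m >= 2` series over `n >= 3` ages. Each series
#' is first anchored by centering and scaling to zero mean and unit SD;
#' the ICC is then computed from the two-way ANOVA decomposition over
#' ages:
#' \deqn{ICC = (MSB - MSE) / (MSB + (m - 1) MSE)}
#' where MSB is the between-age mean square of the per-age means of the
#' m standardized series and MSE the residual mean square. The result is
#' clipped to \[-1, 1\]. Identical standardized series give ICC = 1;
#' exactly opposite pairs give ICC = -1 (diametrical, anti-correlated
#' patterns); for m = 2 the ICC equals the Pearson correlation of the
#' standardized series.
#'
#' @param series_set Numeric matrix, m series (rows) x n ages (columns).
#' @return The ICC in \[-1, 1\].
#' @export
icc_winer <- function(series_set) {
  x <- as.matrix(series_set)
  m <- nrow(x)
  n <- ncol(x)
  if (m < 2L) stop("need at least 2 series")
  if (n < 3L) stop("need series of length >= 3")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) stop("zero-variance series")
  z <- (x - rowMeans(x)) / sds
  age_means <- colMeans(z)
  ss_age <- m * sum((age_means - mean(z))^2)
  ss_tot <- sum((z - mean(z))^2)
  ss_series <- n * sum((rowMeans(z) - mean(z))^2)  # ~0 after centering
  ss_res <- ss_tot - ss_age - ss_series
  msb <- ss_age / (n - 1)
  mse <- ss_res / ((m - 1) * (n - 1))
  icc <- (msb - mse) / (msb + (m - 1) * mse)
  max(-1, min(1, icc))
}
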