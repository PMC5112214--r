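#' Five-number column summary
#'
#' Median, 25th and 75th percentiles (linear interpolation between order
#' statistics, `stats::quantile()` type 7), minimum and maximum. The median
#' of an even-sized sample is the midpoint of the two central order
#' statistics.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `(median, p25, p75, min, max)`.
#' @export
column_summary <- function(values) {
  if (length(values) == 0) stop("empty input")
  stopifnot(all(is.finite(values)))
  c(median = stats::median(values),
    p25 = unname(stats::quantile(values, 0.25)),
    p75 = unname(stats::quantile(values, 0.75)),
    min = min(values), max = max(values))
}

#' Exhaustive iid bootstrap of the sample mean
#'
#' Enumerates every possible bootstrap resample of `values` (all
#' `choose(2N - 1, N)` multisets of size `N` drawn from the `N` values) and
#' weights each multiset by its multinomial coefficient, i.e. by the number
#' of ordered iid resamples that realize it. Under this weighting the
#' distribution of resample means has mean equal to the sample mean exactly,
#' and standard deviation equal to the population standard deviation of the
#' sample divided by `sqrt(N)`.
#'
#' @param values Numeric vector of length 2 to 14 (enumeration bound; use
#'   [bootstrap_mc_means()] for larger samples).
#' @return An object of class `bootstrap_summary`: `resample_means`, `logw`
#'   (log multinomial weights; weights sum to `N^N`), `n` and later,
#'   after [fit_gaussian()]/[fit_nakagami()], the density fits.
#' @examples
#' bs <- enumerate_bootstrap(c(0, 2))
#' exp(bs$logw)          # 1 2 1
#' bs$resample_means     # 0 1 2
#' @export
enumerate_bootstrap <- function(values) {
  n <- length(values)
  if (n < 2 || n > 14)
    stop("enumeration supported for 2 <= N <= 14; ",
         "use bootstrap_mc_means() for larger samples")
  stopifnot(all(is.finite(values)))
  res <- boot_enum_means_cpp(as.numeric(values))
  structure(list(resample_means = res$mean, logw = res$logw, n = n,
                 values = as.numeric(values)),
            class = "bootstrap_summary")
}

#' Monte-Carlo bootstrap of the sample mean
#'
#' Seeded fallback for samples too large to enumerate exhaustively. Draws are
#' equally weighted (`logw = 0`).
#'
#' @param values Numeric vector.
#' @param n_draws Number of resamples.
#' @param seed Optional integer seed applied via [set.seed()].
#' @return A `bootstrap_summary` (uniform weights).
#' @export
bootstrap_mc_means <- function(values, n_draws = 1e5, seed = NULL) {
  stopifnot(all(is.finite(values)), length(values) >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(n_draws),
                  function(i) mean(sample(values, n, replace = TRUE)),
                  numeric(1))
  structure(list(resample_means = means, logw = rep(0, n_draws), n = n,
                 values = as.numeric(values)),
            class = "bootstrap_summary")
}

# normalized weights from log multiplicities
boot_weights <- function(summary) {
  lw <- summary$logw
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Gaussian fit to a bootstrap distribution of the mean
#'
#' Weighted first and second moments of the resample means. For the
#' exhaustive multinomial-weighted bootstrap these have closed forms: the
#' sample mean, and the population standard deviation of the sample divided
#' by `sqrt(N)`.
#'
#' @param summary A `bootstrap_summary`.
#' @return Named numeric vector `(mean, sd)`.
#' @export
fit_gaussian <- function(summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  w <- boot_weights(summary)
  m <- sum(w * summary$resample_means)
  v <- sum(w * (summary$resample_means - m)^2)
  c(mean = m, sd = sqrt(v))
}

#' Nakagami fit to a bootstrap distribution of the mean
#'
#' Weighted maximum-likelihood fit of the Nakagami density
#' `f(x) = 2 m^m x^(2m-1) exp(-m x^2 / omega) / (gamma(m) omega^m)` to the
#' strictly positive resample means (Nakagami support is positive; any
#' negative or zero resample means are excluded and their total probability
#' mass reported). Since `x^2` is Gamma-distributed with shape `m` and scale
#' `omega / m`, the ML equations reduce to `omega = E[x^2]` and the standard
#' Gamma shape equation, solved by bisection on a bracketed root.
#'
#' @param summary A `bootstrap_summary`.
#' @return List with `m`, `omega`, and `excluded_mass` (probability mass of
#'   non-positive resample means).
#' @export
fit_nakagami <- function(summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  w <- boot_weights(summary)
  x <- summary$resample_means
  pos <- x > 0
  if (sum(pos) < 2 || length(unique(x[pos])) < 2)
    stop("need at least 2 distinct positive resample means")
  w <- w[pos] / sum(w[pos])
  y <- x[pos]^2
  mean_y <- sum(w * y)
  mean_log_y <- sum(w * log(y))
  s <- log(mean_y) - mean_log_y          # > 0 unless y is constant
  if (s <= 0) stop("degenerate (constant) positive resample means")
  shape_eq <- function(m) log(m) - digamma(m) - s
  # log(m) - digamma(m) is decreasing from Inf to 0; bracket the root
  lo <- 1e-8; hi <- 1
  while (shape_eq(hi) > 0) hi <- hi * 2
  m <- stats::uniroot(shape_eq, c(lo, hi), tol = 1e-12)$root
  list(m = m, omega = mean_y,
       excluded_mass = 1 - sum(boot_weights(summary)[pos]))
}

#' Nakagami density
#'
#' @param x Quantile(s), support `x > 0`.
#' @param m Shape parameter (> 0).
#' @param omega Spread parameter (> 0), equal to `E[x^2]`.
#' @return Density values (0 outside the support).
#' @export
dnakagami <- function(x, m, omega) {
  stopifnot(m > 0, omega > 0)
  out <- numeric(length(x))
  ok <- x > 0
  out[ok] <- 2 * m^m * x[ok]^(2 * m - 1) *
    exp(-m * x[ok]^2 / omega) / (gamma(m) * omega^m)
  out
}

#' Mean of a Nakagami distribution
#'
#' `E[X] = gamma(m + 1/2) / gamma(m) * sqrt(omega / m)`.
#'
#' @param m Shape parameter (> 0).
#' @param omega Spread parameter (> 0).
#' @return The distribution mean.
#' @examples
#' nakagami_mean(1, 4)  # 2 * gamma(1.5) = 1.7725
#' @export
nakagami_mean <- function(m, omega) {
  if (!is.finite(m) || !is.finite(omega) || m <= 0 || omega <= 0)
    stop("m and omega must be positive")
  exp(lgamma(m + 0.5) - lgamma(m)) * sqrt(omega / m)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of the (average-tie) ranks.
#'
#' @param x,y Aligned numeric vectors, length >= 3.
#' @return The rank correlation; errors on constant input (undefined).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be aligned")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rank correlation undefined for constant input")
  stats::cor(x, y, method = "spearman")
}

#' Regression slope with exhaustive-bootstrap confidence interval
#'
#' Ordinary least-squares line through `(x, y)`, with a confidence interval
#' for the slope taken from the multinomial-weighted distribution of slopes
#' over all paired-case bootstrap resamples (the same `choose(2N-1, N)`
#' multisets as [enumerate_bootstrap()], resampling (x, y) pairs jointly).
#' Resamples with fewer than two distinct `x` values have no defined slope
#' and are excluded; their probability mass is reported.
#'
#' @param x,y Aligned numeric vectors, length 3 to 14.
#' @param level Confidence level (default 0.95).
#' @return List with `slope`, `intercept`, `ci` (two-sided weighted-quantile
#'   interval for the slope) and `excluded_mass`.
#' @export
regression_bootstrap_ci <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("x and y must be aligned")
  n <- length(x)
  if (n < 3 || n > 14) stop("supported for 3 <= N <= 14")
  if (length(unique(x)) < 2) stop("all x values identical")
  fit <- stats::lm(y ~ x)
  res <- boot_enum_slopes_cpp(as.numeric(x), as.numeric(y))
  ok <- !is.na(res$slope)
  lw <- res$logw[ok]
  w <- exp(lw - max(lw)); w <- w / sum(w)
  alpha <- (1 - level) / 2
  ci <- weighted_quantile(res$slope[ok], w, c(alpha, 1 - alpha))
  all_w <- exp(res$logw - max(res$logw)); all_w <- all_w / sum(all_w)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       ci = ci, excluded_mass = sum(all_w[!ok]))
}

# weighted quantiles of a discrete distribution (inverse weighted ecdf)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Recompute the with-elicitor compression exponent from a report row
#'
#' Internal-consistency identity: with the break points fixed,
#' `c_tilde = 1 - (1 - c) * (g_max - delta_g) / g_max`, clamped at 1.
#'
#' @param g_max Baseline maximum gain in dB (> 0).
#' @param c Baseline compression exponent.
#' @param delta_g Elicitor-induced gain reduction in dB.
#' @return The implied with-elicitor compression exponent.
#' @examples
#' ctilde_consistency(17.80, 0.43, 4.04)  # 0.56 to 2 d.p.
#' @export
ctilde_consistency <- function(g_max, c, delta_g) {
  if (any(!is.finite(g_max)) || any(g_max <= 0))
    stop("g_max must be positive")
  pmin(1, 1 - (1 - c) * (g_max - delta_g) / g_max)
}

#' Read a fitted-parameter table in the conventional layout
#'
#' Delimited text with header columns `subject_id`, `G_max`, `c`, `BP_ctr`,
#' `k`, `mu`, `P`, `dG`, `c_tilde` (one row per subject).
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_param_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("G_max", "c", "BP_ctr", "k", "mu", "P", "dG", "c_tilde")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  df
}
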