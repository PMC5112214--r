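test_that("column summary reproduces published medians", {
  t1 <- published_params()
  expect_lt(abs(column_summary(t1$dG)[["median"]] - 2.57), 0.006)
  expect_lt(abs(column_summary(t1$P)[["median"]] - 20.68), 0.006)
  expect_lt(abs(column_summary(t1$BP_ctr)[["median"]] - 43.52), 0.006)
  expect_lt(abs(column_summary(t1$k)[["median"]] - 1.50), 0.006)
  expect_lt(abs(column_summary(t1$mu)[["median"]] - 0.54), 0.006)
  expect_lt(abs(column_summary(t1$c)[["median"]] - 0.18), 0.006)
  s <- column_summary(7)
  expect_equal(unname(s), rep(7, 5))
  expect_error(column_summary(numeric(0)), "empty")
})

test_that("exhaustive bootstrap enumerates weighted multisets exactly", {
  bs <- enumerate_bootstrap(c(0, 2))
  expect_equal(sort(bs$resample_means), c(0, 1, 2))
  expect_equal(exp(bs$logw)[order(bs$resample_means)], c(1, 2, 1))
  g <- fit_gaussian(bs)
  expect_equal(g[["mean"]], 1)
  expect_equal(g[["sd"]], 1 / sqrt(2))
  # resample count and weight total for general N
  x <- c(1.2, -0.4, 3.3, 0.1, 2.2)
  bs5 <- enumerate_bootstrap(x)
  expect_equal(length(bs5$resample_means), choose(2 * 5 - 1, 5))
  expect_equal(sum(exp(bs5$logw)), 5^5)
  # weighted mean of resample means equals the plain mean exactly
  w <- exp(bs5$logw) / 5^5
  expect_equal(sum(w * bs5$resample_means), mean(x))
  # closed-form sd: population sd / sqrt(N)
  g5 <- fit_gaussian(bs5)
  expect_equal(g5[["sd"]], sd(x) * sqrt(4 / 5) / sqrt(5), tolerance = 1e-12)
  expect_equal(length(enumerate_bootstrap(1:12)$resample_means), 1352078)
  expect_error(enumerate_bootstrap(1), "2 <= N")
})

test_that("exhaustive enumeration agrees with Monte-Carlo at small N", {
  x <- c(-1.5, 0.2, 0.9, 2.7, 3.1, 5.0)
  ex <- enumerate_bootstrap(x)
  w <- exp(ex$logw) / sum(exp(ex$logw))
  mc <- bootstrap_mc_means(x, n_draws = 2e5, seed = 99)
  expect_equal(sum(w * ex$resample_means), mean(mc$resample_means),
               tolerance = 0.02)
  ex_sd <- sqrt(sum(w * (ex$resample_means - mean(x))^2))
  expect_equal(ex_sd, sd(mc$resample_means), tolerance = 0.02)
  q_ex <- moctmc:::weighted_quantile(ex$resample_means, w, c(0.025, 0.975))
  q_mc <- unname(quantile(mc$resample_means, c(0.025, 0.975)))
  expect_lt(max(abs(q_ex - q_mc)), 0.1)
})

test_that("Nakagami ML fit recovers known parameters and special cases", {
  # sampling + recovery oracle: x^2 ~ Gamma(shape m, scale omega/m)
  set.seed(5)
  x <- sqrt(rgamma(1e5, shape = 2, scale = 10 / 2))
  bs <- structure(list(resample_means = x, logw = rep(0, length(x)), n = 1),
                  class = "bootstrap_summary")
  fit <- fit_nakagami(bs)
  expect_lt(abs(fit$m - 2) / 2, 0.02)
  expect_lt(abs(fit$omega - 10) / 10, 0.02)
  # independent route: direct numerical ML over (log m, log omega)
  nll <- function(par) -sum(log(dnakagami(x, exp(par[1]), exp(par[2]))))
  opt <- optim(c(0, log(mean(x^2)) + 0.3), nll)
  expect_equal(fit$m, exp(opt$par[1]), tolerance = 1e-3)
  expect_equal(fit$omega, exp(opt$par[2]), tolerance = 1e-3)
  # m = 1 reduces to Rayleigh: mean = gamma(1.5) sqrt(omega)
  expect_equal(nakagami_mean(1, 4), 2 * gamma(1.5), tolerance = 1e-12)
  expect_equal(nakagami_mean(1.52, 23.44), 4.4, tolerance = 0.05)
  expect_equal(nakagami_mean(1e7, 9), 3, tolerance = 1e-3)  # m -> Inf
  expect_error(nakagami_mean(-1, 4), "positive")
})

test_that("Nakagami fit excludes non-positive resample means with report", {
  bs <- enumerate_bootstrap(c(-2, 1, 4))
  fit <- fit_nakagami(bs)
  expect_gt(fit$excluded_mass, 0)
  w <- exp(bs$logw) / sum(exp(bs$logw))
  expect_equal(fit$excluded_mass, sum(w[bs$resample_means <= 0]),
               tolerance = 1e-12)
  expect_error(fit_nakagami(enumerate_bootstrap(c(-5, -2))), "positive")
})

test_that("Spearman correlation matches brute-force ranks including ties", {
  expect_equal(spearman(1:8, (1:8)^3), 1)
  expect_equal(spearman(1:8, -(1:8)), -1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)   # tie at 1
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)   # several ties
  brute <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  expect_equal(spearman(x, y), cor(brute(x), brute(y)))
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("regression slope CI comes from the exhaustive paired bootstrap", {
  # exact line: slope 2, zero-width interval
  x <- c(1, 2, 3, 4)
  reg <- regression_bootstrap_ci(x, 2 * x + 1)
  expect_equal(reg$slope, 2)
  expect_equal(reg$intercept, 1)
  expect_equal(unname(reg$ci), c(2, 2), tolerance = 1e-9)
  # n = 3: compare against explicit enumeration of the 10 multisets
  x3 <- c(0, 1, 3)
  y3 <- c(1, 2, 2.5)
  reg3 <- regression_bootstrap_ci(x3, y3, level = 0.9)
  counts <- expand.grid(c1 = 0:3, c2 = 0:3, c3 = 0:3)
  counts <- counts[rowSums(counts) == 3, ]
  expect_equal(nrow(counts), 10)
  slopes <- apply(counts, 1, function(cc) {
    xx <- rep(x3, cc)
    yy <- rep(y3, cc)
    if (length(unique(xx)) < 2) return(NA_real_)
    unname(coef(lm(yy ~ xx))[2])
  })
  wts <- apply(counts, 1, function(cc) factorial(3) / prod(factorial(cc)))
  ok <- !is.na(slopes)
  w <- wts[ok] / sum(wts[ok])
  o <- order(slopes[ok])
  cw <- cumsum(w[o])
  expected_lo <- slopes[ok][o][which(cw >= 0.05)[1]]
  expected_hi <- slopes[ok][o][which(cw >= 0.95)[1]]
  expect_equal(unname(reg3$ci), as.numeric(c(expected_lo, expected_hi)))
  expect_equal(reg3$excluded_mass, sum(wts[!ok]) / sum(wts))
  expect_error(regression_bootstrap_ci(rep(2, 4), 1:4), "identical")
})

test_that("the compression-change identity reproduces the published column", {
  t1 <- published_params()
  ct <- ctilde_consistency(t1$G_max, t1$c, t1$dG)
  # printed inputs are rounded to 2 d.p., so agreement is to one unit in the
  # last printed digit
  expect_lt(max(abs(ct - t1$c_tilde)), 0.01)
  # boundary rows where dG = G_max give exactly 1.00
  boundary <- t1$dG == t1$G_max
  expect_true(any(boundary))
  expect_equal(ct[boundary], rep(1, sum(boundary)))
  expect_lt(abs(ctilde_consistency(17.80, 0.43, 4.04) - 0.56), 0.001)
  expect_equal(ctilde_consistency(25, 0.3, 0), 0.3)
  expect_error(ctilde_consistency(0, 0.3, 1), "positive")
})
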