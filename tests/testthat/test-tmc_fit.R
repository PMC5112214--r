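test_that("rmsd matches its closed form and validates input", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(0, 0), c(3, -3)), 3)
  expect_error(rmsd(1:3, 1:2), "equal length")
})

test_that("dataset validation catches malformed tables", {
  par <- ref_params()
  ctx <- ref_ctx()
  d <- model_tmc_dataset(par, ctx)
  expect_s3_class(d, "tmc_dataset")
  bad <- as.data.frame(d)
  bad$masker[1] <- "mid"
  expect_error(tmc_dataset(bad), "masker")
  dup <- as.data.frame(d)
  dup$gap_ms[2] <- dup$gap_ms[1]
  expect_error(tmc_dataset(dup), "duplicate")
  expect_error(tmc_dataset(d[, -2]), "missing columns")
})

test_that("TMC tables round-trip through delimited text", {
  d <- model_tmc_dataset(ref_params(), ref_ctx())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tmc(d, path)
  back <- read_tmc(path)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-10)
})

test_that("baseline fit recovers all six parameters from noiseless data", {
  # L_s = 25 places data in all three response regimes, so every parameter
  # is identified
  par <- ref_params()
  ctx <- ref_ctx(l_s = 25)
  d <- model_tmc_dataset(par, ctx)
  fit <- suppressWarnings(fit_tmc_baseline(d))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$g_max - 30), 0.1)
  expect_lt(abs(fit$params$c - 0.2), 0.01)
  expect_lt(abs(fit$params$bp_ctr - par$bp_ctr), 0.1)
  expect_lt(abs(fit$ctx$k - 1.5), 0.01)
  expect_lt(abs(fit$ctx$mu - 0.5), 0.01)
  expect_lt(abs(fit$params$p - 20), 0.1)
  expect_lt(fit$rmsd_db, 1e-6)
  expect_equal(fit$rmsd_db, sqrt(fit$sse / fit$n_points))
  # determinism: identical data, identical result
  fit2 <- suppressWarnings(fit_tmc_baseline(d))
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$sse, fit2$sse)
})

test_that("returned SSE is no worse than any multistart initial point", {
  par <- ref_params()
  ctx <- ref_ctx(l_s = 25)
  d <- model_tmc_dataset(par, ctx)
  fit <- suppressWarnings(fit_tmc_baseline(d))
  starts <- moctmc:::tmc_fit_starts()
  for (i in seq_len(nrow(starts))) {
    theta <- unlist(starts[i, c("g_max", "c", "bp_ctr", "k", "mu", "p")])
    sse_start <- sum(moctmc:::baseline_residuals(theta, fit$data, NULL)^2)
    expect_lte(fit$sse, sse_start + 1e-9)
  }
})

test_that("without off-frequency rows P is fixed and flagged", {
  par <- ref_params()
  ctx <- ref_ctx(l_s = 25)
  d <- tmc_dataset(model_tmc_rows(par, ctx, seq(5, 30, 5), "on"))
  fit <- suppressWarnings(fit_tmc_baseline(d, p_fixed = 17))
  expect_true(fit$p_fixed)
  expect_equal(fit$params$p, 17)
  expect_error(fit_tmc_baseline(d[1:2, ]), "at least 3")
})

test_that("elicitor fit recovers dG and matches with on-frequency rows alone", {
  par <- ref_params()
  ctx <- ref_ctx(l_s = 25)
  d <- model_tmc_dataset(par, ctx, delta_g = 10)
  base <- suppressWarnings(fit_tmc_baseline(d))
  full <- fit_tmc_elicitor(d, base)
  expect_lt(abs(full$effect$delta_g - 10), 0.05)
  expect_equal(full$effect$c_tilde,
               1 - (full$params$g_max - full$effect$delta_g) /
                 (full$params$bp2 - full$params$bp1), tolerance = 1e-8)
  # the robustness check: omitting off-frequency rows leaves dG unchanged
  on_only <- d[!(d$elicitor == "with" & d$masker == "off"), ]
  reduced <- fit_tmc_elicitor(on_only, base)
  expect_lt(abs(reduced$effect$delta_g - full$effect$delta_g), 0.05)
  # with-elicitor data identical to baseline data implies dG ~ 0
  same <- d[d$elicitor == "without", ]
  same$elicitor <- "with"
  null_fit <- fit_tmc_elicitor(same, base)
  expect_lt(abs(null_fit$effect$delta_g), 0.05)
  expect_error(fit_tmc_elicitor(d[d$elicitor == "without", ], base),
               "no with-elicitor rows")
})

test_that("dG beyond G_max reports the boundary value", {
  # gain cannot drop below zero, so all dG >= G_max fit identically; the
  # smallest equivalent value (the boundary) is reported, as in published
  # fits where dG equals G_max exactly
  par <- ref_params()
  ctx <- ref_ctx(l_s = 25)
  d <- model_tmc_dataset(par, ctx, delta_g = 37)   # > G_max = 30
  base <- suppressWarnings(fit_tmc_baseline(d))
  fe <- fit_tmc_elicitor(d, base)
  expect_lt(abs(fe$effect$delta_g - base$params$g_max), 0.05)
  expect_equal(fe$effect$c_tilde, 1)
})

test_that("parameter recovery holds across the population parameter ranges", {
  # noiseless subjects drawn from the default population (signal below the
  # compressive range by construction); the identifiable gain reduction is
  # min(dG, G_max)
  set.seed(42)
  spec <- population_spec(noise_sd = 0)
  for (i in 1:5) {
    s <- sample_subject(spec, "S")
    d <- generate_tmc_dataset(s)
    base <- suppressWarnings(fit_tmc_baseline(d))
    fe <- fit_tmc_elicitor(d, base)
    expect_lt(abs(fe$effect$delta_g - min(s$delta_g, s$params$g_max)), 0.1)
    expect_lt(abs(fe$ctx$mu - s$ctx$mu), 0.01)
    expect_lt(fe$rmsd_db, 0.05)
  }
})

test_that("predicted off-frequency TMC is the fitted line of slope mu", {
  par <- ref_params()
  ctx <- ref_ctx(l_s = 25)
  d <- model_tmc_dataset(par, ctx)
  fit <- suppressWarnings(fit_tmc_baseline(d))
  gaps <- seq(5, 30, 5)
  off <- predict_missing_off_tmc(fit, gaps)
  expect_equal(diff(off), rep(5 * fit$ctx$mu, 5), tolerance = 1e-8)
  expect_length(predict_missing_off_tmc(fit, numeric(0)), 0)
})

test_that("reduced-design workflow infers the same with-elicitor IO function", {
  par <- ref_params()
  ctx <- ref_ctx(l_s = 25)
  gaps <- seq(5, 30, 5)
  d_full <- model_tmc_dataset(par, ctx, delta_g = 10)
  base <- suppressWarnings(fit_tmc_baseline(d_full))
  # full-data workflow: measured with-elicitor off rows
  fe <- fit_tmc_elicitor(d_full, base)
  off_meas <- d_full$threshold_db_spl[d_full$elicitor == "with" &
                                        d_full$masker == "off"]
  on_meas <- d_full$threshold_db_spl[d_full$elicitor == "with" &
                                       d_full$masker == "on"]
  io_full <- infer_io_function(on_meas, off_meas, fe$params$p)
  # reduced workflow: with-elicitor off TMC predicted from the fit
  reduced <- d_full[!(d_full$elicitor == "with" & d_full$masker == "off"), ]
  fe_red <- fit_tmc_elicitor(reduced, base)
  off_pred <- predict_missing_off_tmc(fe_red, gaps)
  io_red <- infer_io_function(on_meas, off_pred, fe_red$params$p)
  expect_equal(io_red$output_level, io_full$output_level, tolerance = 1e-4)
})

test_that("cohort fitting reports one row per subject in the standard layout", {
  par <- ref_params()
  ctx <- ref_ctx(l_s = 25)
  d1 <- model_tmc_dataset(par, ctx, delta_g = 5)
  d2 <- d1
  d2$subject_id <- "Y"
  rep <- suppressWarnings(fit_tmc_cohort(tmc_dataset(rbind(d1, d2))))
  expect_equal(nrow(rep), 2)
  expect_named(rep, c("subject_id", "G_max", "c", "BP_ctr", "k", "mu", "P",
                      "dG", "c_tilde", "rmsd_db", "converged"))
  expect_lt(abs(rep$dG[1] - 5), 0.05)
  expect_equal(rep$dG[1], rep$dG[2], tolerance = 1e-8)
})
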