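#' Validate and construct a TMC dataset
#'
#' A TMC dataset is a long-format data frame with one row per measured
#' forward-masking threshold. Required columns: `subject_id`, `gap_ms`,
#' `masker` (`"on"`/`"off"`), `elicitor` (`"with"`/`"without"`),
#' `threshold_db_spl` and `signal_level_db_spl`. Gaps must be unique within
#' each masker-by-elicitor cell of a subject.
#'
#' @param df A data frame in the layout above.
#' @return The validated data frame with class `tmc_dataset` prepended.
#' @export
tmc_dataset <- function(df) {
  needed <- c("subject_id", "gap_ms", "masker", "elicitor",
              "threshold_db_spl", "signal_level_db_spl")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(df$masker %in% c("on", "off")))
    stop("masker must be 'on' or 'off'")
  if (!all(df$elicitor %in% c("with", "without")))
    stop("elicitor must be 'with' or 'without'")
  if (!all(is.finite(df$gap_ms)) || !all(is.finite(df$threshold_db_spl)))
    stop("gaps and thresholds must be finite")
  dup <- duplicated(df[c("subject_id", "masker", "elicitor", "gap_ms")])
  if (any(dup))
    stop("duplicate gaps within a subject x masker x elicitor cell")
  class(df) <- unique(c("tmc_dataset", class(df)))
  df
}

#' Read / write TMC threshold tables
#'
#' Delimited-text I/O for TMC datasets (tab-separated, header row with the
#' `tmc_dataset` column names).
#'
#' @param path File path.
#' @return `read_tmc()` returns a validated [tmc_dataset()].
#' @export
read_tmc <- function(path) {
  tmc_dataset(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_tmc
#' @param data A [tmc_dataset()] (or compatible data frame).
#' @export
write_tmc <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Root-mean-square deviation between observed and predicted thresholds
#'
#' @param observed,predicted Aligned numeric vectors in dB (equal length,
#'   at least one element).
#' @return RMSD in dB.
#' @export
rmsd <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 1) stop("need at least one point")
  sqrt(mean((observed - predicted)^2))
}

# Default optimizer bounds: generous supersets of the parameter ranges seen
# in normal-hearing cohorts.
tmc_fit_bounds <- function() {
  list(lower = c(g_max = 0, c = 1e-3, bp_ctr = 10, k = 0.05, mu = 0.01,
                 p = -20),
       upper = c(g_max = 60, c = 1, bp_ctr = 90, k = 20, mu = 3, p = 60))
}

# 3-level multistart lattice over (g_max, c, bp_ctr) crossed with central
# (k, mu, p); order fixed so SSE ties break deterministically.
tmc_fit_starts <- function() {
  lattice <- expand.grid(g_max = c(10, 25, 40), c = c(0.1, 0.35, 0.6),
                         bp_ctr = c(30, 45, 60), KEEP.OUT.ATTRS = FALSE)
  lattice$k <- 1.5
  lattice$mu <- 0.5
  lattice$p <- 20
  lattice
}

# Residuals (observed - predicted) for a without-elicitor fit. theta is the
# named vector (g_max, c, bp_ctr, k, mu, p); invalid parameter combinations
# return large residuals so the optimizer backs away from them.
baseline_residuals <- function(theta, data, p_fixed) {
  p_val <- if (is.null(p_fixed)) theta[["p"]] else p_fixed
  params <- tryCatch(
    cochlear_io_params(theta[["g_max"]], theta[["c"]],
                       bp_ctr = theta[["bp_ctr"]], p = p_val),
    error = function(e) NULL)
  if (is.null(params)) return(rep(1e4, nrow(data)))
  ctx <- masking_context(data$signal_level_db_spl[1], theta[["k"]],
                         theta[["mu"]])
  pred <- ifelse(data$masker == "on",
                 predict_threshold(params, ctx, data$gap_ms, "on"),
                 predict_threshold(params, ctx, data$gap_ms, "off"))
  data$threshold_db_spl - pred
}

#' Fit the six baseline (without-elicitor) model parameters
#'
#' Minimizes the sum of squared differences between all observed and predicted
#' without-elicitor thresholds (on- and off-frequency together) by varying the
#' maximum gain `g_max`, compression exponent `c`, center of the compressive
#' range `bp_ctr`, signal-to-masker ratio `k`, masker decay rate `mu` and
#' passive attenuation `p`. Uses bounded nonlinear least squares
#' ([minpack.lm::nls.lm()]) from a fixed 27-point multistart lattice; the
#' start with the lowest SSE wins (ties broken by lattice order), so repeated
#' fits of the same data are identical.
#'
#' Without off-frequency rows the passive attenuation is not identifiable; it
#' is then fixed at `p_fixed` and flagged in the result.
#'
#' @param data A [tmc_dataset()]; only `elicitor == "without"` rows are used.
#' @param p_fixed Value at which to fix `p` when no off-frequency rows are
#'   present (default 20 dB).
#' @param control List of optimizer settings: `ftol`, `ptol` (default
#'   `1e-10`) and `maxfev` (default 2000 evaluations per start).
#' @return An object of class `tmc_fit`: `params` ([cochlear_io_params()]),
#'   `ctx` ([masking_context()]), `effect` (`NULL`), `sse`, `rmsd_db`,
#'   `n_points`, `converged`, `n_starts_used`, `p_fixed` flag and the fitted
#'   rows in `data`.
#' @export
fit_tmc_baseline <- function(data, p_fixed = 20,
                             control = list(ftol = 1e-10, ptol = 1e-10,
                                            maxfev = 2000)) {
  data <- as.data.frame(data)
  data <- data[data$elicitor == "without", , drop = FALSE]
  n_on <- sum(data$masker == "on")
  n_off <- sum(data$masker == "off")
  if (n_on < 3)
    stop("need at least 3 without-elicitor on-frequency thresholds")
  if (n_off > 0 && n_off < 2)
    stop("need at least 2 off-frequency thresholds when any are supplied")
  if (length(unique(data$signal_level_db_spl)) != 1)
    stop("signal level must be constant within a subject's TMC data")
  fix_p <- n_off == 0
  bounds <- tmc_fit_bounds()
  free <- if (fix_p) setdiff(names(bounds$lower), "p") else
    names(bounds$lower)
  starts <- tmc_fit_starts()

  results <- list()
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    start <- unlist(starts[i, free])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        lower = bounds$lower[free], upper = bounds$upper[free],
        fn = function(par) {
          theta <- start
          theta[free] <- par
          baseline_residuals(theta, data,
                             p_fixed = if (fix_p) p_fixed else NULL)
        },
        control = minpack.lm::nls.lm.control(
          ftol = control$ftol, ptol = control$ptol, maxfev = control$maxfev)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_used <- n_used + 1L
    results[[n_used]] <- list(fit = fit, sse = sum(fit$fvec^2))
  }
  if (n_used == 0L) stop("all optimizer starts failed")

  sses <- vapply(results, `[[`, numeric(1), "sse")
  best_i <- which.min(sses)               # first in lattice order on exact ties
  best <- results[[best_i]]
  # candidate set: fits statistically tied with the best SSE. When the data
  # do not sample all three regimes of the tip IO function, the SSE surface
  # has exactly flat directions (e.g. g_max and bp1 trade off when the lower
  # knee is unsampled) and several starts end at equivalent but different
  # parameter vectors; the with-elicitor fit can distinguish them.
  tie_tol <- max(1e-8, 1e-6 * best$sse)
  tied <- which(sses <= best$sse + tie_tol)
  tied <- tied[order(tied != best_i)]     # best (lattice-order) first

  make_fit <- function(res) {
    theta <- res$fit$par
    p_val <- if (fix_p) p_fixed else theta[["p"]]
    list(params = cochlear_io_params(theta[["g_max"]], theta[["c"]],
                                     bp_ctr = theta[["bp_ctr"]], p = p_val),
         ctx = masking_context(data$signal_level_db_spl[1], theta[["k"]],
                               theta[["mu"]]),
         sse = res$sse)
  }
  candidates <- lapply(results[tied], function(r)
    tryCatch(make_fit(r), error = function(e) NULL))
  candidates <- Filter(Negate(is.null), candidates)
  # drop near-duplicate parameter vectors, preserving order
  if (length(candidates) > 1) {
    keys <- vapply(candidates, function(cd)
      paste(round(c(cd$params$g_max, cd$params$c, cd$params$bp_ctr,
                    cd$ctx$k, cd$ctx$mu, cd$params$p), 3), collapse = "|"),
      character(1))
    candidates <- candidates[!duplicated(keys)]
  }

  chosen <- candidates[[1]]
  n_points <- nrow(data)
  structure(
    list(params = chosen$params, ctx = chosen$ctx, effect = NULL,
         sse = chosen$sse, rmsd_db = sqrt(chosen$sse / n_points),
         n_points = n_points,
         converged = best$fit$info %in% 1:4,
         n_starts_used = n_used, p_fixed = fix_p, data = data,
         candidates = candidates),
    class = "tmc_fit")
}

#' Fit the elicitor-induced gain reduction
#'
#' Holds every baseline parameter fixed (break points, `k`, `mu`, `p`) and
#' varies only the gain reduction `delta_g` to minimize the SSE over the
#' with-elicitor thresholds. `delta_g` is not constrained to be positive; its
#' lower bound is only tightened where a large gain enhancement would push the
#' with-elicitor compression exponent below the well-conditioned range. The
#' with-elicitor compression exponent `c_tilde` follows from the fixed break
#' points. On-frequency rows alone are sufficient; off-frequency rows are used
#' when present.
#'
#' @param data A [tmc_dataset()]; only `elicitor == "with"` rows are used.
#' @param baseline A converged `tmc_fit` from [fit_tmc_baseline()].
#' @param bounds Search interval for `delta_g` in dB.
#' @return A `tmc_fit` whose `effect` is the fitted [elicitor_effect()];
#'   `params` and `ctx` are carried over from the baseline.
#' @export
fit_tmc_elicitor <- function(data, baseline, bounds = c(-30, 60)) {
  stopifnot(inherits(baseline, "tmc_fit"))
  if (!baseline$converged)
    warning("baseline fit did not converge; elicitor fit may be unreliable")
  data <- as.data.frame(data)
  data <- data[data$elicitor == "with", , drop = FALSE]
  if (nrow(data) == 0) stop("no with-elicitor rows")
  candidates <- baseline$candidates %||%
    list(list(params = baseline$params, ctx = baseline$ctx,
              sse = baseline$sse))

  fit_one <- function(params, ctx) {
    # keep c_tilde = 1 - (g_max - dG)/(bp2 - bp1) >= 1e-3
    width <- params$bp2 - params$bp1
    dg_min <- max(bounds[1], params$g_max - (1 - 1e-3) * width + 1e-9)
    sse_of <- function(dg) {
      eff <- elicitor_effect(dg, params)
      pred <- ifelse(data$masker == "on",
                     predict_threshold(params, ctx, data$gap_ms, "on", eff),
                     predict_threshold(params, ctx, data$gap_ms, "off", eff))
      sum((data$threshold_db_spl - pred)^2)
    }
    # coarse grid to localize the global minimum (SSE is piecewise smooth in
    # delta_g), then a Brent polish in the bracketing interval
    grid <- seq(dg_min, bounds[2], by = 0.25)
    sse_grid <- vapply(grid, sse_of, numeric(1))
    i <- which.min(sse_grid)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(sse_of, c(lo, hi), tol = 1e-12)
    dg <- opt$minimum
    sse <- opt$objective
    # beyond dg = g_max the effective gain is floored at zero, so the SSE is
    # exactly flat in dg; report the boundary value (the smallest equivalent
    # gain reduction)
    if (dg > params$g_max && params$g_max >= dg_min) {
      sse_b <- sse_of(params$g_max)
      if (sse_b <= sse + 1e-9) {
        dg <- params$g_max
        sse <- sse_b
      }
    }
    list(dg = dg, sse = sse)
  }

  # The without-elicitor data may leave directions of the baseline fit
  # undetermined (exactly flat SSE valleys when not all three response
  # regimes are sampled). Those directions are resolved by the with-elicitor
  # condition: a multistart weighted joint fit keeps the without-elicitor SSE
  # pinned at its fitted minimum (heavily weighted residuals) while
  # minimizing the with-elicitor SSE. Solutions that would degrade the
  # baseline fit are discarded, so the sequential procedure's baseline fit
  # quality is never traded away.
  bthresh <- baseline$sse + max(1e-8, 1e-6 * baseline$sse)
  pool <- list()
  for (cd in candidates) {
    res <- fit_one(cd$params, cd$ctx)
    pool[[length(pool) + 1]] <- list(params = cd$params, ctx = cd$ctx,
                                     dg = res$dg, sse = res$sse,
                                     bsse = cd$sse)
  }
  if (!is.null(baseline$data)) {
    # a coarse lattice adds global diversity beyond the candidate set
    starts <- expand.grid(g_max = c(15, 40), c = c(0.15, 0.5),
                          bp_ctr = c(35, 55), KEEP.OUT.ATTRS = FALSE)
    starts$k <- 1.5
    starts$mu <- 0.5
    starts$p <- 20
    start_sets <- c(
      lapply(seq_len(nrow(starts)), function(i) {
        th <- starts[i, ]
        prm <- tryCatch(
          cochlear_io_params(th$g_max, th$c, bp_ctr = th$bp_ctr,
                             p = if (baseline$p_fixed) baseline$params$p
                                 else th$p),
          error = function(e) NULL)
        if (is.null(prm)) return(NULL)
        list(params = prm,
             ctx = masking_context(baseline$ctx$l_s, th$k, th$mu),
             dg = 5)
      }),
      lapply(pool, function(p0) list(params = p0$params, ctx = p0$ctx,
                                     dg = p0$dg)))
    for (st in start_sets) {
      if (is.null(st)) next
      if (min(vapply(pool, `[[`, numeric(1), "sse")) < 1e-14) break  # exact
      joint <- joint_elicitor_fit(data, baseline, st$params, st$ctx, st$dg,
                                  bounds)
      if (is.null(joint) || joint$bsse > bthresh) next
      final <- fit_one(joint$params, joint$ctx)  # re-polish delta_g,
      pool[[length(pool) + 1]] <-                # incl. boundary rule
        list(params = joint$params, ctx = joint$ctx, dg = final$dg,
             sse = final$sse, bsse = joint$bsse)
    }
  }
  best <- pool[[which.min(vapply(pool, `[[`, numeric(1), "sse"))]]
  # one restart from the winner: resetting the trust region often deepens
  # convergence on nearly-exact fits
  if (!is.null(baseline$data) && best$sse > 1e-12) {
    joint <- joint_elicitor_fit(data, baseline, best$params, best$ctx,
                                best$dg, bounds)
    if (!is.null(joint) && joint$bsse <= bthresh) {
      final <- fit_one(joint$params, joint$ctx)
      if (final$sse < best$sse - 1e-12)
        best <- list(params = joint$params, ctx = joint$ctx, dg = final$dg,
                     sse = final$sse, bsse = joint$bsse)
    }
  }
  params <- best$params
  ctx <- best$ctx
  dg <- best$dg
  sse <- best$sse
  effect <- elicitor_effect(dg, params)
  structure(
    list(params = params, ctx = ctx, effect = effect,
         sse = sse, rmsd_db = sqrt(sse / nrow(data)), n_points = nrow(data),
         converged = TRUE, n_starts_used = length(candidates),
         p_fixed = baseline$p_fixed, data = data),
    class = "tmc_fit")
}

# Weighted joint fit over (baseline parameters, delta_g) from one start:
# the without-elicitor residuals carry a large weight, so the optimizer
# keeps them at their minimum and spends the remaining freedom (directions
# the without-elicitor data leave flat) on the with-elicitor residuals.
joint_elicitor_fit <- function(data_with, baseline, params, ctx, dg,
                               bounds) {
  base_data <- baseline$data
  if (is.null(base_data)) return(NULL)
  fix_p <- isTRUE(baseline$p_fixed)
  bnds <- tmc_fit_bounds()
  free <- if (fix_p) setdiff(names(bnds$lower), "p") else names(bnds$lower)

  theta0 <- c(g_max = params$g_max, c = params$c, bp_ctr = params$bp_ctr,
              k = ctx$k, mu = ctx$mu, p = params$p)[c(free)]
  x0 <- c(theta0, dg = dg)
  lower <- c(bnds$lower[free], dg = bounds[1])
  upper <- c(bnds$upper[free], dg = bounds[2])

  w_base <- 300   # weight pinning the baseline residuals at their minimum
  resid_fn <- function(x) {
    theta <- x[seq_along(theta0)]
    names(theta) <- names(theta0)
    if (fix_p) theta <- c(theta, p = params$p)
    bad <- rep(1e4, nrow(base_data) + nrow(data_with))
    prm <- tryCatch(
      cochlear_io_params(theta[["g_max"]], theta[["c"]],
                         bp_ctr = theta[["bp_ctr"]], p = theta[["p"]]),
      error = function(e) NULL)
    if (is.null(prm)) return(bad)
    cx <- masking_context(base_data$signal_level_db_spl[1], theta[["k"]],
                          theta[["mu"]])
    eff <- tryCatch(elicitor_effect(x[["dg"]], prm), error = function(e) NULL)
    if (is.null(eff)) return(bad)
    bres <- baseline_residuals(
      c(theta[c("g_max", "c", "bp_ctr", "k", "mu")], p = theta[["p"]]),
      base_data, p_fixed = NULL)
    pred <- ifelse(data_with$masker == "on",
                   predict_threshold(prm, cx, data_with$gap_ms, "on", eff),
                   predict_threshold(prm, cx, data_with$gap_ms, "off", eff))
    c(w_base * bres, data_with$threshold_db_spl - pred)
  }

  opt <- tryCatch(
    minpack.lm::nls.lm(par = x0, lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-12, ptol = 1e-12, maxfev = 2000,
                         maxiter = 150)),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  theta <- opt$par[seq_along(theta0)]
  names(theta) <- names(theta0)
  if (fix_p) theta <- c(theta, p = params$p)
  prm <- tryCatch(
    cochlear_io_params(theta[["g_max"]], theta[["c"]],
                       bp_ctr = theta[["bp_ctr"]], p = theta[["p"]]),
    error = function(e) NULL)
  if (is.null(prm)) return(NULL)
  bsse <- sum(baseline_residuals(
    c(theta[c("g_max", "c", "bp_ctr", "k", "mu")], p = theta[["p"]]),
    base_data, p_fixed = NULL)^2)
  cx <- masking_context(base_data$signal_level_db_spl[1], theta[["k"]],
                        theta[["mu"]])
  list(params = prm, ctx = cx, bsse = bsse,
       esse = sum(utils::tail(opt$fvec, nrow(data_with))^2))
}

#' @export
print.tmc_fit <- function(x, ...) {
  cat("TMC model fit (", x$n_points, " thresholds, RMSD ",
      sprintf("%.3f", x$rmsd_db), " dB)\n", sep = "")
  print(x$params)
  cat(sprintf("  k      = %.3f\n  mu     = %.3f dB/ms\n",
              x$ctx$k, x$ctx$mu))
  if (!is.null(x$effect))
    cat(sprintf("  dG     = %.2f dB\n  c_tilde= %.3f\n",
                x$effect$delta_g, x$effect$c_tilde))
  if (x$p_fixed) cat("  (P fixed: no off-frequency thresholds supplied)\n")
  invisible(x)
}

#' Predict the unmeasured off-frequency TMC from a baseline fit
#'
#' For reduced designs where the with-elicitor off-frequency TMC was not
#' measured, the without-elicitor off-frequency TMC predicted by the fitted
#' model (a line of slope `mu`) stands in when constructing the inferred IO
#' function.
#'
#' @param baseline A `tmc_fit` from [fit_tmc_baseline()].
#' @param gaps Masker-signal gaps in ms.
#' @return Predicted off-frequency thresholds in dB SPL.
#' @export
predict_missing_off_tmc <- function(baseline, gaps) {
  stopifnot(inherits(baseline, "tmc_fit"))
  predict_tmc(baseline$params, baseline$ctx, gaps, "off",
              effect = baseline$effect)
}

#' Summarize paired baseline + elicitor fits as a parameter-table row
#'
#' One row in the conventional reporting layout: `G_max`, `c`, `BP_ctr`, `k`,
#' `mu`, `P`, `dG`, `c_tilde`, plus `rmsd_db` (over all rows fitted) and
#' `converged`.
#'
#' @param baseline,elicitor `tmc_fit` objects for one subject.
#' @param subject_id Identifier placed in the first column.
#' @return A one-row data frame.
#' @export
fit_report_row <- function(baseline, elicitor = NULL, subject_id = NA) {
  sse <- baseline$sse + if (is.null(elicitor)) 0 else elicitor$sse
  n <- baseline$n_points + if (is.null(elicitor)) 0L else elicitor$n_points
  # where an elicitor fit exists, its params carry the baseline parameters
  # with any directions the without-elicitor data left undetermined resolved
  # by the with-elicitor condition
  src <- if (is.null(elicitor)) baseline else elicitor
  data.frame(
    subject_id = subject_id,
    G_max = src$params$g_max,
    c = src$params$c,
    BP_ctr = src$params$bp_ctr,
    k = src$ctx$k,
    mu = src$ctx$mu,
    P = src$params$p,
    dG = if (is.null(elicitor)) NA_real_ else elicitor$effect$delta_g,
    c_tilde = if (is.null(elicitor)) NA_real_ else elicitor$effect$c_tilde,
    rmsd_db = sqrt(sse / n),
    converged = baseline$converged && (is.null(elicitor) ||
                                         elicitor$converged))
}

#' Fit both conditions for every subject in a TMC table
#'
#' Runs [fit_tmc_baseline()] and (where with-elicitor rows exist)
#' [fit_tmc_elicitor()] per subject and binds the [fit_report_row()] results.
#'
#' @param data A [tmc_dataset()] possibly holding many subjects.
#' @param p_fixed Passed to [fit_tmc_baseline()].
#' @return A data frame with one row per subject.
#' @export
fit_tmc_cohort <- function(data, p_fixed = 20) {
  data <- as.data.frame(data)
  rows <- lapply(unique(data$subject_id), function(sid) {
    sub <- data[data$subject_id == sid, , drop = FALSE]
    base <- fit_tmc_baseline(sub, p_fixed = p_fixed)
    elic <- if (any(sub$elicitor == "with"))
      fit_tmc_elicitor(sub, base) else NULL
    fit_report_row(base, elic, subject_id = sid)
  })
  do.call(rbind, rows)
}
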