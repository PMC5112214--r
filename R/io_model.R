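#' Piecewise-linear cochlear input-output parameters
#'
#' Constructs the parameter set describing the tip (active) and tail (passive)
#' response of a cochlear place. The tip input-output function has unit slope
#' below the lower break point `bp1`, slope `c` (the compression exponent)
#' between the break points, and unit slope again above the upper break point
#' `bp2`. The maximum gain, the compression exponent and the width of the
#' compressive range are mutually constrained by
#' `g_max = (1 - c) * (bp2 - bp1)`, so the object is parameterized by
#' (`g_max`, `c`, `bp1`) and `bp2` is derived. Either `bp1` or the center of
#' the compressive range `bp_ctr = (bp1 + bp2) / 2` may be supplied.
#'
#' @param g_max Maximum tip gain in dB (>= 0).
#' @param c Compression exponent, dimensionless, in (0, 1]. Values below
#'   `1e-3` are rejected to keep the inverse tip function well conditioned.
#' @param bp1 Lower break point in dB SPL (supply this or `bp_ctr`).
#' @param bp_ctr Center of the compressive range in dB SPL.
#' @param p Passive attenuation of the tail response in dB (may be negative).
#'
#' @return An object of class `cochlear_io_params` with elements `g_max`,
#'   `c`, `bp1`, `bp2`, `bp_ctr` and `p`.
#' @examples
#' par <- cochlear_io_params(g_max = 30, c = 0.2, bp1 = 28.125, p = 20)
#' par$bp2  # 65.625
#' @export
cochlear_io_params <- function(g_max, c, bp1 = NULL, bp_ctr = NULL, p = 0) {
  stopifnot(is.finite(g_max), is.finite(c), is.finite(p))
  if (g_max < 0) stop("g_max must be non-negative")
  if (c < 1e-3 || c > 1) stop("compression exponent c must lie in [1e-3, 1]")
  half_width <- if (c < 1) g_max / (1 - c) / 2 else 0
  if (is.null(bp1) && is.null(bp_ctr))
    stop("supply either bp1 or bp_ctr")
  if (is.null(bp1)) bp1 <- bp_ctr - half_width
  stopifnot(is.finite(bp1))
  bp2 <- bp1 + 2 * half_width
  if (g_max > 0 && bp2 <= bp1)
    stop("degenerate compressive range (bp2 <= bp1) with positive gain")
  structure(
    list(g_max = g_max, c = c, bp1 = bp1, bp2 = bp2,
         bp_ctr = (bp1 + bp2) / 2, p = p),
    class = "cochlear_io_params"
  )
}

#' @export
print.cochlear_io_params <- function(x, ...) {
  cat("Cochlear IO parameters:\n")
  cat(sprintf("  G_max  = %.2f dB\n  c      = %.3f\n  BP1    = %.2f dB SPL\n",
              x$g_max, x$c, x$bp1))
  cat(sprintf("  BP2    = %.2f dB SPL\n  BP_ctr = %.2f dB SPL\n  P      = %.2f dB\n",
              x$bp2, x$bp_ctr, x$p))
  invisible(x)
}

#' Masking context for forward-masking threshold predictions
#'
#' @param l_s Signal level in dB SPL.
#' @param k Signal-to-masker response ratio at threshold (linear intensity
#'   units, > 0). Enters thresholds as `-10 * log10(k)` dB.
#' @param mu Decay rate of the masker effect in dB/ms (>= 0); equals the
#'   slope of the off-frequency temporal masking curve.
#' @return An object of class `masking_context`.
#' @export
masking_context <- function(l_s, k, mu) {
  stopifnot(is.finite(l_s), is.finite(k), is.finite(mu))
  if (k <= 0) stop("k must be positive")
  if (mu < 0) stop("mu must be non-negative")
  structure(list(l_s = l_s, k = k, mu = mu), class = "masking_context")
}

#' Elicitor-induced gain reduction and derived compression exponent
#'
#' The contralateral elicitor is modelled as reducing the maximum tip gain by
#' `delta_g` while the break points stay fixed, which forces the with-elicitor
#' compression exponent to `c_tilde = 1 - (g_max - delta_g) / (bp2 - bp1)`,
#' clamped at 1 (the effective gain cannot fall below zero). `delta_g` itself
#' is not sign-constrained: negative values describe gain enhancement.
#'
#' @param delta_g Gain reduction in dB (any sign).
#' @param params A [cochlear_io_params()] object supplying the baseline
#'   `g_max` and break points.
#' @return An object of class `elicitor_effect` with `delta_g` and `c_tilde`.
#' @export
elicitor_effect <- function(delta_g, params) {
  stopifnot(inherits(params, "cochlear_io_params"), is.finite(delta_g))
  width <- params$bp2 - params$bp1
  c_tilde <- if (width > 0) min(1, 1 - (params$g_max - delta_g) / width) else 1
  if (c_tilde < 1e-3)
    stop("delta_g implies a with-elicitor compression exponent below 1e-3 ",
         "(gain enhancement too large for the fixed break points)")
  structure(list(delta_g = delta_g, c_tilde = c_tilde),
            class = "elicitor_effect")
}

# Baseline params with the elicitor applied: g_max reduced (floored at 0),
# break points unchanged, compression exponent replaced by c_tilde.
apply_elicitor <- function(params, effect) {
  if (is.null(effect)) return(params)
  stopifnot(inherits(effect, "elicitor_effect"))
  g_e <- max(params$g_max - effect$delta_g, 0)
  out <- params
  out$g_max <- g_e
  out$c <- effect$c_tilde
  out
}

#' Level-dependent tip gain
#'
#' `G(L) = g_max` below `bp1`, `(c - 1) * (L - bp1) + g_max` between the break
#' points, and 0 above `bp2`: continuous and non-increasing in level.
#'
#' @param params A [cochlear_io_params()] object.
#' @param level Input level(s) in dB SPL.
#' @return Gain in dB, same length as `level`.
#' @export
gain_at_level <- function(params, level) {
  stopifnot(inherits(params, "cochlear_io_params"), all(is.finite(level)))
  pmax(pmin((params$c - 1) * (level - params$bp1) + params$g_max,
            params$g_max), 0)
}

#' Tip (active) response output level
#'
#' Output of the tip input-output function `f_a` in dB: the input level plus
#' the level-dependent gain. Strictly increasing with slopes 1, `c`, 1 in the
#' three regimes. In intensity units this is `10^((L + G(L)) / 10)`.
#'
#' @inheritParams gain_at_level
#' @return Output level(s) in dB.
#' @export
tip_output <- function(params, level) {
  level + gain_at_level(params, level)
}

#' Tail (passive) response output level
#'
#' Output of the tail input-output function `f_p` in dB: the input level minus
#' the passive attenuation `p` (which may be negative).
#'
#' @inheritParams gain_at_level
#' @return Output level(s) in dB.
#' @export
tail_output <- function(params, level) {
  stopifnot(inherits(params, "cochlear_io_params"), all(is.finite(level)))
  level - params$p
}

#' Inverse of the tip response function
#'
#' Piecewise-linear inverse of [tip_output()] with slopes 1, `1/c`, 1. Total
#' on the real line because `c > 0` is enforced at construction.
#'
#' @param params A [cochlear_io_params()] object.
#' @param output Output level(s) in dB.
#' @return Input level(s) in dB SPL such that `tip_output(params, L) = output`.
#' @export
invert_tip_output <- function(params, output) {
  stopifnot(inherits(params, "cochlear_io_params"), all(is.finite(output)))
  knee_lo <- params$bp1 + params$g_max   # tip output at bp1
  knee_hi <- params$bp2                  # tip output at bp2 (zero gain)
  ifelse(output <= knee_lo, output - params$g_max,
         ifelse(output >= knee_hi, output,
                params$bp1 + (output - knee_lo) / params$c))
}

#' Predict a forward-masking threshold
#'
#' Implements the masking-threshold model: the signal response `f_a(L_s)`
#' must equal `k` times the masker effect, which decays at `mu` dB/ms over the
#' masker-signal gap. The required masker *output* in dB is therefore
#' `f_a(L_s) - 10 log10(k) + mu * gap`; the on-frequency threshold maps this
#' output back through the inverse tip function, the off-frequency threshold
#' through the inverse tail function (adds `p`). With an elicitor effect, the
#' signal and on-frequency masker use the gain-reduced tip function while the
#' off-frequency tail response is unchanged.
#'
#' @param params A [cochlear_io_params()] object.
#' @param ctx A [masking_context()] object.
#' @param gap_ms Masker-signal gap(s) in ms (>= 0).
#' @param masker `"on"` (masker at the signal frequency, tip-driven) or
#'   `"off"` (masker well below the signal frequency, tail-driven).
#' @param effect Optional [elicitor_effect()].
#' @return Masking threshold(s) in dB SPL.
#' @examples
#' par <- cochlear_io_params(30, 0.2, bp1 = 28.125, p = 20)
#' ctx <- masking_context(l_s = 20, k = 1.5, mu = 0.5)
#' predict_threshold(par, ctx, 0, "off")  # 68.24 dB SPL
#' @export
predict_threshold <- function(params, ctx, gap_ms, masker = c("on", "off"),
                              effect = NULL) {
  masker <- match.arg(masker)
  stopifnot(inherits(params, "cochlear_io_params"),
            inherits(ctx, "masking_context"),
            all(is.finite(gap_ms)), all(gap_ms >= 0))
  active <- apply_elicitor(params, effect)
  required_output <- tip_output(active, ctx$l_s) - 10 * log10(ctx$k) +
    ctx$mu * gap_ms
  if (masker == "on") {
    invert_tip_output(active, required_output)
  } else {
    required_output + params$p
  }
}

#' Predict a temporal masking curve
#'
#' Vectorized [predict_threshold()] over a sequence of masker-signal gaps.
#' The off-frequency TMC is exactly affine in gap with slope `mu` dB/ms; the
#' on-frequency TMC has local slope `mu`, `mu / c`, `mu` in the linear,
#' compressive and upper-linear regimes.
#'
#' @inheritParams predict_threshold
#' @param gaps Masker-signal gaps in ms (may be empty).
#' @return Thresholds in dB SPL, one per gap.
#' @export
predict_tmc <- function(params, ctx, gaps, masker = c("on", "off"),
                        effect = NULL) {
  masker <- match.arg(masker)
  if (length(gaps) == 0) return(numeric(0))
  predict_threshold(params, ctx, gaps, masker, effect)
}

#' Predict an off-frequency growth-of-masking (GOM) function
#'
#' Off-frequency masking threshold as a function of signal level at a fixed
#' masker-signal gap. Its slope against signal level equals 1 where the signal
#' sits on a linear limb of the tip function and `c` inside the compressive
#' range, so the GOM function traces the cochlear IO function directly.
#'
#' @inheritParams predict_threshold
#' @param gap_ms Single masker-signal gap in ms.
#' @param signal_levels Signal levels in dB SPL.
#' @return Off-frequency thresholds in dB SPL, one per signal level.
#' @export
predict_gom <- function(params, ctx, gap_ms, signal_levels, effect = NULL) {
  stopifnot(length(gap_ms) == 1)
  vapply(signal_levels, function(ls) {
    ctx_l <- masking_context(ls, ctx$k, ctx$mu)
    predict_threshold(params, ctx_l, gap_ms, "off", effect)
  }, numeric(1))
}

#' Apply direct excitatory masking by the elicitor
#'
#' The alternative to gain reduction: a central excitatory masking effect is
#' equivalent to dividing the signal response by an attenuation factor, which
#' shifts the on- and off-frequency masking thresholds down by the same dB
#' amount (in linear regimes) without changing the on-frequency TMC slope or
#' the inferred IO function. Implemented by scaling the threshold
#' signal-to-masker ratio `k` by the attenuation factor.
#'
#' @param ctx A [masking_context()] object.
#' @param attenuation_db Attenuation of the signal response in dB (>= 0).
#' @return A new `masking_context`.
#' @export
apply_excitatory_masking <- function(ctx, attenuation_db) {
  stopifnot(inherits(ctx, "masking_context"), is.finite(attenuation_db),
            attenuation_db >= 0)
  masking_context(ctx$l_s, ctx$k * 10^(attenuation_db / 10), ctx$mu)
}

#' Infer the cochlear IO function from paired TMCs
#'
#' Plots the off-frequency masking threshold (minus the passive attenuation
#' `p`) against the gap-matched on-frequency threshold. Each point pairs the
#' tip-function input (the on-frequency threshold) with its output (the
#' off-frequency threshold corrected for passive filtering). No smoothing is
#' applied and the gap order is preserved.
#'
#' @param on_thresholds,off_thresholds Gap-aligned on- and off-frequency
#'   thresholds in dB SPL (equal lengths).
#' @param p Passive attenuation in dB.
#' @return A data frame with columns `input_level` and `output_level` (dB).
#' @export
infer_io_function <- function(on_thresholds, off_thresholds, p) {
  if (length(on_thresholds) != length(off_thresholds))
    stop("on- and off-frequency thresholds must be gap-aligned (equal length)")
  stopifnot(is.finite(p))
  data.frame(input_level = as.numeric(on_thresholds),
             output_level = as.numeric(off_thresholds) - p)
}
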