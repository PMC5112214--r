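#' Equivalent rectangular bandwidth of the normal auditory filter
#'
#' `ERB_N = 24.67 * (4.37 * CF + 1)` Hz with the characteristic frequency CF
#' in kHz.
#'
#' @param cf_khz Characteristic frequency in kHz (> 0).
#' @return Bandwidth in Hz.
#' @examples
#' erb_at_cf(2)  # 240.29 Hz
#' @export
erb_at_cf <- function(cf_khz) {
  if (any(!is.finite(cf_khz)) || any(cf_khz <= 0))
    stop("characteristic frequency must be positive")
  24.67 * (4.37 * cf_khz + 1)
}

#' Rounded-exponential (roex) filter weight
#'
#' Symmetric single-parameter roex shape `W(g) = (1 + p|g|) exp(-p|g|)` with
#' `g` the normalized frequency deviation from the filter center and
#' `p = 4 * center / ERB`.
#'
#' @param p Slope parameter (> 0).
#' @param g Normalized frequency deviation(s), `(f - center) / center`.
#' @return Weight(s) in (0, 1]; `W(0) = 1`.
#' @export
roex_weight <- function(p, g) {
  stopifnot(is.finite(p), p > 0)
  pg <- p * abs(g)
  (1 + pg) * exp(-pg)
}

#' Excitation pattern of a pure tone through a dual-roex filterbank
#'
#' Each cochlear place (characteristic frequency, CF) is modelled as an
#' active tip filter in parallel with a passive tail filter. The tip filter
#' is a roex centered at CF with bandwidth `ERB_N(CF)`; its output level is
#' then amplified by the level-dependent gain `G(L)` of the place's IO
#' function (gain applied to the *filtered* level). The tail filter is a
#' roex centered a quarter octave below CF with a bandwidth of
#' `3 * ERB_N(CF)` and zero gain. The two path intensities are summed and
#' the pattern is reported in dB.
#'
#' @param stimulus_freq_hz Tone frequency in Hz.
#' @param stimulus_level_db_spl Tone level in dB SPL.
#' @param params A [cochlear_io_params()] object supplying the tip gain rule.
#' @param cf_grid_hz Ascending grid of characteristic frequencies in Hz;
#'   default 101 log-spaced CFs spanning one octave either side of 2 kHz.
#' @return A data frame with columns `cf_hz`, `excitation_db`, `tip_db` and
#'   `tail_db`.
#' @export
excitation_pattern <- function(stimulus_freq_hz, stimulus_level_db_spl,
                               params,
                               cf_grid_hz = 2000 * 2^seq(-1, 1,
                                                         length.out = 101)) {
  stopifnot(inherits(params, "cochlear_io_params"),
            is.finite(stimulus_freq_hz), stimulus_freq_hz > 0,
            is.finite(stimulus_level_db_spl))
  if (length(cf_grid_hz) == 0) stop("empty CF grid")
  if (is.unsorted(cf_grid_hz, strictly = TRUE))
    stop("CF grid must be sorted ascending")

  erb <- erb_at_cf(cf_grid_hz / 1000)
  # tip path: roex at CF, bandwidth ERB_N, then level-dependent gain
  p_tip <- 4 * cf_grid_hz / erb
  g_tip <- (stimulus_freq_hz - cf_grid_hz) / cf_grid_hz
  tip_level <- stimulus_level_db_spl + 10 * log10(roex_weight_vec(p_tip, g_tip))
  tip_db <- tip_level + gain_at_level(params, tip_level)
  # tail path: roex a quarter octave below CF, bandwidth 3 ERB_N, zero gain
  center_tail <- cf_grid_hz * 2^(-1 / 4)
  p_tail <- 4 * center_tail / (3 * erb)
  g_tail <- (stimulus_freq_hz - center_tail) / center_tail
  tail_db <- stimulus_level_db_spl + 10 * log10(roex_weight_vec(p_tail, g_tail))

  excitation_db <- 10 * log10(10^(tip_db / 10) + 10^(tail_db / 10))
  data.frame(cf_hz = cf_grid_hz, excitation_db = excitation_db,
             tip_db = tip_db, tail_db = tail_db)
}

# vectorized over (p, g) pairs
roex_weight_vec <- function(p, g) {
  pg <- p * abs(g)
  (1 + pg) * exp(-pg)
}

#' Write an excitation pattern as delimited text
#'
#' @param pattern Result of [excitation_pattern()].
#' @param path Output file path.
#' @export
write_excitation <- function(pattern, path) {
  utils::write.table(pattern[c("cf_hz", "excitation_db")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
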