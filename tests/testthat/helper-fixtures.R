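# Reference parameter set used throughout: G_max = 30 dB, c = 0.2,
# BP1 = 28.125 dB SPL (so BP2 = 65.625), P = 20 dB, k = 1.5, mu = 0.5 dB/ms.
ref_params <- function(p = 20) cochlear_io_params(30, 0.2, bp1 = 28.125, p = p)

ref_ctx <- function(l_s = 20) masking_context(l_s = l_s, k = 1.5, mu = 0.5)

# Noiseless TMC rows for one masker x elicitor cell of a synthetic subject.
model_tmc_rows <- function(params, ctx, gaps, masker, elicitor = "without",
                           effect = NULL, id = "X") {
  data.frame(subject_id = id, gap_ms = gaps, masker = masker,
             elicitor = elicitor,
             threshold_db_spl = predict_tmc(params, ctx, gaps, masker,
                                            effect),
             signal_level_db_spl = ctx$l_s)
}

# Full-design noiseless dataset (both maskers, both elicitor conditions).
model_tmc_dataset <- function(params, ctx, delta_g = NULL,
                              gaps = seq(5, 30, 5)) {
  rows <- rbind(model_tmc_rows(params, ctx, gaps, "on"),
                model_tmc_rows(params, ctx, gaps, "off"))
  if (!is.null(delta_g)) {
    eff <- elicitor_effect(delta_g, params)
    rows <- rbind(rows,
                  model_tmc_rows(params, ctx, gaps, "on", "with", eff),
                  model_tmc_rows(params, ctx, gaps, "off", "with", eff))
  }
  tmc_dataset(rows)
}

# Published per-subject parameter estimates shipped with the package.
published_params <- function() {
  read_param_table(system.file("extdata", "cohort_params_2khz.tsv",
                               package = "moctmc"))
}
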