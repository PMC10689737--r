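#' The 67-feature catalogue
#'
#' The pipeline computes exactly 67 features per accepted 5-minute segment:
#' 30 heart rate variability (HRV) features and 37 pulse-wave morphology
#' features. These vectors give their canonical column names, used throughout
#' the feature tables produced by [extract_features()].
#'
#' HRV features (30): time domain (`meanHR`, `SDNN`, `RMSSD`, `pNN50`,
#' `kurtosis`, `skewness`), frequency domain (`VLF`, `LF`, `HF`, `LFnu`,
#' `HFnu`, `LF_HF`), non-linear (`SD1`, `SD2`, `SD1_SD2`, `S`, `alpha1`,
#' `SampEn`), phase-rectified signal averaging (`DC`, `AC`, `IDR`, `IAR`,
#' `SDR`, `SAR`, `ADR`, `AAR`) and heart rate fragmentation (`PIP`, `PAS`,
#' `PSS`, `IALS`).
#'
#' Morphology features (37): amplitudes (`PWA`, `b2_amplitude`), time
#' intervals (`PWD`, `SPD`, `DPD`, `t_a1`, `t_a1b1`, `t_a2b2`, `t_b2e2`,
#' `t_s`), areas (`AUC_total`, `AUC1`, `AUC2`), velocity/acceleration
#' (`mean_V`, `IDR_V`, `mean_Acc`, `MSV`, `SFV`, `EDV`), width ratios
#' (`DW10_SW10`, `DW25_SW25`, `DW50_SW50`, `DW60_SW60`), time ratios
#' (`t_s_PWD`, `t_a1_PWD`, `t_a1b1_PWD`, `t_a2b2_PWD`, `t_b2e2_PWD`),
#' second-derivative amplitude ratios (`b2_a2`, `e2_a2`), `SPD_PWD`,
#' `SP_SPD`, `pulsatility_index`, slopes (`slope_IT_SP`, `slope_SP_FT`) and
#' angles (`alpha_angle`, `gamma_angle`).
#'
#' @format Character vectors of canonical feature names.
#' @name feature_catalogue
NULL

#' @rdname feature_catalogue
#' @export
hrv_feature_names <- c(
  "meanHR", "SDNN", "RMSSD", "pNN50", "kurtosis", "skewness",
  "VLF", "LF", "HF", "LFnu", "HFnu", "LF_HF",
  "SD1", "SD2", "SD1_SD2", "S", "alpha1", "SampEn",
  "DC", "AC", "IDR", "IAR", "SDR", "SAR", "ADR", "AAR",
  "PIP", "PAS", "PSS", "IALS"
)

#' @rdname feature_catalogue
#' @export
morph_feature_names <- c(
  "PWA", "b2_amplitude",
  "PWD", "SPD", "DPD", "t_a1", "t_a1b1", "t_a2b2", "t_b2e2", "t_s",
  "AUC_total", "AUC1", "AUC2",
  "mean_V", "IDR_V", "mean_Acc", "MSV", "SFV", "EDV",
  "DW10_SW10", "DW25_SW25", "DW50_SW50", "DW60_SW60",
  "t_s_PWD", "t_a1_PWD", "t_a1b1_PWD", "t_a2b2_PWD", "t_b2e2_PWD",
  "b2_a2", "e2_a2", "SPD_PWD", "SP_SPD", "pulsatility_index",
  "slope_IT_SP", "slope_SP_FT",
  "alpha_angle", "gamma_angle"
)

#' @rdname feature_catalogue
#' @export
all_feature_names <- c(hrv_feature_names, morph_feature_names)

#' Candidate feature pools for ranking
#'
#' Returns the candidate feature names for a feature-set choice. `PWD` is
#' excluded from the morphology and combined pools used for ranking because
#' it is analogous to mean heart rate, which is already part of the HRV set.
#'
#' @param feature_set One of `"hrv"`, `"morph"`, `"combined"`.
#' @return Character vector of feature names.
#' @export
feature_pool <- function(feature_set = c("hrv", "morph", "combined")) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
    hrv = hrv_feature_names,
    morph = setdiff(morph_feature_names, "PWD"),
    combined = c(hrv_feature_names, setdiff(morph_feature_names, "PWD"))
  )
}
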