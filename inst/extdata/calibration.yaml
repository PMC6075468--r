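# Versioned calibration for the synthetic two-wave cohort generator.
# Marginal descriptives, wave-to-wave serum stability, and the standardized
# serum-MRI coupling values used as generating truths in simulations.
version: 1
serum:
  w2_mean: 0.085      # ug/L
  w2_sd: 0.035
  w3_mean: 0.092
  w3_sd: 0.040
  stability_r: 0.585  # wave-2 / wave-3 Pearson correlation
ages:
  serum_w2_mean: 72.493   # years
  serum_w2_sd: 0.716
  serum_w3_mean: 76.243
  serum_w3_sd: 0.679
  wave_lag_mean: 3.77
  wave_lag_sd: 0.28
  scan_lag_days_w2_mean: 65.39
  scan_lag_days_w2_sd: 34.69
  scan_lag_days_w3_mean: 38.69
  scan_lag_days_w3_sd: 28.37
sex:
  male_n_w2: 395
  female_n_w2: 381
mmse:
  mean: 28.815
  sd: 1.285
volumes:              # cm^3
  tb_w2_mean: 991.176
  tb_w2_sd: 90.522
  tb_w3_mean: 976.179
  tb_w3_sd: 91.483
  gm_w2_mean: 472.862
  gm_w2_sd: 44.860
  gm_w3_mean: 466.321
  gm_w3_sd: 43.753
  wmh_w2_median: 8.060   # raw WMH is skewed; medians calibrate the log scale
  wmh_w3_median: 10.998
pvs:
  n_zero: 426
  n_plus_one: 42
couplings:            # standardized serum (level/change) x construct (level/change)
  wmh: {level: -0.019, change: 0.082}
  gfa: {level: -0.150, change: -0.083}
  gmd: {level: 0.003, change: -0.019}
  gm:  {level: 0.061, change: -0.050}
  tb:  {level: 0.045, change: -0.044}
  pvs_level: -0.034   # serum level x observed PVS change rating
  pvs_change: -0.096  # serum change x observed PVS change rating
tract_fa_level:       # serum level x single-tract FA level
  atr: -0.155
  cingulum: -0.111
  splenium: -0.087
  arcuate: -0.087
global_pvalues: [0.634, 0.475, 0.001, 0.941, 0.133, 0.272, 0.095, 0.041, 0.154, 0.717, 0.309, 0.364]
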