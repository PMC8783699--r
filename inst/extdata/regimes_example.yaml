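# Example simulator configuration: five parameter regimes emulating
# high-dispersion, multitrend beat-to-beat physiology. Each regime draws
# per-beat PTT (s), PIR (ratio), HR (bpm) from truncated normals and
# computes ground-truth pressures as
#   BP = intercept + ptt*PTT + pir*PIR + hr*HR + inv_ptt/PTT + noise.
# Used by: bp-pipeline.R simulate --config regimes_example.yaml
regimes:
  - regime_id: 1
    hr_mean_bpm: 73.0
    hr_sd: 5.0
    ptt_mean_s: 0.205
    ptt_sd: 0.025
    pir_mean: 1.73
    pir_sd: 0.15
    sbp_coeffs: {intercept: 60, ptt: -300, pir: 25, hr: 0.6, inv_ptt: 12}
    dbp_coeffs: {intercept: 30, ptt: -220, pir: 18, hr: 0.45, inv_ptt: 9}
    noise_sd_mmHg: 3.0
    n_beats: 60
  - regime_id: 2
    hr_mean_bpm: 73.0
    hr_sd: 5.0
    ptt_mean_s: 0.3425
    ptt_sd: 0.025
    pir_mean: 1.73
    pir_sd: 0.15
    sbp_coeffs: {intercept: -10, ptt: 280, pir: 20, hr: 0.5, inv_ptt: 6}
    dbp_coeffs: {intercept: -20, ptt: 200, pir: 14, hr: 0.35, inv_ptt: 4.5}
    noise_sd_mmHg: 3.0
    n_beats: 60
  - regime_id: 3
    hr_mean_bpm: 73.0
    hr_sd: 5.0
    ptt_mean_s: 0.205
    ptt_sd: 0.025
    pir_mean: 2.555
    pir_sd: 0.15
    sbp_coeffs: {intercept: 205, ptt: -200, pir: -35, hr: 0.55, inv_ptt: 5}
    dbp_coeffs: {intercept: 145, ptt: -150, pir: -25, hr: 0.4, inv_ptt: 4}
    noise_sd_mmHg: 3.0
    n_beats: 60
  - regime_id: 4
    hr_mean_bpm: 100.5
    hr_sd: 5.0
    ptt_mean_s: 0.205
    ptt_sd: 0.025
    pir_mean: 1.73
    pir_sd: 0.15
    sbp_coeffs: {intercept: 215, ptt: -220, pir: 16, hr: -0.8, inv_ptt: 4}
    dbp_coeffs: {intercept: 150, ptt: -160, pir: 12, hr: -0.55, inv_ptt: 3}
    noise_sd_mmHg: 3.0
    n_beats: 60
  - regime_id: 5
    hr_mean_bpm: 91.5
    hr_sd: 5.0
    ptt_mean_s: 0.2975
    ptt_sd: 0.025
    pir_mean: 2.285
    pir_sd: 0.15
    sbp_coeffs: {intercept: 15, ptt: 0, pir: 12, hr: 0.3, inv_ptt: 20}
    dbp_coeffs: {intercept: -5, ptt: 0, pir: 9, hr: 0.22, inv_ptt: 14}
    noise_sd_mmHg: 3.0
    n_beats: 60
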