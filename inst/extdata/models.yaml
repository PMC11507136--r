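# Published model inputs for the three cost-effectiveness scenarios.
# Probabilities are decimals (the source prints percent); costs are 2022 USD.
# icer_printed is the published ICER per modified ZBI-12 point (telehealth row,
# in-person as reference); it is carried only so results can report their
# deviation from it, never used in computation.
model_a:
  label: "Model A: urban-residing non-Hispanic White individuals"
  stratum: urban_nhw
  p_switch_in_to_tele: 0.3137
  p_switch_tele_to_in: 0.1829
  m_in: 0.1147
  m_tele: 0.0810
  ed_rate_in: 2.24
  ed_rate_tele: 1.52
  hosp_rate_in: 1.86
  hosp_rate_tele: 0.74
  c_ed: 6177
  c_hosp: 34950
  c_delivery_in: 230
  c_delivery_tele: 202
  e_in: 70.28
  e_tele: 67.35
  discount_rate: 0.03
  horizon: 10
  icer_printed: -9.44
model_b:
  label: "Model B: urban-residing racial minorities"
  stratum: urban_minority
  p_switch_in_to_tele: 0.2167
  p_switch_tele_to_in: 0.2677
  m_in: 0.1690
  m_tele: 0.1125
  ed_rate_in: 2.24
  ed_rate_tele: 1.52
  hosp_rate_in: 2.71
  hosp_rate_tele: 1.22
  c_ed: 6459
  c_hosp: 40635
  c_delivery_in: 237
  c_delivery_tele: 220
  e_in: 72.94
  e_tele: 73.55
  discount_rate: 0.03
  horizon: 10
  icer_printed: 29.26
model_c:
  label: "Model C: rural residents"
  stratum: rural
  p_switch_in_to_tele: 0.2667
  p_switch_tele_to_in: 0.3000
  m_in: 0.1029
  m_tele: 0.0752
  ed_rate_in: 1.20
  ed_rate_tele: 0.93
  hosp_rate_in: 0.96
  hosp_rate_tele: 0.61
  c_ed: 5193
  c_hosp: 30346
  c_delivery_in: 503
  c_delivery_tele: 436
  e_in: 60.58
  e_tele: 60.37
  discount_rate: 0.03
  horizon: 10
  icer_printed: -320.93
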