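# Demographic profiles of the Nevada ADRD telehealth cohorts (synthetic
# generator targets). Gender/race probabilities are the published cohort
# counts expressed as exact fractions (printed percentages are rounded and do
# not sum to one). The urban age range uses the upper bound 98 reported in
# the results text; see the package vignette for the rationale.
urban:
  stratum: urban
  n_source: 58
  age_mean: 81.3
  age_sd: 9.7
  age_min: 61
  age_max: 98
  gender_probs:
    male: 0.4137931034      # 24/58
    female: 0.5517241379    # 32/58
    other: 0.0344827586     # 2/58
  race_probs:
    nh_white: 0.5172413793        # 30/58
    nh_black: 0.1551724138        # 9/58
    hispanic_latino: 0.1379310345 # 8/58
    nh_asian: 0.1206896552        # 7/58
    other_mixed: 0.0689655172     # 4/58
urban_nhw:
  stratum: urban_nhw
  n_source: 30
  age_mean: 81.3
  age_sd: 9.7
  age_min: 61
  age_max: 98
  gender_probs:
    male: 0.4137931034
    female: 0.5517241379
    other: 0.0344827586
  race_probs:
    nh_white: 1.0
    nh_black: 0.0
    hispanic_latino: 0.0
    nh_asian: 0.0
    other_mixed: 0.0
urban_minority:
  stratum: urban_minority
  n_source: 28
  age_mean: 81.3
  age_sd: 9.7
  age_min: 61
  age_max: 98
  gender_probs:
    male: 0.4137931034
    female: 0.5517241379
    other: 0.0344827586
  race_probs:
    nh_white: 0.0
    nh_black: 0.3214285714        # 9/28
    hispanic_latino: 0.2857142857 # 8/28
    nh_asian: 0.25                # 7/28
    other_mixed: 0.1428571429     # 4/28
rural:
  stratum: rural
  n_source: 33
  age_mean: 82.6
  age_sd: 6.5
  age_min: 63
  age_max: 89
  gender_probs:
    male: 0.3939393939      # 13/33
    female: 0.6060606061    # 20/33
    other: 0.0
  race_probs:
    nh_white: 0.8484848485        # 28/33
    nh_black: 0.0303030303        # 1/33
    hispanic_latino: 0.0606060606 # 2/33
    nh_asian: 0.0
    other_mixed: 0.0606060606     # 2/33
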