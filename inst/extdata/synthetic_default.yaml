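# Default synthetic cohort: a ~1,230-patient colonoscopy cohort with a
# latent screening indication, three imperfect indication indicators, and
# claims-derived predictor flags.
#
# Calibration (one-off, documented in the methods vignette):
#   * prevalence 0.46 so indicator marginals land near the observed
#     46.8 / 51.0 / 38.9% screening fractions of the three indicators;
#   * indicator sensitivity/specificity chosen to reproduce those marginals:
#       0.46*S + 0.54*(1-C) = target marginal;
#   * each feature_probs pair (p_screening, p_non_screening) solves
#       0.46*p1 + 0.54*p0 = observed marginal flag frequency
#       odds(p1)/odds(p0) = target odds ratio (< 1: history flags are more
#       common before non-screening exams).  Odds-ratio targets follow the
#     BIC-selected logistic model where available, 0.5 otherwise.
n_patients: 1230
prevalence: 0.46
indicator_sens: [0.93, 0.87, 0.72]
indicator_spec: [0.93, 0.80, 0.89]
dep_cov_pos: 0.0
dep_cov_neg: 0.0
sex_ratio: 0.485          # probability male
age_range: [50, 75]       # years, eligibility bounds
age_mean: 60.1
age_sd: 6.9
index_period: ["2007-01-01", "2007-03-31"]
feature_probs:            # per category: [P(flag | screening), P(flag | non-screening)]
  colonoscopy:                 [0.0754, 0.3376]   # marginal 0.217, OR 0.16
  sigmoidoscopy:               [0.0282, 0.0908]   # marginal 0.062, OR 0.29
  polypectomy:                 [0.0376, 0.1401]   # marginal 0.093, OR 0.24
  dcbe:                        [0.0170, 0.0836]   # marginal 0.053, OR 0.19
  rectal_bleeding:             [0.0209, 0.1248]   # marginal 0.077, OR 0.15
  diarrhea:                    [0.0136, 0.0644]   # marginal 0.041, OR 0.20
  vomiting:                    [0.0039, 0.0078]   # marginal 0.006, OR 0.50
  weight_loss:                 [0.0046, 0.0091]   # marginal 0.007, OR 0.50
  anemia:                      [0.0189, 0.1136]   # marginal 0.070, OR 0.15
  crc:                         [0.0352, 0.0681]   # marginal 0.053, OR 0.50
  colorectal_polyps:           [0.1170, 0.2096]   # marginal 0.167, OR 0.50
  ibd:                         [0.0044, 0.0685]   # marginal 0.039, OR 0.06
  large_bowel_hospitalization: [0.0171, 0.0336]   # marginal 0.026, OR 0.50
  large_bowel_surgery:         [0.0138, 0.0272]   # marginal 0.021, OR 0.50
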