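name: antid
outcome: antid
strategies:
- id: s1
  label: Conventional management
- id: s2
  label: AADP to primigravidae
- id: s3
  label: AADP to all RhD-negative women
treatments:
- id: partobulin
  label: Partobulin
- id: dgam
  label: D-Gam
- id: rhophylac
  label: Rhophylac
- id: winrho
  label: WinRho
parameters:
- name: s0
  distribution: beta
  shape1: 9.5
  shape2: 990.5
  description: baseline sensitization probability
- name: or_eff
  distribution: lognormal
  meanlog: -0.947540731874155
  sdlog: 0.25
  description: effectiveness odds ratio (all products)
- name: p_prim
  distribution: beta
  shape1: 40.0
  shape2: 60.0
  description: proportion primigravidae
- name: p_subseq
  distribution: beta
  shape1: 70.0
  shape2: 30.0
  description: subsequent RhD+ pregnancy | sensitized
- name: p_affected
  distribution: beta
  shape1: 60.0
  shape2: 40.0
  description: fetus affected by HDN | sensitized
- name: p_loss
  distribution: beta
  shape1: 5.0
  shape2: 95.0
  description: fetal loss | affected
- name: q_affected
  distribution: gamma
  shape: 16.0
  rate: 8.0
  description: QALY loss per affected fetus
- name: q_loss
  distribution: gamma
  shape: 25.0
  rate: 1.0
  description: QALY loss per fetal loss
- name: ly_loss
  distribution: point
  value: 75.0
- name: d_eff
  distribution: uniform
  min: 0.0
  max: 0.07
  description: annual discount rate, effects
- name: d_cost
  distribution: point
  value: 0.035
- name: t_lag
  distribution: point
  value: 2.0
- name: n_doses
  distribution: point
  value: 2.0
- name: c_dose_partobulin
  distribution: point
  value: 27.5
- name: c_dose_dgam
  distribution: point
  value: 25.0
- name: c_dose_rhophylac
  distribution: point
  value: 32.0
- name: c_dose_winrho
  distribution: point
  value: 30.0
- name: c_admin
  distribution: point
  value: 5.0
- name: c_sens
  distribution: gamma
  shape: 100.0
  rate: 0.03448275862069
  description: lifetime cost per sensitized woman
- name: c_hdn
  distribution: gamma
  shape: 25.0
  rate: 0.001666666666667
  description: cost per affected fetus
- name: cohort
  distribution: point
  value: 100000.0
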