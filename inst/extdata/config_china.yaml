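country: china
wtp: 40451.639999999999
settings:
  cycle_days: 21.0
  horizon_years: 50.0
  discount_annual: 0.05
  half_cycle: yes
population:
  weight_kg: 65.0
  bsa_m2: 1.72
survival:
  evp:
    pfs:
      family: lognormal
      params:
        meanlog: 2.6709
        sdlog: 1.4649
    os:
      family: loglogistic
      params:
        shape: 1.3124
        scale: 32.1285
  ngc:
    pfs:
      family: gengamma
      params:
        mu: 1.9794
        sigma: 1.1635
        Q: -0.6043
    os:
      family: lognormal
      params:
        meanlog: 3.1474
        sdlog: 1.235
utilities:
  pfs: 0.772
  pd: 0.698
drug_prices:
  ev_20mg: 740.14
  pembro_100mg: 2541.56
  nivo_40mg: 650.6
  gem_1000mg: 5.74
  cis_50mg: 8.19
costs:
  second_line_cycle: 157.38
  bsc_cycle: 711.0
  imaging_cycle: 143.0
  administration: 404.79
  labs_radiology: 672.02
  hospitalization: 47.32
  followup: 27.37
  terminal: 1761.0
ae:
  evp:
  - name: peripheral_sensory_neuropathy
    prob: 0.041
    disutility: 0.33
    cost: 16089.48
  - name: maculopapular_rash
    prob: 0.077
    disutility: 0.032
    cost: 85.81
  - name: diarrhea
    prob: 0.039
    disutility: 0.05
    cost: 15016.709999999999
  - name: anemia
    prob: 0.036
    disutility: 0.07
    cost: 140.55
  - name: neutropenia
    prob: 0.052
    disutility: 0.09
    cost: 116.51
  ngc:
  - name: decreased_platelet_count
    prob: 0.076
    disutility: 0.05
    cost: 1525.5
  - name: neutropenia
    prob: 0.188
    disutility: 0.09
    cost: 116.51
  - name: decreased_neutrophil_count
    prob: 0.145
    disutility: 0.2
    cost: 116.51
  - name: anemia
    prob: 0.22
    disutility: 0.07
    cost: 140.55
  - name: decreased_white_cell_count
    prob: 0.099
    disutility: 0.2
    cost: 114.81
options:
  second_line_cycles: 6.0
  vial_sharing: no
ranges:
  discount_annual:
  - 0.0
  - 0.08
  rel: 0.2
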