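country: us
wtp: 150000.0
settings:
  cycle_days: 21.0
  horizon_years: 50.0
  discount_annual: 0.03
  half_cycle: yes
population:
  weight_kg: 70.0
  bsa_m2: 1.86
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
  ev_20mg: 2751.73
  pembro_100mg: 5884.02
  nivo_40mg: 1301.04
  gem_1000mg: 20.93
  cis_50mg: 10.55
costs:
  second_line_cycle: 1358.58
  bsc_cycle: 1374.0
  imaging_cycle: 942.0
  administration: 894.0
  labs_radiology: 2458.04
  hospitalization: 1522.56
  followup: 318.16
  terminal: 6246.0
ae:
  evp:
  - name: peripheral_sensory_neuropathy
    prob: 0.041
    disutility: 0.33
    cost: 24918.400000000001
  - name: maculopapular_rash
    prob: 0.077
    disutility: 0.032
    cost: 16337.360000000001
  - name: diarrhea
    prob: 0.039
    disutility: 0.05
    cost: 7968.48
  - name: anemia
    prob: 0.036
    disutility: 0.07
    cost: 4823.52
  - name: neutropenia
    prob: 0.052
    disutility: 0.09
    cost: 17868.240000000002
  ngc:
  - name: decreased_platelet_count
    prob: 0.076
    disutility: 0.05
    cost: 8608.129999999999
  - name: neutropenia
    prob: 0.188
    disutility: 0.09
    cost: 17868.240000000002
  - name: decreased_neutrophil_count
    prob: 0.145
    disutility: 0.2
    cost: 37550.239999999998
  - name: anemia
    prob: 0.22
    disutility: 0.07
    cost: 4823.52
  - name: decreased_white_cell_count
    prob: 0.099
    disutility: 0.2
    cost: 13506.01
options:
  second_line_cycles: 6.0
  vial_sharing: no
ranges:
  discount_annual:
  - 0.0
  - 0.05
  rel: 0.2
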