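schema_version: 1
currency: 2016 USD
horizon_cycles: 260
days_per_cycle: 21.0
days_per_year: 365.0
wtp: 26598.0
bsa: 1.72
arms:
- X
- XELOX
survival:
  X:
    pfs:
      theta: -3.0531
      kappa: 2.1872
    os:
      theta: -3.2726
      kappa: 1.4703
  XELOX:
    pfs:
      theta: -3.9836
      kappa: 1.6494
    os:
      theta: -4.5714
      kappa: 1.496
dosing:
  capecitabine_mg_m2: 1000.0
  capecitabine_admin_per_day: 2.0
  capecitabine_days: 14.0
  capecitabine_pack_mg: 500.0
  oxaliplatin_mg_m2: 110.0
  oxaliplatin_vial_mg: 50.0
  oxaliplatin_arms: XELOX
conventions:
  trace_method: markov
  accrual_timing: start
  capecitabine_rounding: per_cycle
  capecitabine_dose_reading: full
  admin_cost_in_x: yes
  second_line_application: exclusive
  followup_every_cycles: 3
psa:
  n_iter: 1000
  seed: 20180628
parameters:
  id:
  - cost_capecitabine
  - cost_oxaliplatin
  - cost_laboratory
  - cost_administration
  - cost_supportive_care
  - cost_second_line
  - cost_abdominal_ct
  - cost_abdominal_mri
  - cost_chest_xray
  - cost_ae_diarrhea
  - cost_ae_anemia
  - cost_ae_fatigue
  - cost_ae_anorexia
  - cost_ae_thrombocytopenia
  - risk_ae_diarrhea_x
  - risk_ae_anemia_x
  - risk_ae_fatigue_x
  - risk_ae_anorexia_x
  - risk_ae_thrombocytopenia_x
  - risk_ae_diarrhea_xelox
  - risk_ae_anemia_xelox
  - risk_ae_fatigue_xelox
  - risk_ae_anorexia_xelox
  - risk_ae_thrombocytopenia_xelox
  - risk_second_line_x
  - risk_second_line_xelox
  - utility_pfs
  - utility_pd
  - discount_rate
  value:
  - 4.8
  - 371.9
  - 129.5
  - 18.5
  - 1415.4
  - 5300.4
  - 60.2
  - 123.3
  - 6.0
  - 44.3
  - 531.7
  - 115.4
  - 115.4
  - 3551.7
  - 0.08
  - 0.15
  - 0.08
  - 0.08
  - 0.04
  - 0.04
  - 0.08
  - 0.13
  - 0.13
  - 0.04
  - 0.38
  - 0.58
  - 0.797
  - 0.577
  - 0.03
  low:
  - 3.8
  - 297.5
  - 103.6
  - 16.6
  - 1022.8
  - 4240.3
  - 30.1
  - 61.7
  - 3.0
  - 39.9
  - 478.5
  - 103.8
  - 103.8
  - 3196.5
  - 0.064
  - 0.12
  - 0.064
  - 0.064
  - 0.032
  - 0.032
  - 0.064
  - 0.104
  - 0.104
  - 0.032
  - 0.304
  - 0.464
  - 0.638
  - 0.462
  - 0.0
  high:
  - 5.8
  - 446.3
  - 155.4
  - 20.3
  - 2021.5
  - 6360.5
  - 90.3
  - 185.0
  - 9.0
  - 48.7
  - 584.9
  - 126.9
  - 126.9
  - 3906.9
  - 0.096
  - 0.18
  - 0.096
  - 0.096
  - 0.048
  - 0.048
  - 0.096
  - 0.156
  - 0.156
  - 0.048
  - 0.456
  - 0.696
  - 0.956
  - 0.692
  - 0.05
  family:
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - gamma
  - gamma
  - gamma
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - fixed
  psa:
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - no
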