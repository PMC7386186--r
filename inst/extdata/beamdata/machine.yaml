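version: fixture-s2019-e3
checksum: ae38003bf0c77cefe7977c8e3396027f950c86bfa8a59354750a9ad82e317176
geometry:
  treatment_ssd: 500.0
  cal_distance: 100.0
  cal_field: 10.0
  treatment_field: 40.0
  water_to_muscle: 0.99
dose_rates:
- 100.0
- 200.0
- 300.0
- 400.0
- 500.0
- 600.0
energy_selection:
- sep_min: 0.0
  sep_max: 20.0
  energy: 6X
- sep_min: 20.0
  sep_max: 40.0
  energy: 10X
- sep_min: 40.0
  sep_max: 60.0
  energy: 15X
tables:
- energy: 6X
  kind: TMR
  file: 6X_TMR.csv
- energy: 6X
  kind: Sc
  file: 6X_Sc.csv
- energy: 6X
  kind: Sp
  file: 6X_Sp.csv
- energy: 6X
  kind: spoiler
  file: 6X_spoiler.csv
- energy: 10X
  kind: TMR
  file: 10X_TMR.csv
- energy: 10X
  kind: Sc
  file: 10X_Sc.csv
- energy: 10X
  kind: Sp
  file: 10X_Sp.csv
- energy: 10X
  kind: spoiler
  file: 10X_spoiler.csv
- energy: 15X
  kind: TMR
  file: 15X_TMR.csv
- energy: 15X
  kind: Sc
  file: 15X_Sc.csv
- energy: 15X
  kind: Sp
  file: 15X_Sp.csv
- energy: 15X
  kind: spoiler
  file: 15X_spoiler.csv
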