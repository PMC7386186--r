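protocol: standard_adult
dose_per_field: 75.0
num_fractions: 8.0
separation: 36.0
max_dose_rate: 10.0
arrangement: AP/PA
patient_id: MRN0001
patient_name: DEMO^PATIENT
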