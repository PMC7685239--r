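# Single-dose rich-sampling OAB design: one dose at 3x the weight-adjusted
# PED (approximating steady-state accumulation), dense time grid.
name: giraffe
population: OAB
strata:
  - label: child
    age_min: 5
    age_max: 12
    n_subjects: 30
    weight_mean: 29.32
    weight_sd: 8.65
  - label: adolescent
    age_min: 12
    age_max: 18
    n_subjects: 12
    weight_mean: 55.70
    weight_sd: 14.42
agp:
  meanlog: 4.2047   # log(67)
  sdlog: 0.25
pk_weeks: [0]
duration_weeks: 0
windows: []
single_dose: true
dose_multiple: 3
rich_grid: [0.5, 1, 2, 3, 4, 6, 8, 12, 24, 48, 72]
lloq: 0.2
uloq: 200
formulation: B
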