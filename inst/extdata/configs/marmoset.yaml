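# 52-week open-label NDO dose-titration design in infants/young children
# (6 months to <5 years; weight from a piecewise-linear age curve with
# log-normal scatter; starting dose PED2.5 under 2 years).
# Stratum size is a synthetic default (not a published value).
name: marmoset
population: NDO
strata:
  - label: young
    age_min: 0.5
    age_max: 5
    n_subjects: 36
    weight_by_age: true
    weight_cv: 0.12
agp:
  meanlog: 4.2485   # log(70)
  sdlog: 0.25
titration_weeks: [3, 6, 9, 12]
max_titration_week: 12
pk_weeks: [12, 24, 36]
duration_weeks: 52
windows:
  - {label: predose, lo: -3, hi: 0}
  - {label: early, lo: 1, hi: 3}
  - {label: mid, lo: 4, hi: 5}
  - {label: late, lo: 7, hi: 10}
lloq: 0.2
uloq: 200
formulation: A
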