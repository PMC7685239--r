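# 12-week placebo-controlled OAB dose-titration design (sparse sampling,
# week-12 PK visit with a 2-3 day washout sample)
name: lion
population: OAB
strata:
  - label: child
    age_min: 5
    age_max: 12
    n_subjects: 73
    weight_mean: 29.32
    weight_sd: 8.65
  - label: adolescent
    age_min: 12
    age_max: 18
    n_subjects: 22
    weight_mean: 55.70
    weight_sd: 14.42
agp:
  meanlog: 4.2047   # log(67)
  sdlog: 0.25
titration_weeks: [3, 6, 9]
max_titration_week: 9
pk_weeks: [12]
duration_weeks: 12
windows:
  - {label: predose, lo: -3, hi: 0}
  - {label: early, lo: 1, hi: 3}
  - {label: mid, lo: 4, hi: 5}
  - {label: late, lo: 7, hi: 10}
  - {label: washout, lo: 48, hi: 72, final_only: true}
lloq: 0.2
uloq: 200
formulation: A
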