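# 52-week open-label NDO dose-titration design in children/adolescents
# (four sparse samples at one visit among weeks 12/24/36).
# Stratum sizes and weights are synthetic defaults (not published values).
name: monkey
population: NDO
strata:
  - label: child
    age_min: 5
    age_max: 12
    n_subjects: 48
    weight_mean: 27.5
    weight_sd: 8.0
  - label: adolescent
    age_min: 12
    age_max: 18
    n_subjects: 15
    weight_mean: 52.0
    weight_sd: 14.0
agp:
  meanlog: 4.2767   # log(72)
  sdlog: 0.25
titration_weeks: [3, 6, 9, 12]
max_titration_week: 12
pk_weeks: [12, 24, 36]
duration_weeks: 52
windows:
  - {label: predose, lo: -3, hi: 0}
  - {label: early, lo: 1, hi: 3}
  - {label: mid, lo: 4, hi: 6}
  - {label: late, lo: 7, hi: 10}
lloq: 0.2
uloq: 200
formulation: A
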