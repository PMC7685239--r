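# Final two-compartment population model for the school-age OAB population:
# typical values for a subject with FFM 24 kg and AGP 67, FFM allometry on
# CL/V2/V3, AGP power terms on CL/V2, formulation-B relative bioavailability.
# Omega/sigma blocks are simulation defaults (not published estimates).
structural: 2cpt
theta:
  cl_f: 8.81
  v2_f: 162
  q_f: 98.1
  v3_f: 174
  ka: 0.742
  alag: 0.834
  f1: 1.12
covariates:
  ffm_exp: {cl_f: 0.652, v2_f: 1.18, v3_f: 1.07}
  agp_exp: {cl_f: -0.649, v2_f: -1.06}
  ffm_ref: 24
  agp_ref: 67
ontogeny:
  enabled: false
  tm50: 0.3
  hill: 2
  cyp3a4_fraction: 0.8
omega: {cl_f: 0.35, v2_f: 0.45, ka: 0.5}
sigma:
  - {study: lion, prop: 0.2, add: 0.05}
  - {study: giraffe, prop: 0.15, add: 0.05}
  - {study: monkey, prop: 0.2, add: 0.05}
  - {study: marmoset, prop: 0.2, add: 0.0}
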