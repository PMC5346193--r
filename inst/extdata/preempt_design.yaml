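# Reference four-arm flexible-entry design: two long-acting reversible
# contraceptive arms versus pill or no treatment, minimised on disease
# stage, excision extent, age group and recruiting centre.
classes:
  LARC:
    LNG-IUS: levonorgestrel intrauterine system
    DMPA: depot medroxyprogesterone acetate
  non-LARC:
    COCP: combined oral contraceptive pill
    NONE: no treatment
factors:
  stage: [I, II, III, IV]
  excision: [complete, incomplete]
  age_group: ["<35", ">=35"]
  centre: [C1, C2, C3, C4, C5, C6]
feasibility:
  threshold: 0.10
  metric: compatible_uptake
samplesize:
  delta: 10        # EHP-30 pain points
  sd: 25
  alpha: 0.05      # family-wise, Bonferroni over n_comparisons
  power: 0.80
  n_comparisons: 6
  attrition: 0.20
  round_to: 50
  n_groups: 4
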