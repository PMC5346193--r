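# flexrand

Design toolkit for **flexible-entry multi-arm randomised trials**: trials
in which each participant chooses which admissible subset of arms (a
*randomisation scheme*) they accept randomisation among, an internal pilot
observes which schemes are actually chosen, and a prespecified feasibility
rule fixes the substantive trial design.

The package is aimed at trial statisticians designing multi-arm studies in
populations with strong treatment preferences. It provides:

* **Scheme algebra** — arms partitioned into treatment classes, with the
  "at least one arm per class" admissibility rule. For classes of sizes
  `a₁ … aₖ` there are `∏ᵢ (2^aᵢ − 1)` admissible schemes (nine for the
  shipped 2 × 2 reference design).
* **Minimisation** — Pocock–Simon covariate-adaptive allocation in the
  marginal-totals form, one independent algorithm and state per scheme.
  Candidate arm *t* scores `sₜ = Σ_f w_f · c_{f,ℓ_f,t}` (its running count
  at the participant's level of each factor); the minimal-score arm is
  allocated with probability *p* (default 0.8), ties uniform, one RNG draw
  per allocation so sequences replay bit-exactly from an audit log.
* **Accrual simulation** — a screening funnel (eligibility outcomes),
  preference-driven scheme choice (per-scheme distribution or per-arm
  acceptance probabilities conditioned on the class constraint), and
  covariate generation; plus a deterministic 77-participant **pilot
  fixture** reproducing every published marginal of the reference trial's
  internal pilot.
* **Feasibility rule and adaptation** — the "any group attracting < 10% of
  randomisations" decision rule in both its readings (compatible uptake
  and per-arm allocation share), a full candidate-design sweep, and the
  class-versus-comparator adapted design with prerandomisation strata and
  optional sub-randomisation.
* **Sample size and power** — two-sided two-sample mean comparisons by the
  noncentral-*t* method (power at `2n − 2` df and noncentrality
  `(δ/σ)√(n/2)`), Bonferroni alpha adjustment with half-up rounding,
  attrition inflation, standardised effect sizes, stratified power, and a
  Monte-Carlo power validator.

The reference configuration (`preempt_design()`) is a four-arm trial of
post-surgical hormonal treatment for endometriosis: two long-acting
reversible contraceptives (LNG-IUS, DMPA) versus pill (COCP) or no
treatment, minimised on disease stage, excision extent, age group and
centre, with the EHP-30 pain domain (0–100) as primary outcome.

## Worked example

Reconstruct the internal pilot cohort, summarise the randomisation options
chosen, test the four-way design against the 10% rule, and adapt:

```r
library(flexrand)

fx <- pilot_fixture(seed = 1)
summarise_uptake(fx$participants)
#> Uptake summary (n = 77 randomised)
#>   all arms accepted: 5 (6%)
#>   single-LARC preference: 63 (82%)
#>   single-non-LARC preference: 55 (71%)
#>   two-way selections: 46 (60%)
#>   per scheme:
#>     COCP+DMPA+NONE                17 (22%)
#>     COCP+DMPA                     14 (18%)
#>     COCP+LNG-IUS                  14 (18%)
#>     LNG-IUS+NONE                  13 (17%)
#>     DMPA+LNG-IUS+NONE              9 (12%)
#>     COCP+DMPA+LNG-IUS+NONE         5 (6%)
#>     DMPA+NONE                      5 (6%)
```

Only 5 of 77 participants (6%) accepted randomisation among all four arms,
so a four-way design fails the prespecified 10% feasibility threshold:

```r
evaluate_candidate(c("LNG-IUS", "DMPA", "COCP", "NONE"), fx$participants)
#> Candidate COCP+DMPA+LNG-IUS+NONE: compatible uptake 6.5%, exact selection
#> 6.5%, min allocation share 23.4% -> infeasible (compatible_uptake 6.5% < 10%)

adapt_design(rank_candidates(fx$participants), comparator = "COCP")
#> Adapted design: LARC (as a class) vs COCP
#>   prerandomisation strata: LNG-IUS, DMPA, no-preference
#>   sub-randomisation in 'no-preference': LNG-IUS vs DMPA
#>   sample size: 160 per group, 320 total, recruit 400
```

The adapted two-arm comparison needs 160 per group (8-point difference,
SD 22, 90% power, α = 0.05), 320 in total, inflated to 400 for 20%
attrition; the original four-arm design needed 148 per group at the
Bonferroni-adjusted α = 0.01 (592 total, 750 recruited). Either block is
available directly:

```r
samplesize_block(samplesize_spec(8, 22, 0.05, 0.90, attrition = 0.20))[1:4]
#> $alpha_adjusted      0.05
#> $n_per_group         160
#> $n_total             320
#> $recruitment_target  400
```

or from the shell:

```sh
flexrand samplesize --delta 8 --sd 22 --alpha 0.05 --power 0.9 --attrition 0.2
flexrand run --seed 1 --out-dir pilot_report/
```

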