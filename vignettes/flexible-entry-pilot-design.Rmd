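---
title: "Flexible-entry multi-arm pilot designs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible-entry multi-arm pilot designs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexrand)
```

## The problem

Multi-arm trials are efficient but fragile when patients hold strong
treatment preferences: requiring consent to randomisation among all arms can
cripple recruitment. A *flexible-entry* design lets each participant choose
which admissible subset of arms — a *randomisation scheme* — they accept
randomisation among, subject to a scientific constraint that keeps every
scheme informative. An *internal pilot* then observes which schemes patients
actually choose and applies a prespecified decision rule to fix the
substantive trial design, retaining the pilot participants.

`flexrand` implements this machinery for the general case of arms
partitioned into treatment classes with an "at least one arm per class"
scheme constraint. The shipped reference configuration
(`preempt_design()`) is a four-arm trial of post-surgical hormonal
treatment for endometriosis: a class of two long-acting reversible
contraceptives (LNG-IUS, DMPA) against a class of two comparators (COCP,
no treatment), with the primary outcome the EHP-30 pain domain (0–100,
higher is worse).

## Scheme algebra

For classes of sizes $a_1, \dots, a_k$ the admissible schemes are the
arm subsets containing at least one member of every class, so their number
is $\prod_i (2^{a_i} - 1)$ — nine for the reference $2 \times 2$ design.
Scheme identity is canonical: the lexicographically sorted arm ids joined
by `+`. The ordering is our choice (nothing external imposes one); it
makes scheme ids stable dictionary keys for per-scheme randomiser state
and reproducible report output.

```{r}
names(enumerate_schemes(preempt_design()))
```

## Minimisation

Each scheme runs its own covariate-adaptive randomiser: participants
choosing different schemes never share balancing state, because their arm
sets differ and pooling would bias the marginal counts. We implement
Pocock–Simon minimisation in its marginal-totals form, the variant most UK
trials units deploy: candidate arm $t$ receives the score

$$ s_t = \sum_{f} w_f \, c_{f,\ell_f,t}, $$

the weighted sum over factors $f$ of the arm's current count at the new
participant's level $\ell_f$, and the minimal-score arm is allocated with
probability $p$ (the remaining arms share $1-p$ uniformly; exact ties among
minimal arms are split uniformly). Defaults: equal weights $w_f = 1$ and
$p = 0.8$, a common compromise between balance and unpredictability; the
production system behind the reference trial does not publish its settings,
so these are declared package defaults, not inferences. $p = 1$ gives
deterministic minimisation, under which a single-factor two-arm scheme can
never drift more than one allocation out of balance at any factor level.

Each allocation consumes exactly one uniform draw — the unit interval is
partitioned among the minimal and non-minimal arms — so an audit log
holding the seed and draw index replays any allocation sequence
bit-exactly. With an empty state all scores tie and the first allocation
is uniform; no separate first-allocation rule is needed.

## The accrual simulator and what it emulates

`simulate_accrual()` models the recruitment funnel as independent
categorical draws per screened individual (randomised, planning to
conceive, contraindication, no disease found, declined with a treatment
preference, other exclusion), with default probabilities set to the pilot's
observed counts out of 504 screened. Scheme choice is drawn either from a
categorical distribution over schemes (default: the pilot's empirical
frequencies) or from independent per-arm acceptance probabilities
conditioned on the class constraint by rejection. Covariates are drawn
from the pilot's reported marginals: age $\mathcal{N}(31, 7.5^2)$
truncated to $[16, 45]$, stage probabilities $(0.47, 0.26, 0.14, 0.13)$,
complete excision 0.92, pain $\mathcal{N}(58, 18.5^2)$ truncated to
$[0, 100]$, smoking 0.48, BMI $\mathcal{N}(27, 5.7^2)$ with
missing-completely-at-random probability $17/77$. Truncated normals are
sampled by rejection (the bounds are wide, so acceptance is high).

What the simulator does *not* model: time-to-event accrual dynamics,
centre-level staggered starts (centre is only a label), correlation
between covariates and preference, and informative missingness. Passing
tests therefore demonstrate parameter recovery and flow conservation under
the stated generative model, not fidelity to any real cohort beyond the
printed marginals.

## The pilot reconstruction fixture

`pilot_fixture()` rebuilds a 77-participant cohort reproducing every
printed marginal of the pilot: 5 accepting all four arms; 63 with a
single-LARC preference split 27/36 (the only integer pair consistent with
the printed 43%/57% of 63); 55 with a single-comparator preference split
28/27 (ditto for 51%/49%); 46 two-way selections including 14 choosing
DMPA-versus-COCP; and the covariate counts of the pilot table (stage
36/20/11/10, complete excision 71, age under 35 53, ever-smoked 34 with 6
missing, BMI missing 17, pain score missing 2).

These marginals under-determine the interior of the $3 \times 3$ grid of
LARC acceptance pattern (LNG-IUS only / DMPA only / both) against
comparator pattern (COCP only / none only / both). Any consistent interior
preserves every printed number; for stable tests we fix it
deterministically: `fill_grid()` walks the free cells in row-major order
and assigns each the **largest value that still leaves the remaining grid
completable**, where completability is checked with the Gale–Hoffman
condition for transportation problems (every subset of rows must be able
to ship its remaining supply into the columns it reaches). The
completability check matters: the naive greedy that takes
`min(row remainder, column remainder)` dead-ends on this grid. The
resulting interior is

```{r}
flexrand:::pilot_grid()
```

whose two-way total re-derives the printed 46. Continuous covariates are
drawn from the reported distributions conditioned on the exact counts, and
all columns are shuffled independently of scheme, so the fixture carries
no artefactual covariate–preference association. For a fixed seed the
fixture is bit-identical across runs.

The screening-funnel percentages printed alongside the pilot's counts
round to the stated values only with the non-randomised screenees (427) as
denominator; the simulator nevertheless needs per-screenee probabilities,
so the eligibility model divides the absolute counts by 504. Both readings
preserve the counts themselves.

## Feasibility rule and adaptation

The prespecified rule — "any one group attracting less than 10% of the
randomisations" — admits two readings, and the text does not resolve which
was intended. We implement both and always report both:

* `compatible_uptake` (default): the fraction of participants whose
  accepted-arm set contains *every* arm of the candidate design. This is
  the reading under which the pilot's decisions reproduce: the four-way
  design scores $5/77 = 6.5\% < 10\%$ and is ruled out.
* `allocation_share`: the smallest per-arm share of actual allocations
  among the candidate's arms — the literal per-treatment-group reading.

`evaluate_candidate()` additionally reports the exact-selection share
(participants whose accepted set is exactly the candidate), the framing
under which a sole DMPA-versus-COCP trial "attracted" $14/77 = 18\%$.
`rank_candidates()` sweeps every admissible arm subset — not only the
patient-facing schemes — so dropped-arm designs are scored uniformly.
Raising the threshold can only shrink the feasible set, and adding arms to
a candidate can only lower its compatible uptake; both monotonicities are
property-tested.

`adapt_design()` applies the decision process: a feasible full design is
retained unchanged; otherwise the design collapses to
class-versus-comparator, with the preferred class member chosen by the
participant *before* randomisation (strata: one per class member plus
no-preference, the latter offered sub-randomisation between the members).
Prerandomisation choice is what keeps the stratified subgroup comparisons
unbiased: only participants preselecting a member enter that member's
versus-comparator analysis. The comparator is an explicit input — in the
reference trial it was chosen on external evidence, which is outside this
package's computational scope — so an infeasible pilot with no designated
comparator raises a "pilot inconclusive" error rather than guessing.

## Sample size and power

All calculations are two-sided two-sample comparisons of means. Power uses
the noncentral-*t* formulation: with $n$ per group, degrees of freedom
$2n-2$ and noncentrality $(\delta/\sigma)\sqrt{n/2}$, power is the
probability mass beyond the two-sided critical value. `n_per_group()`
iterates from the normal-approximation start
$n_0 = 2\,((z_{1-\alpha/2}+z_{\text{power}})\,\sigma/\delta)^2$ to the
smallest $n$ meeting the target. The source trial does not state its
formula; we adopt the noncentral-*t* method because it reproduces both
printed totals — $148 \times 4 = 592$ and $160$ per group — where the
plain normal approximation gives $146 \times 4 = 584$ and $159$. The
normal approximation remains available via `method = "normal"`.

Supporting arithmetic follows the published conventions: Bonferroni
division of the family alpha with *half-up* rounding to two decimals
($0.05/6 = 0.008\overline{3} \to 0.01$; base `round()` is banker's
rounding, so a dedicated helper is used), attrition inflation
$\lceil n/(1-a) \rceil$ rounded up to a configurable multiple (the
four-arm design's 750 implies rounding 740 up to a multiple of 50; whether
that multiple was policy or an ad-hoc round figure is unknowable, so it is
a parameter, default 1), and stratified power evaluated at
$\lfloor n \cdot \text{split} / 2 \rfloor$ per arm, reported `NA` for
strata too small to analyse. `simulate_power_check()` validates the
analytic power by direct simulation of normal outcomes with the
equal-variance *t*-test (vectorised; no baseline adjustment, matching the
published calculation).

```{r}
samplesize_block(preempt_design()$samplesize)
unlist(samplesize_block(samplesize_spec(8, 22, 0.05, 0.90,
                                        attrition = 0.20))[1:4])
stratified_power(320, c(0.5, 0.5), delta = 10, sd = 22, alpha = 0.05)
```

## Numerical and testing choices

Problem sizes used by the test suite are chosen to make Monte-Carlo
checks decisive at three standard errors while keeping the default run
desk-scale: $10^4$ draws for the uniform-first-allocation check, 2,000 to
4,000 replicates per Monte-Carlo power point, 5,000 randomised
participants for parameter-recovery checks, and a 200-replicate paired
simulation of 500-participant accruals for the balance comparison against
simple randomisation. All randomness flows through R's global generator
under explicit seeds; identical seeds give bit-identical output, including
the JSON serialisation of the full workflow bundle.

## Known limitations

* The feasibility rule's two readings can disagree on cohorts unlike the
  pilot's; the package reports both but the verdict follows the configured
  metric.
* The minimisation variant, weights and assignment probability of the
  production randomisation system are unpublished; defaults here are
  declared choices.
* The accrual simulator draws covariates independently of preference and
  centre, which real cohorts need not obey.
* Per-arm allocation counts of the pilot are not printed, so the fixture's
  `allocated_arm` column is generated by the package's own minimisation
  algorithm rather than reconstructed.
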