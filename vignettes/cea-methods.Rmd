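---
title: "Methods: a trial-based decision model for antibiotic-prescribing strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a trial-based decision model for antibiotic-prescribing strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxcea)
```

## The decision problem

Children aged 2–14 presenting in primary care with an uncomplicated
respiratory tract infection — and a paediatrician in genuine doubt about
whether an antibiotic is needed — can be managed three ways: immediate
antibiotic prescription (IAP), a delayed prescription to be used only if
symptoms persist or worsen (DAP), or no prescription with safety-netting
advice (NAP). `abxcea` models the 30-day consequences of that choice as a
decision tree: every arm starts with the baseline visit V0 (with the arm's
initial treatment, and for DAP/NAP an extra minute of doctor time to explain
the strategy; none for IAP, the usual option), after which the observed
terminal pathways — resolution, taking the delayed antibiotic, additional
visits V1–V3 with or without antibiotic treatment, or special care — occur
with the frequencies observed in a three-arm randomized trial of 422
children (143 IAP / 140 DAP / 139 NAP).

The model is a single-period tree over a fixed 30-day horizon; there is no
discounting and no Markov structure. Strategies are mutually exclusive.

## Effectiveness: quality-adjusted life days

With a 30-day horizon, effectiveness is measured in quality-adjusted life
days rather than QALYs. For each arm,

$$E = u_{zero} d_{zero} + u_{severe} d_{severe} + u_{moderate} d_{moderate}
      - \delta_{AE}\, d_{AE},$$

where the utilities are arm-mean parent-reported VAS scores (0–100) divided
by 100, collected on the days chosen to represent each symptom state, and
the days are arm means. A child in perfect health accrues exactly 30 QALDs.
Adverse effects of antibiotics (typically gastro-intestinal) carry a
disutility of 0.12 over an expected
$d_{AE} = \Pr(\text{exposed}) \times 0.10 \times 2$ days: a 10% rate of a
2-day adverse effect among antibiotic-exposed children. The packaged
scenario stores the published per-arm $d_{AE}$ values directly (0.05 / 0.20
/ 0.02), keeping the input table authoritative even where re-derivation from
exposure differs in the last printed digit (the NAP exposure of ~6.5%
implies 0.013 rather than the printed 0.02).

## Societal costing

Costs are accrued bottom-up along each pathway in 2022 euros, in four
categories:

* **healthcare direct** — primary-care visits (50 €), emergency-department
  contacts (minor emergency 215 €, non-urgent 130 €), antibiotic (5.20 €)
  and non-antibiotic (2.50 €) courses, and doctor time (5 €/min, charged to
  DAP and NAP only);
* **non-healthcare direct** — a per-contact out-of-pocket expenditure of
  16.50 €, composed as 10.50 € of travel/visit time + 0.20 €/km over an
  assumed 5 km + 5 € parking (5 km is the distance that closes the printed
  sum; the true distance is not stated);
* **indirect** — parental work time lost, valued at the 15.85 €/h wage
  (human-capital approach), accrued per in-person contact;
* **AMR** — 0.20 € per antibiotic prescription, a 30-day monetary proxy for
  the antimicrobial-resistance externality, taken as a parameter.

Adverse effects always add one primary-care visit (with its expenditure and
lost work time) and add a non-antibiotic course with probability 0.5 — the
source data say "sometimes" without a rate, so the 0.5 default is an
explicit, configurable assumption.

### Resource bundles and the per-arm time calibration

The trial publishes pathway *frequencies* and *unit costs* but not the
resource vector of each branch. The packaged scenario therefore derives each
branch's bundle from its label (an "Additional visit (V1) / Antibiotic
treatment" branch carries one extra visit and one antibiotic course, and so
on), with three label-ambiguous choices resolved against the published
aggregates:

* the delayed arm's antibiotic uptake is 0.25 (the take-the-prescription
  subtree), which reproduces both the arm's published adverse-effect days
  (2 × 0.10 × 0.25 = 0.05) and its observed 35 courses / 140 children;
* the single DAP hospitalization (dehydration) is costed as a minor
  emergency, the source's explicit outlier rule;
* the five emergency contacts (three non-urgent, two minor) are assigned one
  minor to DAP, one non-urgent + one minor to IAP's special-care branches,
  and one non-urgent to NAP, keeping all bundle counts integer.

One quantity remains genuinely unpublished: parental work hours lost. It was
collected per patient in the trial and clearly differs by arm (the source
notes that lost work time weighs more on DAP than NAP). The scenario
therefore carries a per-arm mean of hours lost per in-person contact,
calibrated so that each arm's expected total cost equals its published value
(97.48 / 100.90 / 109.68 €); the calibrated values (0.78 / 0.92 / 0.57 h per
contact for DAP / IAP / NAP) are frozen in the YAML file and are of a
plausible magnitude for a visit of 40 minutes plus surrounding disruption.
All other unit values are used exactly as printed. A single shared
hours-per-contact value cannot reproduce all three published totals, which
is itself evidence that the underlying arm means differed.

## Incremental analysis

`rank_strategies()` sorts strategies by ascending cost and classifies
dominance exactly as defined in the health-economics literature: a strategy
is *strictly dominated* if some alternative costs no more and yields no
fewer QALDs (with one inequality strict), and *extendedly dominated* if its
ICER exceeds that of the next more effective alternative — removed
iteratively until the frontier ICERs strictly increase. ICERs and NMB are
computed on full-precision values; tables round only for display (euros and
QALDs to 2 decimals, probabilities to 4). Equal-cost ties keep the more
effective strategy; exact cost-and-effect ties are kept and flagged
equivalent. Dominated rows still report a sign-carrying ICER versus the
previous row in cost order, mirroring the usual "all strategies"
presentation.

A note on precision: the published table's ICER of 28.84 €/QALD between DAP
and NAP is recoverable from its NMB and cost columns
($E = (NMB + C)/82.2$, giving $\Delta E = 0.1186$), while the published
utility/day inputs give $\Delta E = 0.1083$ and hence an ICER near 31.6.
The two disagree at the second decimal of $\Delta E$; the packaged scenario
keeps the published *inputs* authoritative, and the package's own frontier
ICER is therefore ~31.6. Both derivations are exercised in the test suite.

## One-way (tornado) sensitivity analysis

`run_tornado()` perturbs each unit cost to its low and high bound (by
default the stored ±15% band, at cent precision) with everything else at
base, re-evaluates the tree and recomputes the frontier ICER. Effectiveness
does not depend on prices, so the incremental effect is constant and each
ICER response is exactly linear; a parameter with identical exposure in both
frontier arms (doctor time, charged once to each of DAP and NAP) leaves the
ICER bit-identical. Direction is classified by the sign of the ICER response:
lost-work time loads more heavily on DAP (positive direction), visit costs
more heavily on NAP (negative). The `cum_impact_share` column is the
cumulative normalised share of summed impact widths — an interpretation
offered for convenience, as that summary has no standard definition.

## Probabilistic sensitivity analysis

All parameters are varied jointly per Monte Carlo iteration
(`draw_psa_sample()`), with the distribution families conventional for each
parameter type:

* **unit costs and per-arm hours**: gamma, matched to the base mean with
  CV = 0.15/1.96 ≈ 0.077 — the ±15% sensitivity band read as a central 95%
  interval;
* **pathway probability vectors**: Dirichlet with concentration equal to
  the arm size (~140), so each branch's marginal SD equals its binomial
  standard error; structural zeros stay zero;
* **state utilities**: beta matched by moments to the base utility with
  SE = 5/(100·√n) — i.e. state-specific VAS ratings assumed to have a
  ~5-point patient-level SD. This is the one genuinely free dispersion
  choice in the model: the source publishes no parameter uncertainties, and
  within-state ratings plausibly vary far less than ratings across states.
  It is set once here and is configurable (`psa_vas_sd_points`);
* **adverse-effect rate**: beta at an effective n of 140.

State days are held fixed (no distribution is conventionally assigned to
them in this design, and day and utility uncertainty are confounded in a
mean product). An infeasible beta moment match (variance beyond the
mean-variance bound) is an error naming the parameter, never a silent
truncation. One seeded generator drives everything in a fixed documented
order, so `run_psa(params, iterations, seed)` is exactly reproducible, and
zero dispersion (`psa_cost_cv = 0`, `psa_vas_sd_points = 0`,
`psa_ae_n = Inf`, `psa_dirichlet_n = Inf`) reproduces the deterministic
analysis bit-for-bit — an oracle equivalence the tests assert.

`ce_plane_summary()` tallies the incremental cloud by quadrant (I more
effective/more costly … IV more effective/less costly). Boundary
convention, deterministic though measure-zero: ΔE = 0 counts as "not more
effective", ΔC = 0 as "more costly". `ceac()` computes, per
willingness-to-pay value, the fraction of iterations in which each strategy
attains the highest NMB, ties split equally; probabilities sum to 1 at every
grid point by construction. Because the published analysis does not state
its distribution dispersions, its printed PSA percentages are not exactly
reproducible; under the defaults above the qualitative findings hold (the
DAP-vs-NAP cloud falls predominantly in quadrant I and DAP is the most
likely cost-effective strategy at 82.2 €/QALD), and the test suite asserts
exactly those properties rather than any percentage.

## The synthetic trial generator

`generate_trial()` produces individual-patient data emulating the trial's
marginal structure: arm sizes 143/140/139 (overridable), multinomial pathway
assignment, truncated-normal symptom-state durations on [0, 30] — the
location is moment-matched by root-finding so the *realised* post-truncation
mean equals the published arm mean (with SDs 2–3× the means, a naive
location at the published mean would roughly double the realised mean) —
beta-distributed VAS scores with state means 100 × utility and a 5-point SD,
resource counts implied by the assigned pathway, Bernoulli(0.10)
adverse-effect indicators among antibiotic-exposed children only, and
gamma-distributed lost work hours per contact. `estimate_inputs()` inverts
the generator: branch frequencies, mean VAS/100, mean days, observed
exposure and mean hours-per-contact become a new parameter set, with prices
and tree structure carried from a template.

What the generator does *not* emulate: within-patient correlation between
severity, duration and resource use; day-resolution symptom trajectories;
clinical efficacy differences beyond the published summary structure; and
non-normal duration shapes (real symptom-day distributions are zero-inflated
and right-skewed — the truncated normal matches mean and scale, not shape).
Passing parameter-recovery tests therefore show the pipeline is
self-consistent and unbiased at the level of the published marginals, not
that the model captures individual-level dependence in real data.

## Numerical choices

* Pathway probability vectors may be entered as percentages; sums within
  0.0005 of 1 (printed tables sum to 99.99–100.01%) are renormalised to
  exactly 1, anything further off is a validation error.
* Money is kept at full double precision internally; printing and range
  construction round half-up (`round_money()`), matching how the published
  ranges were rounded (e.g. 2.50 × 0.85 = 2.125 → 2.13).
* The generator's truncated-normal location solver brackets the root by
  outward expansion and treats underflown tail mass as collapse onto the
  nearer bound.
* Test problem sizes: the parameter-recovery suite uses 20 000
  patients/arm routinely and 100 000/arm for the tight (±0.005) recovery
  check; the PSA property checks run 10 000 iterations once and small runs
  elsewhere. The oracle-equivalence sweep checks 100 random decision trees
  against full terminal-branch enumeration.

## Known limitations

* The per-arm work-hours calibration reproduces published cost *totals*; the
  split across categories (indirect vs healthcare) inherits any error in the
  label-derived bundles. Published tornado *bounds* depend on that same
  unpublished decomposition, so only directions and orderings are claimed.
* AMR cost is a 30-day per-prescription proxy; long-run resistance dynamics
  are out of scope.
* Utilities come from parent VAS ratings, not choice-based elicitation;
  their PSA dispersion is an assumption, as documented above.
* The three-arm scenario is the only shipped fixture; the YAML schema,
  however, accepts any number of strategies and pathways, and all dominance
  logic handles the general case.
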