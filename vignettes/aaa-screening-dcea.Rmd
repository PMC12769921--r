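---
title: "Methods: a distributional cost-effectiveness analysis of AAA screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a distributional cost-effectiveness analysis of AAA screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question

The English NHS offers every man a one-off abdominal ultrasound scan the
year he turns 65, looking for an abdominal aortic aneurysm (AAA): a
permanent dilatation of the abdominal aorta that is usually asymptomatic
until it ruptures, at which point most men die. Screening finds aneurysms
early, places small ones (3.0–5.4 cm) under surveillance, and refers large
ones (≥ 5.5 cm) for elective repair, trading a certain, modest cost against
a small probability of averting a catastrophic death.

A conventional cost-effectiveness analysis asks whether the programme buys
QALYs cheaply enough on average. A *distributional* cost-effectiveness
analysis (DCEA) additionally asks **who** gets those QALYs and who bears the
opportunity cost. Deprivation cuts both ways here: men in the most deprived
fifth of England (IMD Q1) have roughly twice the AAA prevalence of the least
deprived fifth (Q5) — higher *need* — but attend screening less, drop out of
surveillance more, and wait longer for consultation and surgery — worse
*uptake and delivery*. Meanwhile the health displaced elsewhere in the NHS
by the programme's cost falls disproportionately on deprived groups, who are
the marginal beneficiaries of NHS spending.

This package implements the full chain: an individual-level discrete event
simulation (DES) of AAA natural history and the screening pathway by
deprivation quintile, a cause-deleted life table for non-AAA mortality, and
the DCEA layer (health opportunity cost, per-quintile net health benefit,
counterfactual quality-adjusted life expectancy, Atkinson
equally-distributed-equivalent health, threshold inequality aversion, and
scenario analyses).

## The simulation model

### Paired counterfactuals

Each simulated man is a bundle of natural-history draws — baseline aortic
diameter at 65, an individual annual growth rate, a unit-exponential
rupture draw, and a non-AAA death time — plus one named uniform per pathway
decision (attendance, reinvitation, non-visualisation, each surveillance
dropout, turn-down, reaching hospital after rupture, repair choice,
operative death, reintervention). The *same* bundle drives an invited and
an uninvited lifetime, so the incremental cost and QALYs of invitation are
computed within pairs and the Monte-Carlo noise of the natural history
cancels exactly. A consequence the tests verify: the uninvited arm's event
log is bit-identical under any change to the screening parameters.

To keep that invariance exact, the pathway that follows *incidental*
detection (the only route into care for the uninvited arm, and for invited
men who never attended or dropped out of surveillance) uses fixed
configuration constants — `incidental_wait_consult`,
`incidental_wait_surgery`, `incidental_dropout` (default 0) — rather than
the per-quintile programme parameters. The pathway structure (surveillance,
referral, consultation, turn-down, repair) is identical; only the
programme-specific frictions differ. The clinical logistic models for
repair type and 30-day operative mortality apply in both arms.

### Natural history

* **Baseline diameter**: two-component mixture per quintile — a lognormal
  "body" of non-aneurysmal aortas (median 2.0 cm, sdlog 0.10) truncated
  below 3.0 cm, plus a shifted-lognormal aneurysm tail above 3.0 cm. The
  tail weight is the quintile's AAA prevalence; the default Q5 prevalence
  is 1.1% with a Q1:Q5 ratio of 2.0 (AAA is about twice as common at the
  deprived extreme), interpolated log-linearly across quintiles because
  only the extreme-group contrast is published.
* **Growth**: exponential, `d(t) = d0 · exp(g·t)`, with `g` normal across
  individuals (default mean 0.010/yr, SD 0.008/yr). A single
  population-wide growth distribution must trade off AAA-tail realism
  (registry aneurysms grow faster, ~2 mm/yr at 4.5 cm) against implausible
  late-life incidence generated by the non-aneurysmal body crossing
  3.0 cm; the default deliberately sits on the conservative side of that
  trade-off and is flagged as uncalibrated.
* **Rupture**: inhomogeneous hazard `λ(t) = exp(α + β·d(t))`, default
  `α = −17`, `β = 2.5` per cm: negligible below 3 cm, ≈ 4%/yr at 5.5 cm,
  steeply rising beyond. Rupture times invert the cumulative hazard at a
  unit-exponential draw; for exponential growth the cumulative hazard has a
  closed form in the exponential integral Ei, and the inversion brackets
  and root-finds on `[0, t_max]`. Repair removes rupture risk.
* **Non-AAA death**: inverse-CDF draw from the cause-deleted life table
  (below), uniform within the year of death, certain death at age 110.

### The screening pathway

Invited arm at `t = 0`: invitation letter (£2.13), reinvitation where
drawn, attendance with the quintile's probability, one repeat scan if
non-visualised. A measured diameter < 3.0 cm discharges the man (he remains
incidentally detectable, identical to his uninvited copy); 3.0–5.4 cm
enters surveillance — scans every 12 months below 4.5 cm, every 3 months at
4.5–5.4 cm, with an independent per-scan dropout draw; ≥ 5.5 cm triggers
referral: consultation after the quintile's wait, then turn-down (default
10%, annual surveillance thereafter) or elective repair after the surgical
wait. Rupture at any time sends the man to the emergency pathway: with
default probability 0.35 he reaches surgery (open vs EVAR by the published
emergency logit, 30-day death by the published mortality logits), otherwise
he dies immediately. Thirty-day operative deaths are AAA deaths. Survivors
face a one-off reintervention risk (default 8% uniformly over 5 years) and
post-repair surveillance costs (annual after EVAR, a single 1-year visit
after open repair). Ties at identical times resolve death > rupture >
scheduled scan > administrative events.

Aorta size enters the published logistic models in **millimetres**; the
printed coefficients (±0.01–0.03 per unit) would be negligible against the
intercepts on a centimetre scale. The printed emergency 30-day mortality
logits imply low absolute mortality at typical ages (≈ 1.6% for emergency
EVAR at 75); they are implemented exactly as printed, so case-fatality of
rupture in the model is carried almost entirely by the
`p_emergency_operated` gate rather than by operative mortality.

### Accounting

Costs attach to events at their event time; QALYs accrue continuously as
`utility(age, quintile) × discount factor`, utility piecewise constant over
single years of age. Both use continuous discounting at 3.5%/yr,
`(1.035)^{−t}` with `t` in years since 65 — the natural convention for an
event-driven model given that only the annual rate is specified. One
undiseased life-year at utility 1 is therefore worth
`(1 − 1.035^{−1})/ln 1.035 ≈ 0.983` discounted QALYs, an identity the
acceptance tests check to `1e-6`.

## The cause-deleted life table

National statistics supply AAA deaths (ICD-10 I71) and all-cause deaths by
age and sex, and populations by age, sex and IMD quintile. Both death
counts are apportioned to quintiles by population share (real-valued, so
they reconstruct the national counts to machine precision), AAA deaths are
subtracted, and the central rate `m` converts to a within-year death
probability by the uniform-deaths formula `q = m/(1 + 0.5m)`, capped at 1
(the map only stays below 1 for `m ≤ 2`). Because share-based apportionment
of national-only death counts necessarily yields quintile-uniform rates,
the small helper `apply_rate_gradient()` lets the simulator carry a
deprivation mortality gradient (default multipliers 1.30, 1.15, 1.00,
0.88, 0.78 for Q1..Q5); this is the package's own device, documented here
because the IMD-specific national death tables are not redistributable.

## The DCEA layer

With per-quintile total incremental costs `ΔC_i` and QALYs `ΔQ_i` (from the
simulator or a hand-entered table):

* **Health opportunity cost**: `HOC = Σ_i ΔC_i / k`, with `k = £13,000`
  per QALY — each £13,000 of programme cost displaces one QALY elsewhere in
  the NHS. The total is distributed by the opportunity-cost shares
  `ρ(k)_i` (default 26.4% … 14.0%, the allocation implied by the published
  per-quintile column renormalised), or an explicit per-quintile allocation
  can be supplied. The total net population health is always the identity
  `ΣΔQ_i − HOC`; when a supplied allocation carries independent rounding,
  the quintile nets honour it at face value.
* **Net health benefit**: `nhb_i = (ΔQ_i − HOC_i)/n_i` per person, with
  `n_i` the quintile's whole population (N/5 of 56.5 million by default) —
  per-person and population units are easy to mix here, which is why the
  package keeps totals internally and divides once.
* **Counterfactual QALE**: `h_i|t=0 = h_i|t=1 − nhb_i`, applied to QALE at
  birth. Only the Q1 anchor (63 years) is published; the default Q2–Q5
  values (65.5, 68, 70.5, 73) are a synthetic linear gradient consistent
  with the ~10-year longevity gap between the extremes, and are exposed as
  inputs precisely because they are not published.
* **Atkinson EDE**: per person,
  `EDE = [(1/N) Σ n_i h_i^{1−ε}]^{1/(1−ε)}` (geometric mean at `ε = 1`,
  population mean at `ε = 0`), computed on a mean-relative scale for
  stability at large `ε`; `H_EDE = N·EDE`; Atkinson index
  `1 − EDE/mean`. The social value of the programme is
  `ΔEDE = H_EDE|t=1 − H_EDE|t=0`; subtracting total net health isolates
  the inequality value, and `(inequality value, net health)` is the
  equity-efficiency plane point.
* **Threshold aversion**: the root of `ΔEDE(ε) = 0` on `[0, 20]`, located
  by sign-change bracketing on a 0.1 grid followed by bisection to `1e-4`;
  multiple roots report the smallest, with all brackets returned.

### Scenarios

`equal_hoc` reallocates the opportunity cost one-fifth to each quintile and
recomputes everything without resimulating (the total is unchanged by
construction). `leveling_up` copies each best-case-flagged access, uptake
and delivery parameter to every quintile — attendance 0.8342,
non-visualisation 0.0090, dropout 0.0381, consultation wait 0.0413 y,
surgical wait 0.2847 y, and the two flagged repair-choice logits — and
reruns the simulation; eligibility and costs are untouched. The
reinvitation row carries no best-case flag in the source table and is left
quintile-specific.

## What the synthetic generators do and do not show

The registry baseline-diameter distributions, the calibrated growth and
rupture parameters of the source DES, the IMD-specific HRQoL surface, and
the IMD-specific mortality tables are all unavailable, so this package
generates documented synthetic stand-ins. Consequences to be explicit
about:

* The published headline per-person effects (≈ £59–65 incremental cost,
  0.0052–0.0064 incremental QALYs per man) are **not reproducible** from
  the synthetic inputs, and the package does not try: the simulator is
  validated by properties instead — pairing invariance, the
  zero-prevalence closed form (letters `£2.13·(1+p_reinvite)` plus
  attended scans `p_attend·£40.43·(1+p_nonvisualised)`, and exactly zero
  incremental QALYs), the one-year discounting identity, and agreement of
  cohort QALYs with the life-table expectation when AAA is disabled.
* The published threshold `ε = 10` depends on the unpublished Q2–Q5 QALE
  baselines; under the package's synthetic QALE gradient and the published
  net-impact column the threshold computes to ≈ 13. The *sign structure* —
  positive social value at `ε = 3.5`, a sign change within `[0, 20]` when
  losses concentrate on Q1 — is the reproducible content.
* Passing tests therefore demonstrate correctness of the mechanics and the
  distributional arithmetic, not calibration to English registry outcomes.

## Problem sizes and numerical choices

The default desk-scale cohort is 50,000 men per quintile (the package's
chosen working scale; the published analysis used 1 million per quintile),
which resolves the per-quintile mean incremental cost to a Monte-Carlo
standard error of roughly £1. Pairs whose natural history can never
involve an AAA — diameter never reaches 3.0 cm before death and the
cumulative rupture hazard never reaches the exponential draw — are resolved
in closed form; the event walk runs only for the rest (about 10–15% at
default settings). A cheap upper bound on the cumulative hazard
(`λ(t_end)·t_end`, valid because the hazard is nondecreasing) avoids the
exponential-integral evaluation for the overwhelming majority.

Degenerate inputs are handled explicitly: zero growth uses the
constant-hazard closed form; `−∞` logit intercepts give probability-0/1
choices; zero incidental hazard disables detection; a zero discount rate
makes the discount integral the interval length; share vectors are
validated to sum to 1 within 0.02 and then normalised.

## Reproducibility

Every stochastic quantity descends from one integer seed through fixed
child-seed derivations (a Lehmer-style multiplier mod 2^31−1), with one
named stream per decision per individual, so reruns are bit-identical,
arms share natural histories, and scenarios share cohorts.
`run_full_analysis()` writes a manifest (seed, resolved configuration and
its MD5, parameter file provenance) sufficient to re-derive every output.

```{r example}
library(aaadcea)
ref <- load_quintile_aggregates()
inputs <- dcea_inputs(population_profile(),
                      total_cost = ref$total_cost,
                      total_qaly = ref$total_qalys,
                      hoc_i = ref$hoc)
dcea(inputs)
run_scenario(inputs, "equal_hoc")
```

## Known limitations

Beyond the synthetic-input caveats above: women are not modelled (the
programme screens men); deprivation is quintile-level only; no
probabilistic sensitivity analysis is offered (point values throughout);
mortality is not projected forward; surgery has no HRQoL decrement (the
invitation itself is assumed utility-neutral, as in the source model); and
the emergency mortality logits are implemented as printed despite their
implausibly low implied case fatality.
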