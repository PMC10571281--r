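---
title: "Methods: the RRMS Markov cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the RRMS Markov cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmscea)
```

## Scope and design

`rrmscea` evaluates rituximab and a rituximab biosimilar against best
supportive care (BSC) for newly diagnosed relapsing-remitting multiple
sclerosis in Thailand: a cost-utility analysis from the societal
perspective, probabilistic and one-way sensitivity analyses, and a
five-year budget-impact projection from the government perspective. The
model is a first-order Markov cohort over seven states — four living EDSS
severity bands (0.0–2.5, 3.0–5.5, 6.0–7.5, 8.0–9.5), relapse states
attached to the two mildest bands, and death — with a one-month cycle.

Structural assumptions:

* Disability is irreversible: no transition lowers the EDSS band.
* The same relapse probability applies in both of the mildest bands;
  relapse is treated as extinguished from EDSS 6.0 upward.
* Treatment stops on reaching EDSS 6.0–7.5 (Thai practice); from there the
  cohort follows BSC transitions and costs regardless of strategy.
* Originator and biosimilar have identical efficacy and differ only in
  monthly drug cost.
* No secondary-progressive conversion point, treatment switching, or
  patient-level heterogeneity; no background (age-specific) all-cause
  mortality beyond the MS-specific death probabilities, since the inputs
  provide none.

## Inputs

All inputs live in one `rrms_parameters()` object (also shipped as the YAML
fixture in `inst/extdata/`). Each uncertain input is a (family, mean, SD)
triple — Beta for probabilities and utilities, Gamma for costs — fitted by
the method of moments:

* Beta: `alpha = m*k`, `beta = (1-m)*k` with `k = m(1-m)/s^2 - 1`,
* Gamma: `shape = (m/s)^2`, `scale = s^2/m`.

The published table reports only family, mean and SD, so the
method-of-moments fit is the only parameterisation consistent with it;
`beta_moments()` / `gamma_moments()` reproduce the input moments to
machine precision, and sampling round-trips are tested at n = 100,000
draws. Several SDs equal their means (e.g. relapse 0.0755 ± 0.0755);
implausibly wide, but reproduced as printed. Because such inputs put a
normal approximation far outside the support, 95% intervals for the
one-way analysis default to fitted-distribution quantiles
(`param_ci(..., method = "quantile")`), with truncated normal intervals
available as a flag.

Adverse-event probabilities are per year on treatment and enter accrual as
expected monthly costs (annual probability × unit cost / 12); no
adverse-event disutility is modelled because none is published.

## Structural conventions and their calibration

Four aspects of the model are not pinned down by the published inputs. We
fixed each by calibrating the deterministic base case against the published
totals (costs, life-years, QALYs, incrementals, ICER) — the published table
is the calibration anchor — and each has a configuration switch so the
alternatives remain available:

* **Horizon** (`horizon_cycles`, default 720). The published discounted
  life-years (20.33 untreated, 20.67 treated) exceed the theoretical
  maximum of a 360-cycle model (a fully surviving cohort accrues only
  ~19.9 discounted LYs in 30 years), so the published totals must come
  from a genuinely lifetime accrual. 720 cycles (60 years, i.e. to
  roughly age 80+ for an adult cohort) reproduces the totals; beyond that
  the discounted sums change little.
* **Death from EDSS 6.0–7.5** (`p_death_edss6`, default 0.0013/month).
  The state diagram names this probability but the input table omits it.
  Zero is qualitatively wrong: it makes the severe states a mortality
  refuge, so treatment — which delays reaching them — *loses* life-years,
  inverting the published +0.34 LY gain. The calibrated 0.0013 sits
  between the EDSS 3.0–5.5 death probability (0.0011) and the
  EDSS 8.0–9.5 exit probability (0.0017), preserving a monotone
  severity–mortality gradient.
* **Relapse-cycle progression** (`relapse_progression`, default `TRUE`).
  Whether a patient can progress EDSS bands during a relapse month is
  ambiguous. Allowing it (at the band's progression probability) keeps
  the effective progression hazard equal across relapse and non-relapse
  months; forbidding it makes relapse months protective, which slows the
  untreated arm artificially.
* **Relapse costs in severe states** (`late_relapse_costs`, default
  `TRUE`). The inputs price relapse in EDSS 6.0–7.5 and 8.0–9.5 even
  though those bands have no relapse *state*. Clinically relapses still
  occur there; we charge the expected monthly relapse management cost
  (relapse probability × relapse cost). Without this the biosimilar loses
  its published dominance.

With these defaults every published base-case quantity is reproduced
within 12.5% and the qualitative conclusions exactly (biosimilar dominant;
originator ICER ≈ 436,000 THB/QALY against the published ≈ 435,000, far
above the 160,000 threshold). With the literal alternatives
(`p_death_edss6 = 0`, no relapse-cycle progression, no late relapse costs,
360 cycles) the reproduction fails qualitatively, which is why they are
not the defaults.

Two further conventions were *not* calibrated because the evidence fixes
them: the treated relapse parameter 0.4220 is interpreted as a relative
risk multiplying the untreated relapse probability (its source trial
reports a relapse-rate ratio; 0.4220 as a monthly probability would make
the drug increase relapse sixfold), with the literal-probability reading
available via `relapse_effect = "probability"`; and a relapse lasts one
cycle (`relapse_return = "one_cycle"`), the standard convention in
monthly-cycle MS models, with the symmetric reading (return probability
equal to the relapse probability, implying ~13-month episodes) available
via `relapse_return = "symmetric"`.

## Accrual and discounting

Cycle contributions use start-of-cycle occupancy (rows 0..H−1 of the
trace) with discount factor `(1 + r)^(-t/12)`; cycle 0 is undiscounted. No
half-cycle correction is applied (none is described for the original
analysis); `half_cycle = TRUE` enables the trapezoid variant. Life-years
are discounted at the outcome rate (the published LYs are consistent only
with discounting); `discount_ly = FALSE` disables that. QALYs use annual
utilities divided by 12. ICERs are computed from unrounded intermediates,
which is why the package's ratio (like the published one) differs slightly
from the ratio of the published rounded incrementals.

## Sensitivity analyses

The tornado (`owsa()`) re-runs the full model twice per parameter at its
95% bounds, all else at base case; drug costs use ±20% of base, the range
conventionally examined for acquisition prices. Because the biosimilar
dominates BSC in the base case, its ICER is sign-unstable, so the tornado
outcome defaults to incremental net monetary benefit at the configured
threshold, with the ICER available where well defined.

The probabilistic analysis (`run_psa()`, default 1,000 draws) samples every
non-fixed parameter independently — no correlation structure is published —
and re-runs all strategies per draw. Acceptability curves (`ceac()`) use
the net-monetary-benefit argmax per draw; exact ties are split equally (a
measure-zero event under continuous sampling). The default export grid is
0–500,000 THB in 10,000 steps. Identical seeds give bit-identical draws
and curves. Note that with heavily skewed inputs the PSA *mean* differs
from the deterministic base case by a genuine convexity bias (the model is
nonlinear in its transition probabilities); the tests quantify this by
showing the bias vanishes when only the linearly entering costs and
utilities are sampled.

## Budget impact

The projection ages the prevalent pool (572 patients) and one incident
cohort per year (51 patients, stable incidence, entering each fiscal
year) along the treated and untreated traces; 90% of patients are covered
and the rest remain on BSC in both scenarios. Nothing is discounted.
Patients reaching EDSS 6.0 stop accruing drug cost but stay in the treated
scenario on BSC costs. The default prevalent-pool starting mix places all
patients in EDSS 0.0–2.5 (the newly diagnosed profile); any other mix can
be passed via `initial`.

Which cost components to net between the scenarios is the one place where
the published figures are internally inconsistent, and we document the
choice rather than hide it. Netting *all* direct medical costs (drug,
administration, adverse events, OPD, relapse care) caps the first-year
incremental at ~13.7M THB for every possible prevalent mix — half the
published ~26.4M — because treatment's relapse savings offset most of the
biosimilar's price; the published first-year figure instead equals, almost
exactly, the treated pool times the annual treatment-programme cost. The
default (`budget_components = "treatment_only"`) therefore counts the
drug, administration and adverse-event costs the reimbursement programme
itself pays, reproducing the published first-year figure within 9%. The
published projection *declines* across years, which no component subset
reproduces at the printed inputs while the pool grows with incidence; the
declining pattern does emerge under `"all_direct_medical"`, where care
savings deepen as counterfactual cohorts progress, and the tests assert it
there.

## Microsimulation oracle

`simulate_patients()` draws individual trajectories from the same
transition matrices, vectorised cycle-by-cycle from a single seeded
stream. It validates the cohort engine (maximum per-cell deviation at
n = 100,000 patients within the binomial bound `4*sqrt(p(1-p)/n)`, with a
small-count floor of `5/n` for near-empty cells), recovers every
transition probability by maximum likelihood within 3 standard errors
(`estimate_transitions()`), and reproduces undiscounted cohort accrual
from averaged patient-level costs and QALYs. The generator emulates
exactly what the cohort model assumes — homogeneous patients, first-order
dynamics, no secondary progression — so agreement validates the engine's
arithmetic, not the model's clinical realism.

## Problem sizes

The test suite runs the deterministic model at the full 720-cycle horizon;
microsimulation checks use 20,000–100,000 patients over 60–120 cycles;
distribution round-trips use 100,000 draws; probabilistic checks use
100–1,000 draws (the full 1,000-draw analysis matches the published
acceptability analysis). The whole suite completes in well under a minute.

## Limitations

* The four calibrated conventions are identifiable only jointly; other
  combinations could fit the published totals similarly well.
* Independent sampling overstates joint parameter uncertainty if the
  underlying estimates are correlated.
* No age structure: mortality never rises with age, which flatters the
  long horizon for both arms; with MS-specific death probabilities this
  low, the discounted totals are nevertheless dominated by the first
  decades.
* The budget module inherits the published analysis's ambiguity about
  offsets; both conventions are first-class and the choice is explicit in
  every output.
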