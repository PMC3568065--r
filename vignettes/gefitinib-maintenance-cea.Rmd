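---
title: "Methods: a semi-Markov cost-effectiveness model of gene-guided gefitinib maintenance in advanced NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a semi-Markov cost-effectiveness model of gene-guided gefitinib maintenance in advanced NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Patients with advanced non-small cell lung cancer (NSCLC) who remain
progression free after four cycles of first-line platinum-based doublet
chemotherapy can either be observed with routine follow-up or, if their
tumor carries an activating EGFR mutation, receive switch-maintenance
gefitinib (250 mg/day) until progression. Maintenance gefitinib greatly
lengthens progression-free survival (PFS) in the mutation-positive
subgroup (hazard ratio 0.17, 95% CI 0.07–0.42) but is expensive, so the
policy question from the Chinese health-care payer perspective is whether
*genotype first, treat the mutation-positive* is cost-effective against
routine follow-up for everyone, and how much the manufacturer's patient
assistance program (GPAP — patients pay for six months of gefitinib and
then receive it free) changes the answer.

`gefcea` implements the full decision model: a four-state semi-Markov
cohort simulation with Weibull-extrapolated survival, discounted cost and
QALY accrual, incremental cost-effectiveness ratios (ICERs) and net
monetary health benefit (NMHB), and one-way, two-way and probabilistic
sensitivity analyses. Every input is a published summary figure; the
package carries them as its default parameter registry
(`default_params()`), each with a base value, a plausible range and a
distribution family for probabilistic analysis.

## Model structure

Four health states: progression-free survival (**PFS**), progressed
disease on 2nd-line chemotherapy (**PD_2L**), progressed disease on
supportive care (**PD_SC**) and **DEATH** (absorbing). The cycle length is
3 weeks (one gefitinib dispensing cycle); the base-case horizon is 10
years with 1-, 2- and 5-year scenario truncations. A horizon of $h$ years
is covered by $N = \lceil 365.25\,h / 21 \rceil$ whole cycles (174 for 10
years, 18 for 1 year); taking the ceiling rather than the nearest integer
is the package's convention so that the horizon year is fully contained in
the simulated period.

The whole cohort starts progression free. At cycle $t$ the fraction

$$P_t \;=\; 1 - \frac{S(t)}{S(t-1)} \;=\; 1 - \exp\!\big(\lambda (t-1)^{\gamma}
- \lambda t^{\gamma}\big), \qquad S(t) = \exp(-\lambda t^{\gamma}),$$

of current PFS occupants progresses, where $(\lambda, \gamma)$ are the
Weibull scale and shape of the PFS curve — the control-arm curve, or the
same curve with $\lambda$ multiplied by the hazard ratio for the
mutation-positive gefitinib stratum (the Weibull family is closed under
proportional hazards via scale multiplication, so $S_{hr} = S^{hr}$).
Progressors split 56.6% : 43.4% between PD_2L and PD_SC.

Post-progression survival is **semi-Markov**: the overall-survival (OS)
Weibulls for the two progressed states are measured from second-line
initiation, not from model start, so each progressed subcohort carries its
own clock that resets at progression entry. The engine stratifies
progressed occupancy by entry cycle (tunnel states) and applies $P_k$ of
the relevant OS curve at subcohort age $k$. There is no direct PFS→DEATH
channel — all PFS exits are progressions — and no return from progression
to PFS. Two consequences follow: state occupancy sums to one at every
cycle by construction, and the PFS column of the trace equals the
closed-form survival curve exactly (both are enforced as exact tests, the
engine additionally being checked cell-by-cell against a brute-force
enumeration of every progression-cycle × pathway × death-cycle path at a
12-cycle horizon).

The **Gefitinib strategy** genotypes the whole cohort (one-time cost) and
mixes two arms: mutation-positive (weight = mutation frequency, 50%;
HR-adjusted PFS; drug cost and gefitinib-arm SAE rate) and
mutation-negative (weight 50%; control PFS; control SAE rate). The
mutation-negative stratum is modeled at hazard ratio 1.0 — it receives
routine follow-up only, and the trial found no significant PFS effect in
that subgroup (the reported point estimate 0.86 can be explored through
`settings$hr_egfr_neg`). The **Control strategy** is a single unweighted
arm.

## Survival inputs and the time-unit calibration

The three published Weibull fits are:

| curve | scale $\lambda$ | shape $\gamma$ | adj. $R^2$ |
|---|---|---|---|
| PFS, control strategy | 0.1559 | 1.045 | 0.976 |
| OS, supportive care | 0.04006 | 1.156 | 0.9898 |
| OS, 2nd-line chemotherapy | 0.03897 | 1.509 | 0.981 |

The unit of time these parameters are denominated in is not stated, and a
Weibull scale is meaningless without one. The package therefore fixes the
convention by calibration, once, as follows.

* **PFS on the cycle clock.** $(\ln 2 / 0.1559)^{1/1.045} = 4.17$ time
  units; read as 3-week cycles this is 2.88 months, matching the trial's
  quoted 2.8-month median control PFS. Read as months or weeks it matches
  nothing. `median_survival()` is the diagnostic helper for exactly this
  check, and `calibrate_scale_to_median()` rescales a curve to a target
  median if a user prefers to impose one.
* **Post-progression OS on a weekly clock.** The OS parameters are
  irreconcilable with the quoted source-trial medians (7.5 / 4.6 months)
  under *any* single unit: per month they give 6.7 / 11.8 months, per
  cycle 4.6 / 8.1 months. They are, however, consistent with the published
  model outputs: on a weekly clock the mean post-progression survival is
  0.214 years, which reproduces the published control-strategy life
  expectancy decomposition (overall minus progression-free life-years
  = 0.21 years at 10 years) and the 1-, 2- and 5-year scenario rows, while
  cycle and month clocks miss those outputs several-fold. The package
  default is therefore `time_unit = "week"` for the two OS curves, chosen
  to reproduce the published cohort results; the `time_unit` field on
  every curve (`cycle`, `week`, `month`) makes the convention explicit and
  user-overridable.

The Weibull fitting stage (`fit_weibull()`) is ordinary least squares on
the complementary log-log linearization $\ln(-\ln S) = \ln\lambda +
\gamma \ln t$, the method consistent with the published adjusted-$R^2$ and
correlation diagnostics. Points with $S \in \{0, 1\}$ are dropped (their
transform is undefined) and tied times keep the last survival value
(right-continuous step-curve convention). On noiseless Weibull input the
linearization is exact; on pseudo individual-patient data it tracks the
`survival::survreg` maximum-likelihood estimate, which the test suite uses
as an independent cross-check, never as the implementation.

## Economic accrual conventions

All costs are 2012 US dollars; costs and QALYs are discounted at 3% per
year via $(1.03)^{-t \cdot 21 / 365.25}$; life-years are reported
undiscounted (discounted variants are exposed alongside), which matches
the published incremental life expectancy (0.745 modeled vs 0.74 printed;
the discounted variant gives 0.716).

Membership during cycle $t$ is the state occupancy at the end of cycle
$t-1$ — the standard transitions-at-cycle-end Markov convention — and is
discounted at the end-of-cycle factor $d(t)$. No half-cycle correction is
applied by default (the publication mentions none); `settings$half_cycle
= TRUE` switches to mid-cycle (average of start and end) membership.

Cost components, each independently testable and additive:

* **Genotyping** 507.9 once at model start (undiscounted), Gefitinib
  strategy only.
* **Gefitinib** $21 \times 77.8$ per progression-free occupant-cycle in
  the mutation-positive stratum. Under the GPAP, the payer price applies
  only to the first $6 \times 30.4375 / 21 = 8.696$ cycles of maintenance,
  prorated within the fractional cycle, and is zero afterwards. (The
  published text quotes a first-cycle whole-cohort drug cost of \$1,663.10
  where $21 \times 77.8 = \$1{,}633.80$; the 1.8% gap is unexplained and
  the package uses the unit-price arithmetic.)
* **SAE management** per PFS occupant-cycle:
  `cost_sae_platinum_cycle × p_sae_arm / p_sae_platinum` (507.4 × 0.07/0.80
  = 44.40 for gefitinib, 19.03 for control), SAEs being assumed equally
  likely in every cycle.
* **Follow-up** amortized continuously: one 55.6 visit per 4 months of
  survivorship in years 0–2 and per 12 months thereafter, charged to all
  alive states by default (`settings$followup_scope = "pfs"` restricts it
  to PFS); amortization avoids an arbitrary alignment of discrete visits
  with the 3-week grid.
* **2nd-line chemotherapy** 2,352.7 per PD_2L occupant-cycle for the first
  4 cycles of that subcohort's clock ("four median cycles"), the
  supportive-care cost thereafter while the subcohort remains on its OS
  curve. The 2,352.7 is the published weighted mean of the
  docetaxel/gefitinib/erlotinib/pemetrexed mix (50/20/15/15), retained as
  `secondline_mix` in the registry for sensitivity use.
* **Supportive care** 337.5 per PD_SC occupant-cycle.
* **End of life** 3,664.3 once at each death transition, any pathway;
  patients alive at the horizon are censored and never charged it.

The factorization $d(\tau + k) = d(\tau)\,d(k)$ lets post-progression
costs be accrued exactly per entry cohort without materializing the full
tunnel ledger; the test suite verifies the factorized accrual against an
explicit ledger-matrix double loop.

**Known divergence.** With these components the model's *absolute*
control-strategy cost (~\$8.3k at 10 years) exceeds the published \$4,917;
the printed figure is only consistent with post-progression costs close to
the end-of-life component alone, and the publication does not itemize.
Because the same post-progression machinery applies to both strategies,
every *incremental* quantity — which is what all the headline results are
— is insensitive to this: the modeled incremental cost, QALYs, life-years
and the four ICERs land within 1–9% of the printed values. Absolute
per-strategy costs should be read with that caveat.

## Sensitivity analyses

`tornado()` re-runs the comparison with each of the 15 registry parameters
at its low and high value (the printed ranges; ICER per QALY recorded for
each), sorted by spread. The registry enumerates exactly the varied
parameters — there are no orphan inputs. At base settings the utility of
PFS and the PFS hazard ratio produce the two widest bars with and without
the GPAP, matching the published ranking, with the gefitinib unit price
third.

`two_way()` sweeps EGFR mutation frequency against genotyping cost; the
ICER surface is non-increasing in frequency (more beneficiaries dilute the
fixed genotyping overhead) and non-decreasing in genotyping cost, both
verified numerically across the grid.

`run_psa()` samples, per iteration: costs log-normal moment-matched to
mean = base and SD = 25% of the mean; utilities, probabilities and
proportions beta with the same moments (an infeasible beta moment match is
shrunk to the feasibility boundary with a message); the hazard ratio
log-normal with median 0.17 and 95% interval (0.07, 0.42), i.e.
$\sigma_{\log} = (\ln 0.42 - \ln 0.07)/(2 \times 1.96)$. Weibull scale and
shape are held fixed — the publication names distributions only for costs,
utilities and probabilities/proportions and tabulates no SEs for the
curves. Draws are independent across parameters (only marginal families
are specified). `sd_frac` scales every sampling SD, so the PSA collapses
continuously onto the deterministic base case as `sd_frac → 0` (a tested
property). 1000 iterations with a fixed seed reproduce bitwise.

With the GPAP, the modeled probability of cost-effectiveness at the
3×-GDP-of-China threshold (\$16,349.1/QALY) is ~0.48–0.50 across seeds,
against a published "nearly 51%". At the Shanghai threshold
(\$38,733.3/QALY) the model gives ~0.90 with GPAP and ~0.13 without,
against published "nearly 99%" and "nearly zero". The discrepancy at the
Shanghai threshold is systematic: sampling the administered gefitinib
price log-normally at 25% SD alone gives the no-GPAP NMHB a ~\$6.3k SD
against a ~–\$8.5k mean. The published qualifier that the 25% SD was
assumed "when reported data were not available" suggests the original
analysis held the drug price fixed; setting
`distribution: fixed` for `cost_gefitinib_250mg` in a config file
reproduces that behavior. The package keeps the all-costs-sampled default
as the more conservative characterization of uncertainty and documents the
difference rather than tuning toward the printed probabilities.

## Synthetic data

`simulate_cohort()` draws event times by inverse transform
$T = (-\ln U / \lambda)^{1/\gamma}$ with administrative censoring at a
fixed horizon — the mechanism by which trial duration truncates a
Kaplan-Meier curve — and `km_estimate()` turns a cohort into the
product-limit step curve that `fit_weibull()` reads. This emulates what
the fitting stage actually consumed (digitized KM survival fractions with
known Weibull structure) and supports parameter-recovery testing of the
whole simulate → KM → fit pipeline: recovery within 10% at n = 1,000 and
3% at n = 10,000, averaged over 20 seeds. It deliberately does *not*
emulate random (dropout) censoring, the source trials' at-risk tables, or
digitization error, so passing recovery tests demonstrates correctness of
the fitting pipeline, not robustness to real-curve artifacts.

## Numerical choices and problem sizes

Degenerate inputs are rejected with named errors (non-positive Weibull
parameters, utilities above 1, ranges not bracketing the base, fewer than
three usable fit points, all-equal survival values, a cohort with no
events). The transition probability is computed in exponent-difference
form, immune to survival underflow deep in the tail. The engine is exact
arithmetic on cohort fractions — no Monte-Carlo error outside the PSA.

Suite problem sizes, chosen to keep the full test run around a minute:
cohort horizons of 12 cycles for the brute-force oracle and 30–80 cycles
for property tests, full 174-cycle runs for the published-results checks;
10,000 draws for distribution moment checks; 1000-iteration PSAs for the
acceptance probabilities and 20–150 for reproducibility/shape properties;
synthetic cohorts up to n = 10,000 × 20 seeds for recovery.

## Limitations

Beyond the absolute-cost caveat and the PSA dispersion discussion above:
the comparator set is fixed (no erlotinib or pemetrexed maintenance arms,
which the source publication also excluded for lack of head-to-head
data); genotyping sensitivity/specificity is not modeled; indirect and
societal costs are excluded; post-progression survival borrows a
different trial's OS curves and is applied identically in both strategies;
and the 2012 USD cost base is carried without inflation adjustment.
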