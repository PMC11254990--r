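---
title: "Joint unbound/total docetaxel PK and the oral-dose feasibility framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint unbound/total docetaxel PK and the oral-dose feasibility framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odoxpk)
```

## The problem

Docetaxel is given intravenously because little of an oral dose survives
intestinal P-glycoprotein efflux and first-pass metabolism. Encequidar, an
intestine-restricted P-gp inhibitor, raises oral bioavailability to roughly
25% (versus about 8% without it), which makes an oral regimen worth
evaluating. Because the IV formulation contains polysorbate 80 — an
excipient that binds docetaxel — total plasma concentrations after the two
routes are not directly comparable; the pharmacologically active, unbound
concentration is the common currency. `odoxpk` implements the whole chain
needed to ask "does a feasible oral regimen exist?" before investing in
larger trials: a joint population model of total and unbound docetaxel for
both routes, a synthetic phase-I data generator, likelihood-based
estimation, and a virtual-patient simulation framework that ends in a
GO / CONDITIONAL GO / NO-GO recommendation.

## Structural and statistical model

Unbound docetaxel follows a three-compartment mammillary model with linear
elimination, parameterised on the unbound scale: clearance $CL_u$, central
volume $V_{1u}$, peripheral volumes $V_{2u}, V_{3u}$ and
inter-compartmental clearances $Q_{2u}, Q_{3u}$. IV doses are zero-order
infusions into the central compartment; an oral dose places $F \cdot D$ mg
into a depot at $t_{dose} + t_{lag}$, transferring first-order with rate
$k_a$. Concentrations obey $C_u\,[\mathrm{ng/mL}] = A_{central}\,[\mathrm{mg}]
\times 1000 / V_{1u}\,[\mathrm{L}]$. Binding is constant within a route, so
$C_{total} = C_u / f_u$ with route-specific fractions unbound ($f_{u,IV}$,
$f_{u,PO}$): richer binding mechanics (time-varying, Michaelis–Menten,
two-site) are deliberately not implemented, having not improved fit in the
source analysis, and a single shared three-compartment disposition is used
for both routes. Derived total-scale quantities follow the same constant:
$CL_{total} = CL_u \cdot f_u$ and $V_{ss,total} = (V_{1u}+V_{2u}+V_{3u})
\cdot f_u$.

The solver is exact: the rate matrix (depot plus up to three disposition
compartments; peripheral compartments with zero $Q$ are removed from the
state) is eigendecomposed once per individual and regimen, infusions use the
$\varphi_1(\lambda,\tau) = (e^{\lambda\tau}-1)/\lambda$ convolution kernel,
and superposition handles arbitrary event sequences. A dense
matrix-exponential propagation backs this up in the (numerically rare) case
of a near-defective eigenbasis. Output times are therefore only a reporting
grid; the 3-minute simulation step used by the feasibility framework has no
bearing on solution accuracy, only on the point-wise AUCOEC rule below.

Between-subject variability is exponential, $p_i = \theta_p e^{\eta_i}$,
$\eta \sim N(0, \omega_p^2)$, diagonal by default (no off-diagonal
$\omega$ terms are reported in the source analysis) with an optional
correlation matrix. Residuals are combined additive + proportional per
observable, and the two observations from one blood sample share a
standardized-residual correlation $\rho_{L2}$. Negative simulated
concentrations from the additive term are retained and resolved by BLQ
flagging, mirroring assay behaviour.

## BLQ handling (M6)

Observations strictly below the LLOQ (2 ng/mL total, 0.084 ng/mL unbound; a
value exactly at the LLOQ is quantifiable) are flagged, including negative
simulated values. The M6 rule is applied per subject × occasion ×
observable: in each maximal consecutive BLQ run the first observation is
imputed at LLOQ/2 and kept, and the rest of the run is discarded; leading
and trailing runs are treated alike. This is the canonical reading of the
M6 method; since variants exist, the preprocessing is a separate,
composable step (`censor_blq()` then `apply_m6()`) rather than being baked
into the likelihood, and `apply_m6()` is idempotent.

## Estimation

`population_ofv()` computes $-2\log$ marginal likelihood with the integral
over each subject's random effects approximated by the Laplace method at
the empirical-Bayes mode. The original analysis used NONMEM's FOCE-I;
that estimator is tool-specific, and the Laplace approximation is a
well-defined substitute whose adequacy is checked directly against
brute-force quadrature in the test suite (agreement within 0.1 OFV units on
a one-random-effect problem). With all $\omega = 0$ the marginal likelihood
is exact. The outer problem (`fit_population()`) optimizes free parameters
on unconstrained scales — log for positive parameters and
variability/error magnitudes, logit for fractions, atanh for
$\rho_{L2}$ — with `nlminb`; inner mode searches use a $10^{-8}$ relative
tolerance and are warm-started across outer iterations, the outer tolerance
is $10^{-6}$ on the OFV. Standard errors come from the inverse observed
information at the optimum with delta-method propagation to the natural
scale; a singular Hessian is reported (SEs set to `NA`) without failing the
fit. Nested models are compared with `lrt_improved()`: a drop of more than
$\chi^2_{0.95}(df)$ — 3.84 for one degree of freedom — is an improvement.

## Default parameter values

The main analysis text reports four anchors: $CL_u = 8570$ L/h, $F = 25\%$,
$f_{u,IV} = 0.67\%$, $f_{u,PO} = 1.02\%$, plus the derived total-scale
clearance (≈57.3 L/h) and steady-state volume (≈425 L). The remaining
defaults in `default_population_model()` are the package's own synthetic
choices, fixed once to be realistic for docetaxel rather than fitted
estimates:

* **Volumes** $V_{1u} = 1200$, $V_{2u} = 3700$, $V_{3u} = 58500$ L and
  **inter-compartmental clearances** $Q_{2u} = 1040$, $Q_{3u} = 1940$ L/h:
  chosen so the total-scale values ($\times f_{u,IV}$: $V_1 \approx 8$ L,
  $V_{ss} \approx 425$ L, $Q_2 \approx 7$, $Q_3 \approx 13$ L/h) sit in the
  range published three-compartment IV-docetaxel models occupy while
  reproducing the 425 L anchor.
* **Absorption** $k_a = 0.35$ h$^{-1}$, $t_{lag} = 0.5$ h: an oral
  absorption phase peaking a few hours post-dose with unbound
  concentrations near 1 ng/mL at the higher dose levels and largely
  undetectable by the next day, as described for this combination.
* **Variability**: $\omega$ of 0.25–0.45 (CV ≈ 25–45%) across structural
  parameters, 0.30 on $F$, 0.15 on the fractions unbound — moderate
  phase-I-like heterogeneity with clearance the dominant term.
* **Residual error**: proportional 20% (total) and 25% (unbound) with small
  additive floors (0.5 and 0.02 ng/mL) scaled to the two assays' LLOQs, and
  $\rho_{L2} = 0.5$ for within-sample correlation.

All of these can be replaced verbatim from a fitted parameter table through
the YAML/JSON configuration (`read_model_config()`), whose `theta` /
`omega` / `sigma` sections match the constructor arguments.

## The synthetic phase-I generator

`generate_trial_dataset()` emulates the source study's design exactly: nine
patients, two occasions per patient (130 mg IV infused over 1 h; a single
oral dose with levels cycling 75/150/300 mg/m² across patients at a default
BSA of 1.7 m²), the verbatim 24-point IV and 23-point oral sampling
schedules, and unbound assays on 7 (IV) + 8 (oral) samples per patient —
135 unbound and 423 total observations at n = 9. The per-patient dose
allocation and BSA values are not published, so cycling and a fixed BSA are
declared defaults. The unbound-assay subsets were chosen once to span
infusion/absorption, peak and elimination (IV: 0.33, 1, 1.5, 3, 7, 19, 49 h;
oral: 0.5, 1.5, 2.5, 3.5, 5, 8, 12, 24 h); the original optimal-design
selection is out of scope and the subsets are overridable. No
between-occasion variability, carryover, period or sequence effects are
simulated, matching the simulation assumptions of the framework.

What passing tests on these data do and do not show: the generator shares
the estimation model's structure, so parameter-recovery results demonstrate
internal consistency of solver + likelihood + optimizer, not robustness to
the model misspecification, assay artefacts or adaptive sampling a real
trial would bring.

## Exposure metric and the feasibility framework

`compute_aucoec()` implements the AUCOEC: data points below the effective
concentration EC are removed, EC is subtracted from the rest, and the
trapezoidal area is taken within each maximal retained run (the horizontal
re-anchoring to the first crossing time changes nothing about an area and
is not applied). This literal point-wise rule is the default
(`strict_points`) because it is what the framework's 3-minute grid
procedure describes; it is grid-dependent, so an `interpolated` mode that
inserts the exact EC crossings is provided, and the two agree within 1% on
the 3-minute grid in the test suite. Whether the original procedure
interpolated at crossings is not stated; both behaviours are exposed.

`run_pta_grid()` samples one cohort of 1000 virtual patients (common random
numbers across all cells), simulates each patient's IV reference (130 mg
over 1 h — fixed, with no BSA distribution) and each single oral dose
(400–600 mg by 50) over 24 h at 3-minute steps, and evaluates every
(dose, n-doses, EC) cell: multi-dose AUCOEC is the single-dose value times
the dose count (complete washout at the 24-h repeat interval), the target
is the same patient's IV AUCOEC minus the 20% bioequivalence margin, ties
count as successes, and PTA is the success percentage. The EC grid is
0.1–1.0 ng/mL in 0.1 steps — ten values including 0.5, which the 50-cell
single-dose panel confirms. A no-inhibitor comparator (600 mg at F = 8%,
overriding each patient's bioavailability while keeping their other
parameters) runs on the same cohort as a separate arm. Because a
single-dose profile is linear in $F \cdot D$, each patient's oral profiles
are exact scalar multiples of one unit profile; the implementation exploits
this, and the superposition property is itself under test.

`classify_decision()` applies the two-part framework with a strict 80%
threshold (a PTA of exactly 80.0 is not a pass): NO-GO when no cell
exceeds it, GO when some regimen exceeds it at every EC, otherwise a
conditional GO reporting each regimen's highest passing EC — the quantity
further pharmacological work would need to pin down. Under the synthetic
default parameters the 1000-patient grid classifies as GO (three 600 mg
doses pass at all ECs); with other variability assumptions the same code
path yields the conditional verdicts, as the classification tests exercise.

## Numerical choices and degenerate inputs

* Eigen-solver fallback triggers on near-repeated eigenvalues
  ($< 10^{-9}$ relative gap); $\varphi_1$ switches to its series below
  $|\lambda| < 10^{-12}$.
* Zero-amount dose events predict zero (the system is linear); empty
  regimens, unsorted time grids, non-finite parameters, correlations at or
  beyond $\pm 1$ and degenerate residual variances are rejected with
  specific errors.
* Sampling and simulation take explicit integer seeds and restore the
  session RNG state; identical seeds give identical artifacts end-to-end,
  including through the command-line driver.
* Pre-dose (time-zero) samples are simulated as zero plus residual noise
  and end up BLQ-flagged, mirroring a pre-dose draw.

## Problem sizes used by the checks

The test suite runs the full 9-subject design for counting and round-trip
checks, 100–150 virtual patients for PTA monotonicity, the complete
1000-patient grid only in the acceptance script, and a 50-subject
reduced-sampling design (10 + 10 times, 5 + 5 unbound pairs) for the
parameter-recovery fit with three free structural parameters — sizes chosen
to exercise every code path at interactive timescales.

## Known limitations

* The estimator is a Laplace approximation, not FOCE-I; OFV values are
  comparable within this package but not across tools.
* Multi-dose exposure uses the washout product rule rather than
  re-simulating accumulation; at the 24-h interval the approximation error
  is negligible for these parameters but it would not be for long
  half-life/low-clearance settings.
* No covariates, no between-occasion variability, no toxicity or
  tolerability layer: PTA speaks to exposure non-inferiority only.
* The default variability and absorption values are synthetic; conclusions
  about docetaxel itself require a fitted parameter table in the
  configuration.
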