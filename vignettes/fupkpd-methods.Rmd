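---
title: "Methods: a semi-physiological PKPD model of 5FU-induced myelosuppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a semi-physiological PKPD model of 5FU-induced myelosuppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling choices behind `fupkpd`: the
structural model and its assumptions, the population layer, the native
FOCE-I estimator, the synthetic study generator, and the numerical and
design decisions that a maintainer or reviewer would want stated
explicitly.

## Structural model

The parent drug (5FU, given as bolus and/or constant-rate intravenous
infusion) follows a two-compartment disposition model with linear
elimination from the central compartment. A fixed fraction $F_m = 0.85$ of
eliminated parent appears as the inactive catabolite 5FUH2, itself described
by one compartment. With amounts $A_c, A_p, A_m$ (mg) and
$C_p = A_c/V_c$ (mg/L):

$$
\begin{aligned}
\dot A_c &= R(t) - \frac{CL+Q}{V_c} A_c + \frac{Q}{V_p} A_p, &
\dot A_p &= \frac{Q}{V_c} A_c - \frac{Q}{V_p} A_p, &
\dot A_m &= F_m\, CL\, C_p - \frac{CL_m}{V_m} A_m .
\end{aligned}
$$

$F_m$ is not identifiable from plasma data alone (only $CL_m/F_m$ and
$V_m/F_m$ would be); fixing it to the literature value 0.85 resolves the
scaling, and the reported $CL_m$, $V_m$ must be read conditional on that
convention.

Myelosuppression uses the transit-compartment model that is the field's
standard semi-mechanistic description of chemotherapy-induced cytopenia: a
proliferating pool, $n = 3$ maturation transit compartments and a
circulating pool, all sharing one rate constant
$k_{tr} = (n+1)/\mathrm{MTT}$, with feedback $(Circ_0/Circ)^\gamma$ on
proliferation and a linear drug effect $E_{drug} = \text{slope}\cdot C_p$:

$$
\dot{Prol} = k_{tr} Prol \left[(1-E_{drug})\left(\frac{Circ_0}{Circ}\right)^{\gamma} - 1\right],
\quad
\dot T_i = k_{tr}(T_{i-1}-T_i),
\quad
\dot{Circ} = k_{tr}(T_n - Circ).
$$

All pharmacodynamic compartments start at $Circ_0$ (the chain's
drug-free steady state). $\gamma$ is fixed at 0.17: estimating it is
notoriously unstable in sparse designs (it was unstable here too), and the
value is the accepted literature magnitude for leukocyte feedback. An
$E_{max}$ drug-effect variant and a Michaelis–Menten elimination variant
are retained as structural options for model-comparison exercises; the
linear forms are the defaults and the shipped final model.

$E_{drug} > 1$ is deliberately *not* capped: under the linear effect model
it flips proliferation to net cell loss, which is the model's literal
statement at high exposure. The solver flags it (one warning per
trajectory; aggregated per dataset) so the user knows the linear regime has
been left.

## Parameters and units

Units are fixed package-wide: mg, L, h; concentrations mg/L (numerically
equal to µg/mL); leukocytes $10^9$/L; slope L/mg so that $E_{drug}$ is
dimensionless. The packaged final-model file
(`inst/extdata/final_model_parameters.yaml`) carries both reported estimate
columns — direct NONMEM estimates and bootstrap medians (e.g. total 5FU
clearance 256 vs 249 L/h); the bootstrap column is the default everywhere.
IIV magnitudes are stored as %CV and converted as
$\omega^2 = \log(1+(CV/100)^2)$.

## Population layer

Individual parameters arise as
$P_i = \theta_P \cdot \mathrm{cov}_i \cdot e^{\eta_P}$ with diagonal
log-normal IIV on $CL$, $V_c$, $CL_m$, $V_m$ and $Circ_0$ (the final
model's set; MTT and slope carry no IIV). The body-size model is a single
linear fractional change shared by both clearances,
$\mathrm{cov}_i = 1 + \theta_{BSA}(BSA_i - 1.95)$, with the reference at
the cohort median 1.95 m². A linear ("per m² difference") form is used
rather than a power model because that is what the estimated coefficient
means; the factor is validated to stay positive and the covariate effect is
applied *before* the random effect — the two orders are indistinguishable
for typical-value predictions, and this one keeps $\eta$ interpretable as
residual (body-size-corrected) variability. Cisplatin co-medication acts
only through the drug-effect slope (slope_comb vs slope_mono), not through
PK. Residual error is proportional per observation type
($y = f\,(1+\sqrt{\sigma^2}\varepsilon)$), with simulated observations
floored at zero.

## Solving the model

The PK subsystem is linear and time-invariant with piecewise-constant
input, so it is solved *exactly* per input segment via eigendecomposition
of the $3\times3$ system matrix (precomputed real-mode coefficients per
segment), with an augmented-matrix-exponential fallback for degenerate
cases (e.g. zero clearance in mass-balance checks, near-defective
matrices). The nonlinear PD chain is integrated with an adaptive embedded
Dormand–Prince RK45 (relative tolerance $10^{-8}$, absolute $10^{-10}$ by
default) driven by the analytic concentration, restarted at every dosing
discontinuity. The chain is not stiff at the estimated rate constants
($k_{tr}\approx 0.014\,h^{-1}$), but the integrator guards against
pathological parameter proposals during estimation: non-finite error norms
abort, states may be clipped only at machine scale, and larger negativity
is an integration failure. AUC accumulators for both analytes are carried
as extra states, mirroring the convention of adding an integral compartment.

The nadir search refines the trajectory-grid minimum by re-solving on
successively finer grids down to 0.01 h inside the bracket, with
earliest-time tie-breaks; a minimum on the right edge raises a "nadir not
bracketed" error rather than returning a boundary value.

## Estimation: native FOCE-I

The estimator is implemented natively because the estimation method is part
of the methodology being reproduced. For subject $i$ the conditional mode
$\hat\eta_i$ minimises
$\sum_j [(y_{ij}-f_{ij}(\eta))^2/v_{ij}(\eta) + \log v_{ij}(\eta)] +
\eta^\top\Omega^{-1}\eta$, located by a quasi-Newton (BFGS) search with
finite-difference gradients in compiled code, warm-started from the
previous outer iteration. The subject contribution then linearises $f$
about $\hat\eta_i$ with the residual variance held at the conditional
prediction (the "interaction"):

$$
\mathrm{OFV}_i = \log\det V_i + r_i^\top V_i^{-1} r_i + n_i\log 2\pi,
\quad V_i = F_i \Omega F_i^\top + \mathrm{diag}(v_i(\hat\eta_i)),
\quad r_i = y_i - f_i(\hat\eta_i) + F_i\hat\eta_i .
$$

The $n\log 2\pi$ constant is included, so absolute OFV values are
comparable only within this package; $\Delta$OFV between nested fits on the
same data is unaffected, and model decisions use the $\chi^2$ rule
($\Delta\mathrm{OFV}\ge 3.84$ per degree of freedom at $\alpha=0.05$). For
models linear in $\eta$ with additive error the expression equals the exact
Gaussian marginal $-2\log L$, which the test suite verifies against an
independent closed form; a one-subject nonlinear toy is checked against
adaptive quadrature of the exact marginal. The FOCE-I approximation error
on that toy scales as $O(\omega^2)$, so the sub-$10^{-3}$ agreement is
asserted at small IIV where the approximation is genuinely that accurate.

The outer problem maximises over $\log\theta$ (positivity), $\log\omega^2$
and $\log\sigma^2$, with $\theta_{BSA}$ untransformed (it may be negative).
$\gamma$ and $F_m$ live among the structural constants and are never
estimated. Gradients are explicit finite differences with step $10^{-3}$
on the unconstrained scale — deliberately large, because the inner
optimisation leaves residual noise of order $10^{-3}$ OFV units and
machine-step differencing would be dominated by it. The first optimisation
round uses forward differences; restart rounds (fresh curvature memory, up
to two, stopping when a restart gains less than 0.01 OFV) switch to central
differences, whose $O(h^2)$ truncation error no longer biases the search
direction — the likelihood around the optimum is a long, gently sloping
valley (volumes and slopes trade off against variances), and biased
gradients otherwise stall the search several OFV units short. For the same
reason the standard-error Hessian uses central differences with step 0.05.
For cold starts, `fu_fit_staged()` first fits the PK submodel alone and
then the joint model from there, mirroring the conventional development
sequence (empirical PK model first, then the combined PKPD model); the
joint cold start otherwise spends most of its budget dragging PD parameters
through badly scaled terrain. Standard errors come
from $2H^{-1}$ on the unconstrained scale, delta-method-transformed back;
$\eta$-shrinkage is $1-\mathrm{sd}(\hat\eta)/\omega$. Proportional-error
variances are floored at predictions of $10^{-10}$ to avoid degenerate
zero-variance records.

The bootstrap resamples subjects with replacement *stratified by
co-medication group*: the source analysis is silent on stratification, but
without it a replicate can lose an entire slope arm and the comb/mono
slopes become unidentifiable. Failed replicates are counted and reported,
never silently dropped.

## Synthetic study generator

The generator emulates the study design that produced the original data,
and its defaults are those conditions: 30 subjects (5 women / 25 men), BSA
from a normal distribution centred at the cohort median 1.95 m² truncated
to the observed range 1.48–2.33 m² (SD 0.20 m², chosen so that a sample of
30 plausibly spans that range); 650 or 1000 mg/m²/day as a single 120-h
continuous infusion (the published report does not give the dose-level
split, so the default weight is 50:50); exactly 14/30 subjects
cisplatin-comedicated (an exact split preserves slope identifiability in
small cohorts); PK samples pre-dose, at 36, 48 and 108 h, at end of
infusion and 5/30/60/90 min after; WBC at baseline and on days
5/8/12/15/19/22/26, each post-baseline visit retained with probability
0.52 so the average of about 4.7 WBC observations per subject matches the
reported 135 observations in 29 patients (exact per-patient days were not
published). LLOQs are 0.005 (5FU) and 0.01 (5FUH2) mg/L; the pre-dose
sample is zero by construction and flagged BQL; BQL records are flagged,
retained in the table, and discarded before fitting (the analysis used
quantifiable concentrations only — the flag leaves room for an M3-style
likelihood later). Cohort and observation draws use seed-offset RNG streams
so regenerating observations never reshuffles covariates.

What the generator does *not* emulate: dropout or dose modification due to
toxicity, additional treatment cycles, platelet/erythrocyte lines,
time-varying covariates, genotype effects (hooks exist in the covariate
table, but no genotype model ships), and any PK of co-administered drugs.
Passing recovery tests on these synthetic cohorts therefore demonstrates
internal consistency of simulator + estimator under the stated design — not
robustness to the misspecification real data would add.

## Simulation scenarios

`run_scenario()` simulates the typical individual ($\eta=0$, BSA 1.95 m²)
over 45 days — long enough to bracket the nadir and rebound. The `mono` and
`combination` scenarios share the 5-day continuous-infusion regimen and
differ only in the slope; the published typical-individual figures leave
the simulated dose level unstated, and the package default of
1000 mg/m²/day at the bootstrap-column parameters yields nadirs of about
4.09 (mono) and 2.02 (combination) ×10⁹/L on days 23–24. The reported
nadir pair (4.29 / 2.26) is matched within ~1% only at an intermediate
exposure near 900 mg/m²/day (AUC₂₄ ≈ 7 mg·h/L, close to the reported
typical AUC₂₄); the combination arm at the 1000 mg/m²/day setting sits
about 10% below the reported value, and the package keeps the stated-dose
default rather than tuning the dose to the printed numbers. The
`folfirinox_5fu` and `degramont_5fu` scenarios simulate the 5FU components
of the two standard regimens in isolation — a single course, other
components ignored; de Gramont is the day-1 bolus + 24-h infusion sequence
(the full multi-day course can be built via the `regimen` override).

## Visual predictive checks

`vpc()` re-simulates the design embedded in an observation table (same
subjects, doses, sampling times; fresh $\eta$ and $\varepsilon$),
summarises the 2.5th/50th/97.5th percentiles per time bin, and overlays
the observed percentiles on the simulation-based 95% confidence band of
each percentile. Concentration VPCs bin at the nominal protocol times; WBC
VPCs use 3.5-day bins. Bins with fewer than two observations are merged
leftward with a warning. On self-simulated data the observed percentiles
should fall inside the bands at about the nominal rate, which the
acceptance suite checks with 500 simulations.

## Problem sizes and reproducibility

The shipped tests run at sizes chosen to exercise every path at desk
scale: single 30-subject fits for recovery (judged at the ±20%
single-replicate band; the slopes' sampling error at this design is large —
the original bootstrap RSEs are 25–27% — so individual replicates scatter
widely), a 5-replicate likelihood-ratio smoke test for the body-size
effect on 5FU-only data, 500-simulation VPC calibration, and
2-replicate bootstrap determinism checks. Full-size analyses (1000
bootstrap replicates, 50-replicate power studies) use the same functions
with larger arguments. Every stochastic step takes an explicit integer
seed, and file writers emit JSON provenance sidecars recording seed and
package version.

## Known limitations

- FOCE-I is a linearisation; its OFV differs from exact-likelihood methods
  and from other implementations by constants and approximation details —
  decisions ($\Delta$OFV) transfer, absolute OFVs do not.
- $\Omega$ is diagonal; $\eta$ correlations are not estimable from this
  design and are not modelled.
- No M3 likelihood for BQL records (flagged and dropped instead).
- The drug-effect slope and MTT are strongly correlated under the sparse
  late-sampling WBC schedule; single-study estimates of the slopes carry
  large sampling error, which is a property of the design, not the
  estimator.
- Single treatment cycle only; no accumulation across courses.
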