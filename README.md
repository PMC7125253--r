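# fupkpd

Population pharmacokinetic–pharmacodynamic (PKPD) modelling of
myelosuppression under continuous-infusion 5-fluorouracil (5FU), for
pharmacometricians and clinical-pharmacology researchers who want a fully
scripted, reproducible counterpart to a NONMEM-style analysis: simulate
virtual studies, fit the nonlinear mixed-effects model, test covariates,
bootstrap uncertainty, run visual predictive checks and explore dosing
scenarios — all in R.

## The model

**Pharmacokinetics.** 5FU follows a two-compartment model with linear
elimination; a fixed fraction *F*ₘ = 0.85 of the eliminated parent is
converted to the catabolite 5-fluoro-5,6-dihydrouracil (5FUH2), described by
a one-compartment model:

    dA_c/dt = R(t) − (CL + Q)/V_c · A_c + Q/V_p · A_p
    dA_p/dt = Q/V_c · A_c − Q/V_p · A_p
    dA_m/dt = F_m · CL · C_p − CL_m/V_m · A_m,      C_p = A_c/V_c

This linear system is solved exactly per constant-rate infusion segment
(eigendecomposition / matrix exponential), so PK predictions carry no
time-step error.

**Pharmacodynamics.** Leukocyte suppression follows the transit-compartment
(Friberg-type) model: a proliferating pool, three maturation transit
compartments and a circulating pool, with
*k*<sub>prol</sub> = *k*<sub>tr</sub> = *k*<sub>circ</sub> = (*n*+1)/MTT,
feedback (Circ₀/Circ)^γ (γ fixed at 0.17) and a linear drug effect
*E*<sub>drug</sub> = slope · *C*ₚ inhibiting proliferation:

    dProl/dt = k_tr · Prol · (1 − E_drug) · (Circ0/Circ)^γ − k_tr · Prol
    dT_i/dt  = k_tr · (T_{i−1} − T_i)
    dCirc/dt = k_tr · T_n − k_tr · Circ

**Population layer.** Log-normal interindividual variability on CL, V_c,
CL_m, V_m and Circ₀; proportional residual error per observation type; a
single linear body-surface-area factor, 1 + θ_BSA·(BSA − 1.95), scaling both
clearances; and separate drug-effect slopes for 5FU monotherapy and
cisplatin co-medication.

**Estimation.** A native FOCE-I engine (first-order conditional estimation
with interaction): per subject, the conditional mode of the random effects
is located, the model is linearised about it with residual variance held at
the conditional prediction, and Gaussian marginal contributions are summed.
Likelihood-ratio covariate tests (ΔOFV ≥ 3.84 per df), nonparametric
bootstrap CIs and VPCs complete the workflow. Units are mg, L, h, mg/L and
10⁹/L throughout; the slope is in L/mg.

## Worked example

```r
library(fupkpd)

pop <- fu_final_model("bootstrap")    # packaged final-model estimates

# typical-individual dosing scenarios (BSA 1.95 m2, eta = 0)
mono <- run_scenario("mono", pop, dose_per_m2 = 1000)
comb <- run_scenario("combination", pop, dose_per_m2 = 1000)
comb
#> Scenario 'combination': 5-day continuous infusion, 5FU + cisplatin
#>   slope 2.82 L/mg; WBC nadir 2.022 x 1e9/L at 584.2 h (day 24.3)
mono$wbc_nadir
#> [1] 4.085553
```

The combination arm (slope 2.82 L/mg) drops the typical leukocyte count to
about 2.0 × 10⁹/L around day 24 after the start of the 120-h infusion;
monotherapy (slope 1.17 L/mg) reaches about 4.1 × 10⁹/L a day earlier. The
two arms share the identical regimen and differ only in the slope, so the
difference is purely the cisplatin interaction on the drug effect.

```r
# simulate a 30-subject virtual study at those parameters and refit it
design <- study_design()
cohort <- generate_cohort(design, seed = 1)
dataset <- simulate_dataset(cohort, pop, design, seed = 1)
fit <- fu_fit(dataset, init = fu_final_model("nonmem"), se = FALSE)
fit$estimates$theta[["CL"]]    # recovered total 5FU clearance, L/h
```

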