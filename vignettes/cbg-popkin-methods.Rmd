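---
title: "Methods: population pharmacokinetics of cannabigerol and its glucuronide in horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of cannabigerol and its glucuronide in horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cannabigerol (CBG) is a lipophilic, non-psychoactive cannabinoid whose
disposition in the horse is characterized by extensive hepatic conversion to
a glucuronide conjugate (CBG-G), a very large distribution volume and high
systemic clearance. `cbgpk` implements the full population-pharmacokinetic
analysis of a three-occasion crossover in eight horses — IV 1 mg/kg infused
over 5 minutes, then 10 mg/kg orally as a micellar and as an oil
formulation — exercised end to end on synthetic data that emulates the
study design, since the animal-level concentrations are not public.

## Structural model

Parent kinetics are two-compartmental with linear elimination; the
glucuronide occupies a single compartment fed by a fixed fraction
$F_m = 0.75$ of parent elimination. Amounts are tracked in nmol/kg of
parent-molar equivalents, so $F_m$ conserves moles; concentrations are
$C_1 = A_1/V_c$ (parent) and $C_3 = A_3/V_m$ (metabolite):

$$
\begin{aligned}
\dot A_1 &= r(t) + \tfrac{Q}{V_p} A_2 - \tfrac{Cl + Q}{V_c} A_1, &
\dot A_2 &= \tfrac{Q}{V_c} A_1 - \tfrac{Q}{V_p} A_2, \\
\dot A_3 &= F_m \tfrac{Cl}{V_c} A_1 - \tfrac{Cl_m}{V_m} A_3,
\end{aligned}
$$

IV doses enter the central compartment as a zero-order infusion of 5 min
(a configuration switch allows a true bolus). Oral doses load a depot of
size $F \cdot D$ that empties with Weibull survival
$\exp\{-(k_a t)^\beta\}$; the input rate $r(t)$ is its negative derivative.
Two conventions deserve a note:

* **Bioavailability scales the absorbed amount.** The depot is initialized
  at $F \cdot D$ with outflow $k_a^W A_4$. Written with $F$ on both sides of
  the depot transfer, $F$ would cancel out of total exposure, contradicting
  the estimated 28% bioavailability; the absorbed-fraction convention is
  the one that reproduces exposure.
* **Shape below one.** For the oil formulation ($\beta = 0.70$) the input
  rate diverges at $t \to 0^+$. The compiled solver therefore never
  evaluates the rate at the dose time: integration restarts $10^{-4}$ h
  after each oral dose with the (analytically known, $\sim 10^{-4}$ of the
  dose) mass absorbed in that window credited to the central compartment.

The kernel is an adaptive Dormand–Prince 5(4) integrator written in C++
(the pattern used by compiled-model pharmacometric packages), carrying two
extra states for the running concentration AUCs so interval exposures are
integrated to solver tolerance rather than by quadrature on a grid. Default
tolerances are `rtol = atol = 1e-8` (`1e-6` inside the stochastic fit,
where solver error is far below the Monte Carlo noise); the oracle tests
run at `1e-10` against (a) the analytic eigen-decomposition solution for IV
dosing and (b) an independent `deSolve::lsoda` integration for oral dosing.
Multiple doses superpose linearly, each oral dose on its own Weibull clock;
no steady-state shortcut is used anywhere.

The terminal half-life implied by the published typical values — the
smaller root of $\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21}$
— is 28.4 h, matching the reported "approximately 29 h".

## Population layer

Each structural parameter is log-normal between subjects except
bioavailability, which is logit-normal so draws stay inside (0, 1).
Occasion-level variability (IOV) applies to the absorption-side parameters
$F$, $k_a$, $\beta$ only, and only across the two oral occasions; the IV
occasion bypasses the depot entirely. The oral formulation enters as a
categorical covariate on $k_a$ and $\beta$ (micellar reference, oil
coefficients $\ln(0.31/0.99)$ and $\ln(0.70/1.59)$ on the log scale).
Residual error is proportional per analyte,
$C_{obs} = C_{pred}(1 + b\,\varepsilon)$, with $b_1 = 0.29$ (parent) and
$b_2 = 0.41$ (metabolite), truncated at zero.

The published variabilities are printed as percentages without a stated
convention. We read them as CV% for log-normal parameters,
$\omega = \sqrt{\ln(1 + (\mathrm{pct}/100)^2)}$, and as the direct SD of
the logit-scale effect for $F$ — CV is the dominant reporting convention
and the difference is second order at these magnitudes. Random effects are
uncorrelated (no off-diagonal covariances are reported).

## Synthetic-study generator

`generate_study()` reproduces the design: 8 subjects (configurable), body
weight $\sim N(451, 49.4^2)$ kg truncated positive (carried in the dataset,
not used as a covariate — weight was tested and rejected in the original
analysis), sampling at 0, 5, 10, 15, 30, 45 min and 1–72 h, complete
washout, oral order alternating subject-by-subject as a 2×2 Latin square.
Observations below the limit of quantification are flagged and excluded
from fitting (likelihood-based censoring is out of scope; with the printed
LOQs of 0.0004/0.0008 nmol/L — orders of magnitude below simulated
concentrations, most likely a units typo in the source, retained as
configurable defaults — only the pre-dose zeros are affected). Generating
parameters go to a sidecar, never into the fitting table.

What the generator does *not* emulate: assay drift, dropout, sampling-time
deviations, correlated random effects and model misspecification. Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the assumed model, not robustness to the frictions of real
data.

## Estimation

`fit_nlme()` maximizes the marginal likelihood by SAEM. The E-step samples
subject latents by Metropolis-within-Gibbs in four blocks — parent
disposition $(Cl, V_c, V_p)$, metabolite $(V_m, Cl_m)$, $Q$, and the
per-occasion absorption vector $(F, k_a, \beta)$ — with an exact Gibbs
update for the subject-level absorption mean given its occasion latents.
Proposal scales adapt per subject toward 30% acceptance. The M-step is
closed-form on the sampled sufficient statistics (means/variances on the
transformed scale; the covariate coefficient is the mean occasion-level
deviation in the oil category; $b^2$ is the mean squared relative
residual). Two phases: an exploration phase (step size 1, default 250
iterations) in which variances may not shrink faster than 5% per iteration
(simulated annealing, preventing early collapse), then a
stochastic-approximation phase (default 150 iterations, step
$1/k^{0.65}$).

Choices worth recording:

* **$Q$ carries no random effect** (none is reported). A parameter without
  variability has no closed-form M-step in SAEM, so $Q$ keeps an artificial
  exploration SD (0.3 during burn-in, 0.05 after) and its typical value
  tracks the stochastic mean of the per-subject walkers — the standard
  device for no-variability parameters. It remains the loosest-identified
  typical value (self-consistency runs recover it within ~10–20% where
  data-rich parameters land within a few percent).
* **Initial values.** NCA heuristics (Cl from IV dose/AUC, F from
  dose-normalized AUC ratios, volumes from the terminal phase) refined by a
  naive-pooled least-squares fit of all typical values to the median
  observed curve per stratum/time/analyte (`pooled_prefit()`): under
  multiplicative noise the median curve tracks the typical-subject curve,
  and starting SAEM inside the right basin removes the one-compartment
  local mode the cold start can fall into.
* **IOV floor.** The occasion-level SDs are floored at 0.015 during
  sampling so the Gibbs step stays proper; a fitted IOV at the floor is
  reported as (numerically) zero variability.
* **Fixed $F_m$.** The metabolized fraction is structurally unidentifiable
  without IV dosing of the metabolite and is fixed at 0.75, as in the
  source analysis; requesting it free is an error.
* **Likelihood and model choice.** The marginal log-likelihood is estimated
  after fitting by importance sampling at the per-subject conditional
  (Gaussian proposal from the stored chain, inflated 1.5×; subject-level
  absorption means integrated out analytically). AIC $= -2LL + 2p$ and
  BIC $= -2LL + p\ln N$ with $N$ = number of subjects (the source does not
  state its convention). A covariate is retained when it lowers BIC by at
  least 10. The stepwise conditional-sampling covariate search of the
  original workflow is out of scope; the direct ΔBIC comparison replaces it.
* **Uncertainty.** Parameter uncertainty is quantified by the
  non-parametric bootstrap (subjects resampled with replacement, 2.5/97.5
  percentiles; 200 replicates by default — the test suite and examples use
  far fewer). Convergence robustness is assessed by refitting from
  perturbed starting values (`convergence_assessment()`; the original used
  500 replicates, the default here is 20, scaled to the compute of a
  routine run).
* **Residual model.** Proportional, as selected in the source; $b$ floors
  at $10^{-3}$ so noise-free self-consistency tests remain well posed.

## Problem sizes used by the tests

The recovery experiments use 50-subject crossover studies (the size at
which the median of a log-normal draw is tight enough to compare against
the published typicals) and ten replicate datasets for the bias study;
throwaway fits inside unit tests use 2–8 subjects with shortened SAEM
schedules. One caveat is intrinsic to the design: the oil-category $k_a$
combines 46.6% IIV with 38% IOV, so the median of 50 draws has a sampling
SD near 10% — single-study estimates can sit 20–30% from the generating
value without any estimator bias (the tests bound the single-study error
at 2.5× the sampling SD and additionally check the estimate against the
realized sample median; the replicate study bounds the median bias at 15%,
with 10% for $Cl$ and $F$).

## Monte Carlo regimen simulation

`monte_carlo_regimen()` draws 5000 subjects per arm from the population
distribution (one IIV draw plus one IOV draw per subject — the treatment
course is a single occasion), solves the 14-dose profile directly and
integrates the first (0–24 h) and last (312–336 h) dosing intervals via
the AUC states. The accumulation index is the per-subject ratio of those
two. Summaries report the **median**: the typical-value closed form
$F D/Cl = 5297.8$ nmol·h/L sits within 1.5% of the published steady-state
5225.31 on the median reading, whereas a mean over log-normal variability
would sit ~7% high; the source does not state its summary statistic. Note
that the source simulated from its eight horses' individual estimates,
which a population draw cannot reproduce exactly; its oil-arm steady-state
AUC (4619.62) sits ~12% below what the published population parameters
imply (absorption is >99.9% complete within 336 h even at low $k_a,\beta$
draws, so both arms share the same theoretical steady-state exposure).
`time_to_steady_state()` reports when the interval AUC of the typical
subject reaches a threshold (default 90%) of the final interval — about
day 4 for the micellar formulation at 90%, consistent with the reported
attainment "from the fifth or sixth day" read at a stricter threshold.

## Diagnostics

The VPC simulates replicates of the exact observed design, bins by nominal
sampling time (the design is nominal-time rich sampling; no adaptive
binning), stratifies by analyte × administration stratum, and draws the
5th–95th percentile band of each simulated 10th/50th/90th percentile.
IWRES uses the empirical Bayes modes (short scaled BFGS refinement of the
chain state). PWRES uses marginal moments estimated by simulating the
fitted model at the design points — a simulation estimate of the same
moments a first-order approximation would linearize, chosen because the
decorrelation convention is not specified in the source; no off-diagonal
decorrelation is applied.

## Units

Internally everything is molar: h, nmol/L, nmol/kg, with CBG's molecular
weight fixed at 316.48 g/mol for the mg↔nmol bridge at configuration
boundaries only. The published exposure tables label AUCs "μmol/L·h", but
the values are consistent with the nmol scale (the closed forms above
reproduce them to <0.1%); all comparisons are made on that numeric scale.

## Known limitations

Saturable elimination, enterohepatic recirculation and the unquantified
phase-I metabolites are out of scope, as are likelihood-based BLOQ
handling, correlated random effects, body-weight covariate modeling and
the real-animal observed-data summaries (which depend on the unreleased
raw concentrations). The SAEM implementation targets recovery of this
model class, not algorithmic equivalence with commercial tools.
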