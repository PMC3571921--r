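---
title: "In vivo kinetic parameters and kinetically constrained flux balance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In vivo kinetic parameters and kinetically constrained flux balance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Constraint-based models of metabolism predict steady-state flux
distributions from mass balances (`S v = 0`), flux bounds and an
optimization objective, without any kinetic information.  Their
predictions can therefore be kinetically unachievable: no enzyme
complement at physiological concentrations may be able to carry the
predicted fluxes.  `kfba` implements the complementary program: estimate
the kinetic parameters of central *Escherichia coli* metabolism *in vivo*
from multi-omic chemostat data, and feed the resulting kinetically
achievable flux ranges back into the constraint-based model as
relaxable bounds (KFBA).

Three data layers are integrated per experimental condition `l`:
measured fluxes (mmol/gDW/h, projected onto the steady-state space of the
network), metabolite concentrations `c_il` (mM, mean and standard
deviation), and enzyme concentrations `e_kl` (mg protein/gDCW).  Every
kinetic reaction `k` carries a rate law of the form

    v_kl = e_kl * f_k(c_l; theta)

where `f_k` is a mechanistic function of concentrations and the kinetic
parameter vector `theta` (catalytic constants `kcat`, equilibrium
constants `Keq`, binding coefficients `Km`).

## The estimation problem

Parameters and per-condition concentrations are estimated jointly by a
weighted sum of least squares (WSLS):

    min over (c, e, AEC, theta) of
      sum_l sum_i Wc_il (c_il - c_il_exp)^2 + sum_k We_kl (e_kl - e_kl_exp)^2

subject to, for every condition and kinetic reaction,

* the rate-law equality `v_kl = e_kl f_k(c_l; theta)` with `v_kl` fixed
  to the adjusted flux measurement,
* the adenylate energy charge `(ATP + ADP/2) / (ATP + ADP + AMP) >= 0.8`
  (ATP is not measured; this constraint ties it to measured ADP and AMP),
* concentration and enzyme boxes `0.001` to `10` (mM and mg
  protein/gDCW),
* global parameter bounds `1e-6` to `1e4` in each parameter's units,
  except equilibrium constants, which are confined to `0.35` to `2.85`
  times their reference value — a band of about 2.6 kJ/mol on the
  free-energy scale.

Weights are inverse experimental variances, with a coefficient-of-
variation floor (default 5%) guarding degenerate variances, and zero
weight for missing cells (missing data drop out of the objective rather
than being imputed).

### Numerical strategy

The solver works on log-transformed variables and proceeds in phases:

1. **Relaxation phase.**  Enzymes are kept as free box-bounded variables
   and the rate-law equality enters as a smooth penalty
   `lambda (e f - v)^2 / max(1, v)^2`.  This formulation has no poles, so
   the sign of each reversible rate factor can settle onto the sign of
   its flux regardless of the starting point.
2. **Exact phase.**  Enzymes are eliminated through `e = v / f`, making
   the rate-law constraint hold exactly at every iterate, and the
   problem is polished first by bound-constrained quasi-Newton steps and
   then by Levenberg–Marquardt on the residual system with an analytic
   Jacobian.  The second-order step is what crosses the long, narrow,
   ill-conditioned valleys this problem develops (see below).
3. **Multi-start.**  The feasible space is non-convex, so the solve is
   repeated from several starts: the first start places concentrations at
   their measurements and parameters at per-law least-squares pre-fits
   computed directly from the raw data; later starts jitter these, and
   every fifth start draws parameters log-uniformly within their global
   bounds.  The feasible solution with the lowest objective wins.  The
   default of 24 starts is deliberately moderate: with the data-informed
   first start the best solution is typically found by start 1 or 2, and
   the remaining starts act as a non-convexity guard.

The adenylate energy charge is enforced exactly by reparameterizing ATP
over its AEC-feasible interval `[(1.5 ADP + 4 AMP), 10]` (for the default
floor of 0.8).  Enzyme box bounds are enforced by a scale-invariant
quadratic penalty and audited at the solution; the audit value is
reported in the fit object.

### A structural caveat: the ATP scale

Because ATP is unmeasured and enters four laws (PFK, PGK, PYK, 6PG
dehydrogenase), the model admits an exact compensation: rescaling every
per-condition ATP concentration by a common factor can be absorbed by
rescaling `kcat_PFK`, `kcat_PYK`, `kcat_GND` and `Keq_PGK`.  Only the
energy-charge floor, the concentration box and the `Keq` band delimit
this direction.  These parameters are therefore set-identified rather
than point-identified; their profile confidence intervals are
correspondingly wide, which is the honest description of what the data
determine.  The tests distinguish *sharply determined* parameters
(relative confidence-interval width below 0.1), which must land on the
ground truth in the noiseless limit, from *identifiable* parameters
(relative width below 10), for which interval coverage is asserted.

### Confidence intervals

Each parameter is perturbed one at a time on the log scale and all other
variables re-optimized (a profile); the WSLS increase is extrapolated
quadratically to the chi-square quantile with one degree of freedom.
Each side probes two offsets (`delta` and `3 delta`) and keeps the more
conservative extrapolation, so profiles that steepen locally but flatten
farther out — the signature of the compensable directions above — are
not cut short.  Flat profiles are flagged unbounded and truncated at the
global bounds.  Near-equilibrium reactions illustrate the expected
pattern: their equilibrium constants are determined to a fraction of a
percent while their catalytic constants are essentially unbounded above,
because the rate factor is close to zero and `kcat` only needs to be
large enough.

## Thermodynamics

Fitted equilibrium constants yield standard reaction free energies
`dG = -RT ln Keq` (T defaults to 298.15 K, the temperature at which the
Keq band corresponds to 2.6 kJ/mol), and the per-condition values
`dG* = dG + RT sum_i S_ij ln c_i` with concentrations in mM — the same
convention the equilibrium constants were fitted under, so the choice of
standard state cancels between conditions for balanced reactions.
Reactions with mean `dG*` below −10 kJ/mol are classified far from
equilibrium (the natural flux-control points); means in `[-2, 0]` are
near equilibrium.  Irreversible laws carry no equilibrium constant and
are excluded.  Retained binding coefficients are compared with their
metabolite's concentrations to classify saturation/inhibition and
activation effects as strong (ratio outside one order of magnitude) or
intermediate.

## Kinetic flux bounds and KFBA

For a held-out condition, each rate law maps the measured enzyme and
metabolite concentrations plus the 95% parameter box to a flux interval
`[v_min, v_max]`.  All laws are monotone in each parameter at fixed
concentrations, so the extrema sit at vertices of the box; the
implementation enumerates vertices (at most `2^3` per law plus a factor
two when ATP is ranged over its energy-charge interval) and is verified
against dense parameter grids in the tests.  Measurement error in the
concentrations themselves is deliberately not propagated (a documented
non-goal); the bound-coverage property is therefore asserted against the
generating concentrations of the synthetic study.

KFBA then minimizes glucose uptake at the chemostat growth rate subject
to mass balance, default bounds (−1000/0/1000 mmol/gDW/h), blocked
fermentative pathways, and the kinetic bounds — each carrying a binary
that relaxes it back to the default bound.  The minimum number of
violated bounds `n*` is found first (branch and bound over proximal-point
LP relaxations; the convex substeps use a dual active-set QP), then
uptake is minimized under the budget `n*`, and finally the alternate
optimum with the smallest sum of squared fluxes is selected, which makes
the reported flux vector unique.  Every solution is re-verified against
the constraint set by direct substitution.  When every bound is allowed
to be violated the KFBA solution coincides with FBA component-wise — a
built-in test.

Prediction error against the adjusted flux measurements counts
stoichiometrically coupled reactions (parallel null-space rows of `S`)
once, and biomass yield is growth rate over predicted glucose uptake.
Paired FBA/KFBA comparisons use the exact two-sided sign test.

## The synthetic chemostat study

No experimental dataset ships with the package; a generator produces
studies with known ground truth that emulate a glucose-limited chemostat
design: a parental strain at dilution rates 0.1–0.7 1/h plus
single-knockout strains at 0.2 1/h, 20 training and 5 held-out test
conditions by default, with the shipped fitted parameter values as
ground truth.  Per condition the generator

1. samples a steady-state flux distribution: glucose uptake is drawn
   8–30% above the minimal feasible uptake at that dilution rate
   (chemostat cultures are near, not at, maximal yield), the oxidative
   pentose phosphate branch carries a sampled 15–35% of uptake, pyruvate
   kinase a floor share (it is minimum-norm-fragile otherwise), and a
   random target vector is projected onto the steady-state polytope;
2. solves for concentrations and enzymes satisfying every rate law
   exactly at the true parameters, the energy-charge constraint and both
   boxes, anchored softly to a fixed base concentration profile;
3. emits multiplicative log-normal noise (default CV 5%) on metabolite
   and enzyme concentrations — the quantities that carry standard
   deviations and weights in the estimation objective — with reported
   per-cell standard deviations `truth * CV`; ATP is never reported.
   Fluxes are reported as the steady-state values the estimator fixes
   them to (an optional `flux_noise_cv` perturbs them for robustness
   experiments; flux error is outside the WSLS error model).

Knockouts are modeled as depletion to the enzyme floor (0.001 mg
protein/gDCW) with the reaction's flux capped at what the floor enzyme
can carry, which keeps the rate-law equality exactly satisfiable; the
knockout list excludes reactions whose depletion cannot sustain
chemostat growth in the reduced network (glucose uptake, pyruvate
dehydrogenase — the sole acetyl-CoA source with fermentation blocked —
and phosphofructokinase/aldolase, whose caps would force carbon through
CO2-wasting pentose phosphate cycling).  Everything is a deterministic
function of the seed.

What passing tests on such studies do show: the estimator, interval
machinery, bound computation and KFBA pipeline are mutually consistent
and recover a known truth under realistic noise.  What they cannot show:
that the shipped rate-law forms describe any particular organism's
kinetics, or how the pipeline behaves under structured (non-log-normal,
correlated) measurement error and model misspecification.

## The shipped network fixture

The package ships a curated ~54-reaction central *E. coli* network
(glycolysis, pentose phosphate pathway, TCA cycle with glyoxylate shunt,
lumped oxidative phosphorylation with P/O 2 for NADH and 1 for
succinate, PEP carboxylase/carboxykinase and malic-enzyme anaplerosis,
four fermentative secretion routes that KFBA blocks, exchanges, an ATP
maintenance drain at 3.15 mmol/gDW/h, and a core-like lumped biomass
drain with glutamate demands folded into 2-oxoglutarate).  CoA,
orthophosphate, protons and water are not balanced; AMP appears in
concentration data only.  The composition is documented inside the JSON
fixture itself, and the minimum-uptake yield at 0.2 1/h is about
0.079 gDW per mmol glucose.

## Tunable parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `aec_min` | 0.8 | – | adenylate energy charge floor |
| `conc_bounds` | 0.001–10 | mM | metabolite box |
| `enzyme_bounds` | 0.001–10 | mg protein/gDCW | enzyme box |
| `variance_floor` | 0.05 | CV | weight floor for degenerate variances |
| `n_starts` | 24 | – | multi-start budget |
| `alpha` | 0.05 | – | CI significance level |
| `delta` | 0.1 | log units | CI profile probe offset |
| `temperature` | 298.15 | K | thermodynamic analyses |
| far-from-equilibrium threshold | −10 | kJ/mol | classification |
| `noise_cv` | 0.05 | CV | generator measurement noise |

## Problem sizes used in the shipped tests

The module tests run on 5–7-condition studies; the acceptance tests and
`scripts/acceptance.R` use the canonical 20 + 5 design at 5% noise with
two multi-start replicates for the joint fit.  These sizes were chosen
so a full check-out of the package completes comfortably on a laptop
core while still exercising every stage at the study scale the design
calls for.

## Known limitations

* The two garbled-source rate laws (6PG dehydrogenase, and the
  PTS/pyruvate-kinase ratio forms) are unit-consistent reconstructions;
  the registry accepts replacement expressions through the JSON schema if
  a different reading is preferred.
* The ATP-scale compensation described above caps what any estimator can
  extract from data lacking ATP measurements.
* Kinetic bounds ignore concentration measurement error.
* The MILP solver is a small branch and bound adequate for tens of
  binaries; genome-scale bound sets would need an industrial solver.
* Confidence intervals are one-at-a-time profiles with quadratic
  extrapolation, not full likelihood scans; strongly non-quadratic
  profiles are handled conservatively but approximately.
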