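---
title: "13C-constrained metabolic flux analysis of chemostat-grown Pichia pastoris"
author: "PichiaMFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{13C-constrained metabolic flux analysis of chemostat-grown Pichia pastoris}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PichiaMFA)
```

## The estimation problem

*Pichia pastoris* grown in a glucose-limited chemostat at dilution rate
D = 0.1 h^-1^ adapts its central carbon metabolism to the oxygen supply:
fully aerobic (normoxic, 21% O~2~ in the inlet gas), oxygen-limited (11%)
and hypoxic (8%, with ethanol and arabitol excretion). The quantity of
interest is the *net metabolic flux distribution* — the vector x of
reaction rates (mmol gDCW^-1^ h^-1^) through glycolysis, the pentose
phosphate pathway (PPP), the TCA cycle, the fermentative branches and the
anabolic precursor drains.

Fluxes are not observable directly. Three kinds of measurement constrain
them:

1. **Metabolite mass balances.** At steady state every balanced
   intracellular pool satisfies S x = 0, where S is the stoichiometric
   matrix. Cofactors (NADH/NADPH/ATP), O~2~ and CO~2~ are deliberately
   left unbalanced: balancing them would require isoenzyme- and
   compartment-resolved cofactor specificities, a major error source, and
   the flux-ratio constraints below make their balances unnecessary.
2. **Exchange and drain rates.** Specific glucose uptake, by-product
   excretion (ethanol, glycerol, arabitol) derived from broth
   concentrations via q = D·c/X, and the depletion of thirteen precursor
   pools into biomass (coefficient × growth rate).
3. **METAFoR flux ratios.** Fractional 13C-labelling of proteinogenic
   amino acids followed by 2D-NMR yields *metabolic flux ratio* (METAFoR)
   estimates: the fraction of a metabolite pool produced by one of several
   converging pathways. These are relative quantities, immune to absolute
   calibration error, and they close exactly the degrees of freedom that
   rates and balances leave open.

The four ratios used as constraints are, in terms of the aliased
reactions (x16 = mitochondrial malate dehydrogenase step, x17 = pyruvate
carboxylase, x23/x24 = oxaloacetate transport into/out of the
mitochondria, x23\* = net transport under normoxia, x3 = upper glycolysis,
x9/x10 = transketolase 1/2, x11 = transaldolase):

* a = x23 / (x23 + x16) — fraction of mitochondrial Oaa imported from the
  cytosol (oxygen-limited and hypoxic conditions only; under normoxia the
  cytosolic and mitochondrial Oaa labelling cannot be separated),
* b = x23\* / (x23\* + x16) — the normoxic analogue, built on the net
  transport flux and PEP labelling,
* c = x17 / (x17 + x24) — the anaplerotic ratio: fraction of cytosolic
  Oaa made from PEP/pyruvate rather than exported from the mitochondria,
* d ≥ (x9 + 2·x11 + 3·x10) / (2·x3 + x9 + x10) — an *upper bound* on the
  fraction of PEP originating from the pentose phosphate pool.

A measured ratio r with numerator flux u and denominator partner v turns
into the homogeneous linear row u·(1−r) − v·r = 0. The bound d becomes the
single inequality x9·(1−d) + 2·x11 + x10·(3−d) − 2·x3 ≤ 0. (This is the
published linearisation; the exact algebra of the ratio would put the
factor d on the x3 term as well. Since d ≤ 1 the published form is the
weaker, conservative side, and it is what this package implements.)

The complete system stacks S, the measurement rows and the ratio rows into
one matrix N with right-hand side b, and the estimate solves

  minimize ‖W(Nx − b)‖² subject to lower bounds, the d-inequality,
  and the mass balances as hard equalities,

a bounded, inequality-constrained least-squares problem. `W` holds per-row
weights; the default "whitened" mode divides every measurement-derived row
by its standard deviation so residuals are compared on a common scale, and
an "unweighted" mode reproduces the plain stacked system. Measurements
enter softly by default (they carry error); `strict = TRUE` pins them
exactly instead. Both choices are exposed because the original analysis
does not state which was used.

## The network model

`buildNetwork()` reconstructs the compartmented central-carbon model with
separate cytosolic and mitochondrial pools of pyruvate, acetyl-CoA and
oxaloacetate: glucose uptake, phosphoglucose isomerase, lumped upper
(F6P → 2 T3P) and lower (T3P → PEP) glycolysis, the oxidative PPP
(G6P → P5P + CO~2~), transketolase 1 and 2 and transaldolase, pyruvate
kinase, the fermentative chain (pyruvate decarboxylase → acetaldehyde →
ethanol excretion), cytosolic acetyl-CoA synthesis for the anabolic
demand, pyruvate transport and dehydrogenase, pyruvate carboxylase, the
oxaloacetate transport pair, a lumped TCA cycle
(Oaa + AcCoA → AKG → Oaa, the second span carrying the malate
dehydrogenase alias), glycerol and arabitol excretion branches (arabitol
drawn from the pentose-phosphate pool), and thirteen anabolic drains
(G6P, F6P, T3P, P5P, E4P, PEP, both pyruvate pools, both acetyl-CoA
pools, both oxaloacetate pools, AKG). The glyoxylate cycle, PEP
carboxykinase and malic enzyme are omitted (measured to be inactive or at
basal levels), and acetyl-CoA transport — the last step of the PDH
bypass — is omitted with the bypass flux lumped into PDH, because the
labelling protocol cannot distinguish the two routes.

Unbranched spans are lumped; a METAFoR-constrained analysis is invariant
to lumping because every reaction in an unbranched span carries the same
flux. Under normoxia the oxaloacetate import/export pair collapses into
one sign-free net transport reaction, giving 33 reactions; the
oxygen-limited and hypoxic variants carry the separate irreversible pair
and 34 reactions. The reversible set is PGI, the transketolases,
transaldolase and the normoxic net Oaa transport; every other flux,
including all excretions and drains, is non-negative.

The identities of the PPP aliases (x3, x9, x10, x11) are a modelling
convention; `setAliases()` remaps them if a different convention is
preferred.

```{r}
nReactions(buildNetwork("normoxic"))
nReactions(buildNetwork("hypoxic"))
```

## Measured inputs and their defaults

`packagedChemostat()` and `packagedRatios()` load the packaged
steady-state measurements (macroscopic growth parameters and METAFoR
ratios for the Fab-expressing and control strains at the three oxygen
setpoints). Two derived quantities deserve a note:

* The feed glucose concentration is not part of the packaged record and
  is back-computed as biomass / yield (residual glucose is below
  detection under carbon limitation). Consequently the relative error of
  the glucose uptake rate propagates from D and the yield only.
* The anabolic drain coefficients (`defaultDrainCoefficients()`) are
  **synthetic**: order-of-magnitude yeast precursor demands summing to
  about 43 mmol precursor carbon per gDCW (biomass elemental carbon is
  roughly 40 mmol C/g). The study they stand in for used condition-specific
  measured biomass composition that is not packaged here; any analysis
  that depends quantitatively on the drains should replace them.

The 13C-labelling protocol feeds labelled medium for one residence time
before harvest, so a fraction exp(−D·t) of the harvested biomass predates
the switch; `unlabeledFraction()` implements this wash-out correction
(exp(−1) ≈ 0.368 after one residence time). `carbonRecovery()` reports the
fraction of consumed glucose carbon recovered in biomass, CO~2~ and
products as a consistency diagnostic.

## Solving and uncertainty

`solveFluxes()` delegates the quadratic program to an active-set QP
solver, then re-solves the face identified by the active set with a
null-space/QR least-squares step (the raw QP solution of a whitened
system can sit slightly off the constraint face; the polished solution is
the exact face optimum). Optimality is certified by the projected-gradient
norm with tolerance 1e-10 on the normalized scale; the certificate is
evaluated residual-first to avoid forming the ill-conditioned normal
equations. Rank-deficient systems with structurally free flux directions
raise an error naming the free reactions (a minimum-norm fallback with a
warning is available). For positive-definiteness of the QP a relative
ridge of 1e-12 is added; it does not affect the polished solution.

Uncertainty follows the Fisher-Information route. The measured parameters
p are the rates (right-hand-side entries) and the equality ratios (row
coefficients). `sensitivityMatrix()` differentiates the constrained
estimator on the active face, analytically (implicit differentiation of
the reduced least-squares problem, stable across whitening scales) or by
finite differences (relative step 1e-6, with one-sided differences and a
warning when a perturbation changes the active set). With C the diagonal
measurement covariance ("assumed independent"), the flux covariance is
W·C·Wᵀ; on unconstrained full-rank systems this equals the inverse of the
classical information matrix Wᵐᵀ·C⁻¹·Wᵐ built from the measurement-model
sensitivities (`fisherInformation()`), which is also exposed directly.
Confidence intervals are estimate ± σ·t(α/2, v). The residual degrees of
freedom v are reported but the packaged systems are exactly determined
(measurement + ratio rows equal the free directions after the balances),
so v = 0 and the default quantile falls back to the normal distribution;
the measurement variances are taken as known, not re-estimated from
residuals.

Fluxes sitting on an active bound are flagged: the linearization is
one-sided there and σ describes the active face only. The d-inequality
contributes no Fisher information (an inactive inequality has zero
derivative; an active one truncates rather than informs).

## The synthetic-data generator

`sampleGroundTruth()` draws a feasible interior flux distribution by
hit-and-run sampling of the flux polytope with glucose uptake (default
2.0 mmol gDCW^-1^ h^-1^) and the anabolic drains fixed, under one of two
regimes: *respiratory* (ethanol, arabitol and glycerol excretion pinned
to zero) and *respiro-fermentative* (ethanol at least 25% of glucose
uptake, some arabitol). Draws are rejected until the METAFoR ratios of
the sample fall in the physiologically observed ranges (a, b, c in
0.30–0.80; d in 0.10–0.60), so synthetic experiments mirror realistic
flux partitioning and simulated ratio noise stays clear of the [0, 1]
truncation bounds; the respiratory regime, used for structural checks,
only guards against degenerate ratios. `simulateMeasurements()` adds
independent Gaussian noise — 5% relative on rates (with a 1e-4 floor for
zero rates) and per-ratio standard deviations of 0.02–0.07, matching the
published measurement precision — with ratios clipped to [0, 1]. Every
draw is fully determined by its seed.

What the generator does *not* emulate: correlated measurement errors,
systematic biases in the NMR-derived ratios, non-stationarity of the
pseudo-steady hypoxic state, or condition-specific biomass composition.
Passing recovery tests therefore demonstrates the correctness of the
estimation machinery under the stated error model, not robustness to
violations of it.

`recoveryExperiment()` runs simulate → solve → compare replicates and
reports per-flux bias, RMSE and CI coverage. A flux counts as
*identifiable* when its design standard deviation (FIM σ evaluated at the
truth under the stated noise) is at most half the flux magnitude and no
bound is active at the noiseless solution. This matters: under
measurement noise of the published magnitude, the PPP interconversion
fluxes (PGI, the transketolases, transaldolase, and the oxidative-PPP
flux itself) have design relative standard deviations of 0.5–1.5 — the
transport/anaplerotic ratios determine them only through a long,
ill-conditioned chain — and are genuinely *not identified* by these data;
their point estimates lean on the d-bound, which truncates rather than
informs. Coverage statements are made for the identifiable set.

`monteCarloCheck()` validates the FIM σ against empirical scatter from
noisy re-solves. When replicate noise pushes the estimate against the
d-inequality or a bound, the sampling distribution is truncated and the
linearized σ is conservative; the function therefore reports both the
all-replicate and the inactive-replicate empirical SDs plus the fraction
of constraint-free replicates. `uncertaintyValidationScenario()`
constructs an experiment in which the linearization premise holds by
design: the inequality is dropped and candidate truths are screened until
every irreversible flux estimate sits at least two FIM σ inside its
bound — a rule evaluated on the design only, never on Monte-Carlo
outcomes.

```{r, eval = FALSE}
model <- buildNetwork("hypoxic")
rec <- recoveryExperiment(model, "respiro_fermentative",
                          n_reps = 200, seed = 1)
rec$coverage_identifiable
```

## The packaged oxygenation series

`runMFA(condition)` assembles and solves the full system from the
packaged measurements. Across the series the estimates reproduce the
fermentative shift: the normalized glycolytic flux and ethanol excretion
rise from normoxia to hypoxia, and the normalized TCA respirative flux
falls. One published trend is *not* reproduced with the synthetic drain
coefficients: the decrease of the oxidative-PPP contribution under
hypoxia. With the small synthetic mitochondrial drains, the measured
transport/anaplerotic ratios pin the TCA flux low, and the surplus carbon
that cannot be respired exits through oxidative-PPP cycling — the only
remaining CO~2~ vent — keeping the fitted PPP flux high in all
conditions. Reproducing that trend quantitatively requires the
condition-specific biomass composition that the drains merely stand in
for. The weighted residuals of the fixture solves (reported as
`weighted_ssr`) make the same point: the packaged measurements and the
synthetic drains are not mutually consistent at their stated precisions.

```{r, eval = FALSE}
res <- runMFA("hypoxic")
res$solution
branchFractions(res$solution, res$model)
```

## Numerical choices, in one place

* Projected-gradient optimality tolerance: 1e-10 (normalized), evaluated
  residual-first.
* QP ridge: 1e-12 relative to the mean diagonal of the quadratic term.
* Finite-difference sensitivity step: 1e-6 relative.
* Feasibility tolerances: 1e-9 on bounds and the inequality when
  accepting the polished face solution.
* Rank decisions use the QR rank at R's default tolerance; singular
  information matrices are pseudo-inverted with a warning.
* Degrees of freedom for the t quantile: residual dof when at least 2,
  otherwise the normal quantile (the packaged systems are exactly
  determined, v = 0).
* Hit-and-run: 300 steps per draw, chord margin 1e-9, up to 250
  rejection retries.
* Reported problem sizes in the validation experiments: 200 replicates
  for coverage and Monte-Carlo checks, 1000 cases for the ratio
  round-trip property.

## Known limitations

* The anabolic drains are synthetic; absolute fluxes through the TCA and
  PPP depend on them materially (see above).
* The d-ratio enters as the published linearised inequality, which is
  weaker than the exact bound when x3 is large.
* FIM-based σ is a linearization: it is one-sided at active bounds and
  conservative under constraint truncation; the Monte-Carlo check
  quantifies this.
* The PPP interconversion fluxes are not identifiable at the published
  measurement precision; treat their point estimates and intervals as
  bounded by the d-constraint rather than measured.
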