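---
title: "Models and methods in coldlac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in coldlac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coldlac implements the full quantitative analysis chain used to
characterize a cold-active, reversibly dimerizing β-galactosidase. This
vignette is the package's own account of those models: what each one
assumes, which parameters matter and why their defaults are what they are,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate about real data.

## The shared fitting engine

All nonlinear fits minimize Σ((y − ŷ)/σ)² with Levenberg–Marquardt
trust-region least squares (minpack.lm) under box constraints, and return a
uniform object: estimates, standard errors, σ-weighted residuals, reduced
χ², and convergence/singularity flags. Standard errors come from the
Gauss–Newton covariance (J'J)⁻¹ scaled by reduced χ², matching `nls()`
conventions; a singular J'J is reported as infinite uncertainties rather
than an error, because unidentifiable parameters (e.g. K_D from a flat
titration) are an expected outcome, not a failure. Fits are deterministic
given data and initialization; the one multimodal surface (the biphasic
rate law) gets an optional seeded multi-start (n = 10) around the supplied
initialization.

Positive scale parameters (all dissociation constants, the taylorgram
radii) are fitted in log10 space. K_D is bounded in log10 units to
[−12, −2]; when no initialization is given, it starts at the concentration
where the titration crosses its half-transition.

## Kinetics

**ONP extinction.** Only the phenolate absorbs at 420 nm, so
ε(pH) = ε₋·10^(pH−pKa)/(1+10^(pH−pKa)) with ε₋ = 4600 M⁻¹cm⁻¹ and
pKa = 7.2. At pH 7.0 this evaluates to 1779.6 M⁻¹cm⁻¹; a figure of
1741 M⁻¹cm⁻¹ is sometimes quoted for the same inputs but is not consistent
with the formula, and the package follows the formula.

**Biphasic rate law.** The sequential-binding scheme
E + 2S ⇌ E:S + S ⇌ E:S₂ gives
k_obs = (kcat1 + kcat2·S/K2)/(1 + K1/S + S/K2). The same fit is exposed in
both parameterizations in use for two-phase Michaelis–Menten plots
(Vmax1 = kcat1, Km1 = K1, etc., via `biphasic_params()`). Fitting this
model to single-site data correctly drives K2 to its upper bound, which is
how "no second phase" manifests.

**Mg²⁺ activation.** The published rendering of the two-site activation
equation is typographically inconsistent (its K subscripts change mid
equation); the package implements the canonical three-state ladder
k_obs = (kcat_a·K_A/[Mg] + kcat_b + kcat_c·[Mg]/K_B)/(K_A/[Mg] + 1 +
[Mg]/K_B), which is the unique rational form with the stated limits: kcat_a
at zero Mg²⁺, kcat_b dominating when K_A ≪ [Mg] ≪ K_B, kcat_c at
saturation.

**Eyring analysis.** Linear regression of ln(k/T) on 1/T;
ΔH‡ = −slope·R, ΔS‡ = (intercept − ln(κk_B/h))·R. The transmission
coefficient κ is fixed at 1 by default (it is conventionally not
measurable from these data) but exposed. Plots that kink near room
temperature are handled by a user-supplied breakpoint (default 300 K)
splitting the data into two independent regressions; no objective
breakpoint detection is attempted because three points per segment is
typical and model selection at that n is not meaningful.

**Ionic strength.** I = ½Σcᵢzᵢ² after phosphate speciation. Only the
second phosphate ionization (pKa₂ = 7.2, configurable) is treated — the
first and third are >4 pH units away from neutral working buffers.
Counterions are counted at their formal concentrations; each supported
salt dissolves into a charge-neutral formal ion set, and the pH-dependent
proton balance of the re-speciated phosphate is absorbed by H⁺/OH⁻ and
not tracked. For the working buffer (2.7 mM KCl, 8 mM Na₂HPO₄, 2 mM
KH₂PO₄, 137 mM NaCl, 0.1 mM MgCl₂, pH 7.0) this yields 159.8 mM ≈ 160 mM.

## Stability

**Chemical denaturation.** The two- and three-state equations use decadic
exponents with m/RT inside — fidelity to how these equations are printed —
so the m-values carry a log10 convention; `m10_to_mln()` converts to the
conventional natural-log kcal/(mol·M) value (×ln 10). In the three-state
model the denatured population is weighted by the *product*
K_IN·K_DI, the thermodynamically consistent sequential form, which reduces
exactly to the two-state equation when the second transition is pushed to
infinite denaturant. Midpoint ordering u50_I ≤ u50_D is enforced by box
constraints to prevent label switching.

Because unfolding of the modeled enzyme is irreversible, the linear
extrapolation of ΔG to 0 M denaturant is deliberately not a headline
output; midpoints and m-values are reported as empirical, not equilibrium,
quantities.

**Thermal transitions.** Two-state van 't Hoff form
K(T) = exp[−(ΔH_vH/R)(1/T − 1/t_m)] with linear baselines per state;
two sequential transitions share the same structure with the denatured
population carrying K₁K₂. Populations are computed in log-space
(logistic/log-sum-exp), so arbitrarily steep transitions cannot overflow.
The choice of the van 't Hoff form (rather than any proprietary analysis
package's internals) is deliberate: t_m and baselines are the comparable
outputs, and the van 't Hoff form is the standard open model that produces
them.

**DSF inflection points.** Savitzky–Golay smoothing (window 11, order 3 —
unstated in typical instrument software, so declared here), finite
-difference derivative, discrete extremum with parabolic refinement. A
transition is only reported when the derivative peak has prominence ≥ 5%
of the derivative range *and* the derivative range itself is non-negligible
relative to its level; flat or purely linear scans return a no-transition
result rather than an error.

## Oligomerization

Dimer speciation is the closed-form physical root of the mass-action
quadratic, followed by one Newton polish step to remove the catastrophic
cancellation that otherwise appears at M₀ ≫ K_D; conservation and
mass-action residuals hold to 10⁻⁹ relative across M₀ ∈ [10⁻¹², 10⁻²] M.
Observables (R_h, or apparent t_m) map linearly between monomer and dimer
endpoints by the fraction of subunits in dimers, 2D/M₀. The apparent-t_m
titration reuses the identical functional form — the thermodynamic linkage
of unfolding and dissociation is deliberately *not* modeled, matching the
empirical treatment such data receive.

The n-mer generalization solves M + n·Mⁿ/K = M₀ by bisection (relative
tolerance 10⁻¹²; the function is strictly increasing so the root is
bracketed by construction) and reproduces the dimer model exactly at
n = 2. For the engineered tetramer-forming variant the natural reading is
"units are preformed dimers assembling 2→4", and both that and the 1→2
parameterization are available, since the choice cannot be decided from
titration data alone.

## SAXS

**Forward model.** One bead per residue at Cα with uniform weights;
I(q) = scale·ΣᵢΣⱼwᵢwⱼ·sinc(q·rᵢⱼ) + background. The hydration layer is a
single multiplicative weight increment on solvent-exposed beads (neighbor
count below 16 within 11 Å), scaled by the dimensionless ρ_hydration
bounded in [0.2, 1.3]. This is a deliberate simplification of atomistic
hydration-shell models: it preserves the fitted contract
(scale, hydration, background) while remaining evaluable in milliseconds.
Two caveats follow and are tested: the hydration term is only identifiable
when the structure actually has buried beads, and it is nearly collinear
with the scale, so its uncertainty is large on featureless models.

**q convention.** q = 4π·sinθ/λ throughout. (The same symbol is sometimes
defined without the π in print; the π-form is the one consistent with
typical laboratory q-ranges and the stated wavelength, and is what the
package uses.)

**Guinier.** ln I vs q² on a self-consistently iterated window
q·Rg < 1.3; upward low-q curvature beyond the residual noise sets an
aggregation flag.

**p(r) inversion.** Regularized non-negative least squares of
I(q) = 4π∫p(r)·sinc(qr)dr on a fixed grid with p(0) = p(Dmax) = 0 and a
second-difference smoothness penalty (weight auto-scaled to the design
matrix so the default α = 0.01 is dimensionless), solved by bounded
L-BFGS-B on the quadratic objective. Rg and I(0) come from the moments of
p(r). A long same-signed residual run flags a too-small Dmax.

**Mass.** M = I(0)·N_A/(c·Δρ_m²), Δρ_m = 2.0×10¹⁰ cm/g for a typical
protein; mass is exactly linear in I(0) and inversely linear in c, and the
monomer count is M/monomer mass. These estimates carry ~10% systematic
uncertainty in practice (concentration accuracy, contrast assumption).

**Rigid-body refinement.** The structure's three parts move as rigid
bodies in a Metropolis walk: per step one part gets a random rotation
(axis uniform on the sphere, angle U(0, 5°) about its centroid) plus a
translation U(−2, 2 Å)³. The objective is reduced χ² plus soft one-sided
springs on the inter-part anchor distances plus a per-pair clash penalty
below 3 Å. Scale and constant background are re-fitted analytically
(weighted linear profile) at every step; ρ_hydration is held at its
pre-refinement `chi2_fit()` value, because profiling the nonlinear
hydration term would multiply the Debye evaluations several-fold for no
measurable benefit in synthetic recovery experiments. The default
acceptance temperature is τ = 0.5 objective units with 100 steps × 10
runs; τ → 0 gives a greedy walk, and a low τ (~0.05) is what the recovery
tests use to polish into the basin. The refinement is bit-stable given the
seed (one RNG stream per run, seeded seed + run − 1), and the summary
reports mean ± SD of the per-run best reduced χ², the convention for
reporting such ensembles.

**Superposition.** Kabsch (SVD) rotation with reflection correction; RMSD
is invariant to rigid motions of either input.

## FIDA / Taylor dispersion

A taylorgram is modeled as a sum of Gaussians centered at the residence
time with species variance σ² = R_c²·t_R/(24D), D from Stokes–Einstein.
Fitting uses the central 75% of points around the apex — the standard
fraction, interpreted as a point fraction because vendor semantics are not
published — with one species' radius lockable (0.6 nm for free label). A
free species whose amplitude collapses below 10⁻³ of the apex is flagged
radius-unidentifiable. Buffer viscosity defaults to water via the
three-coefficient Vogel equation (well under 1% error at 0–60 °C) and is
overridable. The instrument constants (R_c = 37.5 μm, t_R = 180 s) are
declared synthetic fixtures, not measured values. The bead-model R_h uses
the Kirkwood double-sum approximation, which is 5–10% from full bead-shell
hydrodynamics — adequate for monomer-vs-dimer discrimination, not for
absolute hydration studies.

## Evolutionary fitness

Filtering drops sequences with gap fraction strictly above 25%, then
greedily removes sequences within 95% identity of an already-kept sequence
(identity = matches over mutually non-gap columns), in input order —
deterministic, Hobohm-1 style, since the clustering method behind such
thresholds is typically unstated. Sequence weighting by inverse
neighborhood counts is off by default for the same reason, with an option
to enable it left to downstream code.

The generative model is a variational autoencoder over one-hot encoded
alignments: tanh MLP encoder to a Gaussian latent (reparameterized),
mirrored decoder to per-position softmax, trained full-batch with Adam on
the ELBO (categorical reconstruction + KL to a standard-normal prior).
It is implemented directly in matrix algebra; training is reproducible
given the architecture seed. The scaled-down defaults (one hidden layer of
64, latent 50→8, 200 epochs) are the test surface; family-scale settings
(encoder 2000/1000/300, latent ~50, tens of thousands of epochs) are
accepted but impractically slow in pure R — the latent dimension default
is a package choice, as the number is typically unstated.

Mutation scores are −[log p(mutant) − log p(WT)], each log-likelihood
estimated by importance-weighted posterior sampling (default 2000 draws);
mutant and WT share the same posterior draws (common random numbers), which
cancels most sampling noise, and a mutation to the identical residue is 0
by construction. Only the *ordering* and sign convention of such scores
(lower = fitter) are meaningful across models; absolute values depend on
the training corpus.

Interface contacts use the 5.5 Å any-heavy-atom rule with a spatial
binning grid of cell size equal to the cutoff, verified exactly against
the O(n²) brute force in the tests. Buried surface fractions use
Shrake–Rupley sampling with 960 points per atom and a 1.4 Å probe on a
small van der Waals radius table (C/N/O/S/P, default 1.7 Å).

## Synthetic data: what passing tests show

Every generator evaluates the corresponding forward model on a stated
design and adds seeded Gaussian noise (defaults 2–3% of the dynamic range;
zero for closure tests). The generators reproduce the *statistical
structure* the fitters assume — sigmoidal transitions with baselines,
log-spaced titrations between endpoint observables, q-dependent noise on
scattering curves, conserved/coupled/free MSA columns, two-width
taylorgrams — and deliberately not instrument artifacts: detector smearing,
capillary adsorption, label photophysics, aggregation kinetics, or
inter-particle structure factors. Closure of a generator/fitter pair
therefore demonstrates correctness of the implementation and
identifiability under the stated design; it does not demonstrate
robustness to the systematic errors of real instruments.

Problem sizes in the test-suite (a few hundred beads, 40–400 q points,
MSAs of 100–250 sequences × ~20–30 columns, 100–200 fit replicates,
10 × 100 MC steps) were chosen so the full suite documents every claim in
minutes on one CPU; all scale up linearly through the exported parameters.

## Known limitations

- The SAXS form factor is residue-coarse with uniform weights: no
  explicit-atom form factors, no excluded-volume solvent term, no
  absolute-scale water calibration.
- The hydration parameterization is a weight increment, not a shell; treat
  fitted ρ_hydration as a nuisance parameter.
- The three-part decomposition of a refined structure must be supplied by
  the user (residue intervals); the package does not detect domain
  boundaries.
- The VAE is CPU-bound R; it is sized for synthetic families and method
  validation, not for training on full protein families.
- Apparent-t_m titrations are fitted with the same form as R_h titrations;
  the folding–dissociation linkage is intentionally not modeled.
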