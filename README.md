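# coldlac

Model fitting and simulation tools for the quantitative biophysics of a
cold-active, reversibly dimerizing GH2 β-galactosidase — and, more
generally, for any enzyme whose activity, stability and quaternary
structure are characterized by the same battery of experiments: initial-rate
kinetics, chemical and thermal denaturation, concentration titrations of a
hydrodynamic or stability observable, small-angle X-ray scattering (SAXS),
Taylor dispersion sizing (FIDA), and evolutionary analysis of interface
mutations.

The package is written for biophysicists and structural bioinformaticians
who need the *analysis chain* of such a study as reusable, tested code:
every fit the study performs is an exported function, every input it
consumes has a seeded synthetic generator, so the whole chain runs without
instrument data.

## What it implements

**Kinetics.** ONP extinction vs pH (Henderson–Hasselbalch), specific
activity in U/mg from absorbance slopes, the biphasic sequential-binding
rate law

    k_obs(S) = (kcat1 + kcat2·S/K2) / (1 + K1/S + S/K2),

a two-site Mg²⁺ activation ladder (rates with 0/1/2 ions bound), Eyring
analysis ln(k/T) = −ΔH‡/R·(1/T) + ln(κk_B/h) + ΔS‡/R with an optional
two-segment fit, and ionic-strength bookkeeping with phosphate speciation.

**Stability.** Two- and three-state isothermal denaturation with linear
baselines and decadic m-values (as these equations are conventionally
printed), van 't Hoff one- and two-step thermal transitions, DSF
inflection-point extraction from the smoothed first derivative, sigmoid
(A50) midpoint fits, cosolute stabilization slopes (°C/M), and refolding
recovery percentages.

**Oligomerization.** Exact monomer–dimer speciation
D = [(4M₀+K_D) − √((4M₀+K_D)² − 16M₀²)]/8, the observable map
obs(M₀) = obs_mono + (2D/M₀)(obs_dimer − obs_mono) for R_h or apparent
t_m titrations, weighted fits of K_D in log space, and a general n-mer
model (e.g. dimer→tetramer for engineered variants).

**SAXS.** Debye forward scattering of one-bead-per-residue models with a
hydration-layer weight on exposed beads, Guinier fits on a self-consistent
window, regularized indirect Fourier transformation to p(r), molar mass
from M = I(0)·N_A/(c·Δρ_m²), low-q/mid-q window summaries, reduced-χ²
fitting of scale/hydration/background, three-part rigid-body Monte Carlo
refinement with backbone restraints and clash penalties, and Kabsch
superposition RMSD.

**FIDA.** Stokes–Einstein conversions, Taylor-dispersion taylorgram
simulation (σ² = R_c²t_R/24D), two-species fits with the label radius
locked (0.6 nm), the Kirkwood bead-model R_h predictor, and denatured-chain
power-law scaling (2.21·N^0.57 Å).

**Evolutionary fitness.** MSA filtering (gap fraction > 25% discarded,
≥ 95% identity deduplicated), one-hot encoding, a small variational
autoencoder trained by ELBO maximization, importance-weighted mutation
scores −[log p(mutant) − log p(WT)] (lower = fitter), heavy-atom interface
contacts at a 5.5 Å cutoff (grid-accelerated, brute-force verified),
interface mutation ranking, and Shrake–Rupley buried-surface fractions.

**Synthetic data.** Seeded generators for every input above, with presets
named after the study conditions (`"ailac-wt-fida"`, `"ailac-dsf"`,
`"eclac-thermal"`, `"ailac-far-uv"`, …). Zero-noise generation is exactly
on-model, so every generator/fitter pair closes to 10⁻⁴ relative.

## Worked example

Fit the monomer–dimer model to a (noisy, synthetic) hydrodynamic-radius
titration and run an Eyring analysis:

```r
library(coldlac)

titr <- gen_association_titration(preset = "ailac-wt-fida",
                                  noise_sd = 0.05, seed = 42)
fit <- fit_association(titr)
print(fit)
#> coldlac fit (3 parameters, 12 points)
#>             logKD          obs_mono         obs_dimer
#> "-6.47643 ± 0.12"  "4.41057 ± 0.08" "5.89014 ± 0.032"
#> reduced chi-squared: 0.7593

p <- association_params(fit)
sprintf("KD = %.2f +/- %.2f uM", p$KD * 1e6, p$KD_se * 1e6)
#> "KD = 0.33 +/- 0.09 uM"

e <- gen_kinetics("eyring")          # noiseless activation preset
print(eyring_fit(e$x, e$y))
#> segment 1 (283.1-298.1 K): dH_act = 8.03 +/- 2.5e-14 kcal/mol,
#>                            dS_act = 25 +/- 8.7e-14 cal/(mol K)
```

The titration fit says: across 0.032–33.5 μM total protein the labeled
species grows from ~4.4 nm (monomer) to ~5.9 nm (dimer) with a
dissociation constant of 0.33 ± 0.09 μM — dimers dominate above a few
hundred nanomolar. The Eyring fit recovers the activation enthalpy
(8.03 kcal/mol) and entropy (25 cal/(mol·K)) used to generate the rates.

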