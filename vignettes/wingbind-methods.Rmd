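---
title: "Methods: models, parameters and design choices in wingbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in wingbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbind)
```

wingbind re-implements, as one tested pipeline, the quantitative analyses
used to characterize a small (76-residue) winged helix–turn–helix (wHTH)
transcription factor and its operator DNA: operator-motif architecture,
secondary structure from chemical shifts, the DNA-binding surface from
chemical shift perturbation, monomeric hydrodynamics from ¹⁵N relaxation,
sequential 2:1 binding energetics from ITC, and the stoichiometry /
stability / cooperativity titrations. A synthetic-data generator emulates
every input type, so the whole pipeline is exercised without downloads.
This vignette records the models, the tunable parameters and the design
decisions taken where the methods literature leaves genuine freedom.

## Operator motifs and promoter coordinates

The operator is a 15-nt paired motif, TTAA-N₇-TTAA. `scan_motif()` reports
all occurrences (overlaps allowed) in 1-based inclusive coordinates; TTAA
is self-reverse-complementary, so one-strand scanning covers both strands,
while non-palindromic motifs are additionally scanned on the reverse
strand. `find_paired_sites()` enumerates **all** spacer-exact pairs rather
than greedily consuming hits, so nested or overlapping operators are never
silently lost.

Promoter coordinates use the biology convention with no position 0
(…−2, −1, +1, +2…). `tss_span_length()` therefore subtracts one base when a
span crosses the transcription start site: (−120, +17) is 137 bp, and
(−1, +1) is 2 bp.

`direct_repeat_check()` operationalizes "almost perfect direct repeat" as:
two 8-nt windows holding the TTAA anchors at the same relative offset match
with ≤ 2 mismatches. The window length and tolerance are heuristic
constants chosen to separate the repeat-bearing site (one mismatch over
8 nt) from random sequence; they are documented, not derived.

## Chemical shift index (CSI) secondary structure

Secondary shifts are Δδ = observed − random-coil(residue type), using a
frozen Wishart-style random-coil table embedded in the package
(`random_coil_shifts()`; one version, Cα/Hα for the index, plus nominal
amide values used only by the generator). Index thresholds are the
classical ones: Cα ±0.7 ppm, Hα ±0.1 ppm; helix is the (+1, −1) pattern,
strand the (−1, +1) pattern. Because the upstream study states only that
CSI was used, two consensus modes are exposed: the default smooths the
per-residue call by majority over a 3-residue window; `"strict"` requires
the per-residue AND. Minimum run lengths are 4 (helix) and 3 (strand);
shorter runs become coil. Neither mode is asserted to be "the" original
variant.

The synthetic fold is αβααββα over boundaries 8–18, 21–23, 24–31, 35–48,
51–58, 61–68 and 72–76. The last segment deserves a note: the C-terminal
72–76 stretch is reported in the source system as a helical *propensity*
rather than a defined helix, but the seven-element topology string requires
a fourth α; the generator therefore plants it as a (short) helix so the
generator→caller round trip closes. Generator offsets are +2.5/−0.25 ppm
(helix Cα/Hα) and −2.0/+0.35 ppm (strand) — comfortably beyond the index
thresholds, so zero-noise recovery is exact, and recovery remains ≥ 95%
at realistic noise (σ = 0.3 ppm Cα, 0.03 ppm Hα; verified over 100 seeds
in the test suite).

## Chemical shift perturbation (CSP) interface mapping

The combined amide perturbation is the weighted Euclidean form

$$\Delta\delta_{HN,av} = \sqrt{\tfrac{1}{2}\left[(\Delta\delta_H)^2 +
(\Delta\delta_N/5)^2\right]}$$

computed per matched residue between free and bound peak lists. The
interface set is the union of three criteria: (i) Δδ above the global
mean + 1 SD of all matched residues (no trimming — the reference lines of
a standard CSP bar plot), (ii) relative intensity reduction
1 − I_bound/I_free exceeding the mean reduction + 1 SD (the population for
"over one standard deviation" is not fixed by the method description; all
matched residues is the documented choice), and (iii) peaks present free
but lost bound (broadened away — maximal intensity loss is binding
evidence). Intensity ratios are median-normalized first, so a global
rescaling of either spectrum cannot move the interface. When all combined
shifts are numerically identical (SD ≈ 0 up to floating-point noise) the
classifier warns and falls back to mean-only classes.

## ¹⁵N relaxation, τc and hydrodynamic radius

Decays are fit per residue as I(t) = I₀e^(−Rt) by Levenberg–Marquardt
started from the log-linear slope; non-decaying series are flagged, not
fit. The forward model for rates is the rigid isotropic rotor with
dipolar + CSA relaxation, J(ω) = (2/5)τc/(1+(ωτc)²), and frozen physical
constants r_NH = 1.02 Å, Δσ(¹⁵N) = −160 ppm, CODATA gyromagnetic ratios.
These constants are the conventional fixed choices of backbone relaxation
analysis.

Residue filtering is two-stage. Coarse: drop fit failures, relative rate
errors > 20%, and user-marked flexible termini. Fine: iteratively drop
residues whose R2/R1 deviates from the current mean by more than 1 SD.
A literal fixed point of the 1-SD rule does not exist for Gaussian scatter
(iterating it trims any finite sample toward a degenerate floor), so
"until stable" is implemented as: stop when the trimmed mean changes by
less than 1%. Pure noise then costs one trimming pass, while genuine
outliers (exchange-broadened residues, mobile loops) keep being shed.

τc is recovered per residue from the standard slow-tumbling inversion
τc = (1/(4π·ν_N))·√(6·R2/R1 − 7) and averaged over passing residues; the
inversion is an approximation of the full spectral-density model and
reproduces a forward-simulated 8.4 ns at 600 MHz to −1.2% (within the
documented 5% band across 3–15 ns and 500–800 MHz). Residues with
R2/R1 < 7/6 (imaginary radicand) are skipped with a warning.

The hydrodynamic radius uses the Stokes–Einstein–Debye sphere,
r_H = (3k_BTτc/4πη)^{1/3}, with defaults T = 298.15 K and
η = 8.90×10⁻⁴ Pa·s (water at 25°C, overridable). With τc = 8.4 ns this
gives 2.10 nm — the monomer-sized radius that anchors the oligomeric-state
conclusion.

## Sequential two-site ITC model

DNA is the two-site macromolecule (cell), protein the titrant (syringe),
matching the experiment's roles; K₁, K₂ are stepwise site association
constants. Free titrant is found by bracketed root finding on the coupled
mass balances (uniroot on [0, P_tot], the bracket where the balance is
guaranteed to change sign, followed by Newton polishing to machine
precision); species conservation holds to 10⁻⁹ relative and the solver is
tested against a brute-force grid oracle.

Heats use the cumulative content Q_i = V₀([PD]ᵢΔH₁ + [P₂D]ᵢ(ΔH₁+ΔH₂)) and
the displaced-volume correction
q_i = Q_i − Q_{i−1} + (dV_i/V₀)(Q_i+Q_{i−1})/2. Cell totals follow the
continuous-perfusion dilution convention, D_tot = D₀e^{−v/V₀},
P_tot = P_syr(1−e^{−v/V₀}). Fitting minimizes Σ(q_obs − q_model)² in
log-Kd space (positivity) with Levenberg–Marquardt from five jittered
starts, guarding against the shallow second-site direction. Temperature
defaults to 295.15 K (22°C).

Defaults plant Kd₁ = 40 nM with ΔH₁ = +10 kcal/mol (endothermic,
entropy-driven) and Kd₂ = 5 µM with ΔH₂ = −5 kcal/mol; the second site is
only constrained to "micromolar and exothermic" by the source data, and
these values reproduce the characteristic endothermic-early /
exothermic-late isotherm with a single zero crossing. Generator noise is
i.i.d. Gaussian with SD a fraction (default 2%) of the largest heat — the
constant-baseline-noise model of a real calorimeter. A caveat the test
suite documents deliberately: at c = D_tot/Kd₁ = 250 the first-site Kd is
weakly identified, so under noise the fitted Kd₁ scatters widely
(median |log error| ≈ 0.5 at 5% noise in this package's own simulation
study) even though noiseless recovery is exact to < 1%. This is a property
of the experiment geometry, not of the optimizer — at the reported optimum
the residual norm is below that of the generating truth.

`thermo_convert()` applies ΔG = −RT ln K and ΔS = (ΔH − ΔG)/T with
R = 1.98720 cal mol⁻¹ K⁻¹; Kd 40 nM with ΔH +10 kcal/mol at 22°C gives
ΔS ≈ +68 cal mol⁻¹ K⁻¹.

## Titration-style analyses

* **Breakpoint stoichiometry** fits the continuous two-segment model
  S(r) = a + br + c·max(r−x₀, 0), profiling x₀ (coarse grid plus local
  refinement; the linear coefficients are closed-form at each candidate).
  A break is only reported when the slope change is resolvable above the
  residual noise (|c| > 3× a noise-derived slope scale); a straight line
  returns "no breakpoint". x₀ is invariant to affine transforms of the
  signal axis. The 2:1 endpoint is read from the source system
  qualitatively; the two-segment model is this package's
  operationalization and is validated on synthetic data only.
* **Emission maxima** are located by parabolic interpolation through the
  grid maximum and its neighbors; an edge maximum is returned as-is with a
  warning. The planted blue shift is 355 → 350 nm.
* **Melting temperature** is the maximum of the smoothed derivative
  dA₂₆₀/dT (central differences, 3-point moving average, parabolic
  refinement). A two-state sigmoid's derivative is symmetric, so noiseless
  midpoints are recovered exactly on the 0.5°C grid; under noise the
  derivative estimator is the dominant error source (≈ ±2°C at 1%
  amplitude noise). ΔTm = Tm(bound) − Tm(free), planted at +10°C.
* **Hill cooperativity** fits f(c) = cⁿ/(Kⁿ+cⁿ) by Levenberg–Marquardt
  started from the linearized Hill plot, on fraction-bound values at the
  gel-titration concentrations (3.2–32.4 µM). The gel densitometry that
  produces fraction-bound values is upstream of the package; the generator
  emits fractions directly. Planted n = 4.5, K½ = 12 µM.

## Ensemble coordinate statistics

Superposition is the SVD-based optimal rigid transform with determinant
correction (reflections rejected); it is verified in the tests against an
independent Euler-angle optimization oracle. Ensemble precision is the
iterative mean convention: superpose all models on the current mean,
recompute the mean, repeat until the mean RMSD changes by < 10⁻⁶ Å, then
report the average over models of the RMSD to the converged mean (whether
the source figures used a single global superposition instead is not
stated; the iterative convention is documented here). Backbone atoms are
{N, Cα, C′, O}; "heavy" is all non-hydrogen; both residue windows used in
the source statistics (8–68 and 5–69) are plain parameters.

Backbone φ/ψ are standard torsions in (−180°, 180°], sign-checked against
an established structural-biology package; termini yield absent values.
The optional region label ("favored_like"/"other") is a deliberately
simplified descriptive polygon — validation-grade Ramachandran region maps
are out of scope.

## Synthetic-data generator

One `synth_spec()` object holds every planted parameter; its defaults are
the study conditions themselves (τc 8.4 ns at 600 MHz; Kd₁ 40 nM /
+10 kcal/mol; break 2.0; ΔTm +10°C; Hill 4.5; 24-residue interface;
operators at TSS spans (−92,−78) and (−28,−14) with the direct-repeat
site A context). Where the source prints no value, one realistic choice
was made and frozen: Kd₂/ΔH₂ as above, Hill K½ = 12 µM (centered in the
concentration window), melting midpoints 55/65°C, noise defaults of 2%
(relaxation intensities), 2% of the largest heat (ITC), 1% (optical
curves), 0.1/0.01 ppm (Cα/Hα shifts) and 0.005/0.025 ppm (amide H/N peak
positions). All noise is i.i.d. Gaussian on the measured quantity — the
simplest model consistent with the least-squares analyses downstream.

Determinism: the single spec seed derives one deterministic sub-stream per
data type; generators restore the caller's RNG state, and identical
(spec, seed) gives bit-identical outputs. The synthetic amino-acid
sequence excludes proline (every residue then has an amide), and the
generator is a stand-in: it does not simulate lineshapes, spectral
overlap, baseline drift, gel images, or anisotropic tumbling, so passing
tests demonstrate correctness of the analysis chain, not robustness to
those real-data pathologies. The promoter background is rejection-screened
so exactly the planted operator pairs exist, making round-trip counts
exact.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the sizes the analyses
were designed around: 76 residues, 54 rigid + 5 flexible relaxation
series with 8 delays per experiment, 20-injection thermograms, 121-point
melting curves, 12-point titrations, 9-point binding curves; simulation
studies use 50–100 seeds. Root finding is bracketed with Newton polish;
nonlinear fits are Levenberg–Marquardt with analytic-free numerics,
log-parameterized where positivity matters, and multi-started where a
direction is known to be shallow. Ties and degenerate inputs error or
warn loudly (flat melting curves, all-identical CSPs, collinear
coordinate sets, delay designs without distinct delays) rather than
returning plausible numbers.

## Known limitations

* Anisotropic diffusion, model-free order parameters and exchange terms
  are out of scope; τc assumes a rigid isotropic rotor even though an
  elongated fold tumbles anisotropically (the source analysis makes the
  same simplification).
* The sequential ITC model has no independent-sites or competitive
  alternative, and no error-in-concentration treatment.
* Kd₁ under realistic heat noise is weakly identified at this experiment
  geometry (see above); report intervals, not point estimates, when using
  noisy thermograms.
* The CSI caller is a threshold/consensus method; probabilistic
  secondary-structure estimation is not attempted.
* The Ramachandran label is descriptive only.
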