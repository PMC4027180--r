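# wingbind

Quantitative analyses for the solution-state characterization of a small
winged helix–turn–helix (wHTH) transcription factor and its operator DNA.
The package is aimed at structural biologists and biophysicists who need
the standard battery of protein–DNA measurements as reproducible, tested
code rather than one-off spreadsheets:

* **Operator motifs** — scanning for the 15-nt TTAA-N₇-TTAA paired motif,
  direct-repeat detection, and promoter coordinate arithmetic under the
  no-zero TSS convention.
* **Secondary structure** — chemical shift index (CSI) calls from backbone
  Cα/Hα shifts against an embedded random-coil reference, with segment and
  topology reporting (e.g. `αβααββα`).
* **Binding interface** — chemical shift perturbation (CSP) mapping from
  free/bound HSQC peak lists using
  ΔδHN_av = √[(Δδ_H² + (Δδ_N/5)²)/2], intensity-reduction flags and
  broadened-away peaks.
* **Hydrodynamics** — ¹⁵N R₁/R₂ decay fitting, coarse/fine residue
  filtering, rotational correlation time from
  τc = (1/4πν_N)·√(6·R₂/R₁ − 7), and the hydrodynamic radius from the
  Stokes–Einstein–Debye relation r_H = (3k_BTτc/4πη)^⅓.
* **Binding energetics** — a sequential two-site ITC model (simulation and
  Levenberg–Marquardt fitting) with ΔG/ΔS decomposition.
* **Titrations** — two-segment breakpoint stoichiometry, melting-curve Tm
  and ΔTm, tryptophan emission blue shift, and Hill cooperativity fits.
* **Ensemble QC** — Kabsch superposition, iterative RMSD-to-mean ensemble
  precision, and backbone φ/ψ dihedrals from multi-MODEL PDB files.

A deterministic synthetic-data generator (`synth_spec()` and the `gen_*`
functions) emulates every input type — shift tables, peak lists,
relaxation decays, thermograms, titration/melting/EMSA curves, promoter
sequences — so the entire pipeline runs and is tested without any
downloads. The `analysis/` directory contains numbered driver scripts that
generate a bundle and run each analysis stage, writing tables under
`results/`.

## Worked example

```r
library(wingbind)

# operator architecture of a printed gel-shift probe
probe <- dna_sequence("GGAAACAGTATTAATAAAGTGTTAATCCTATTACCC", "probe_A")
find_paired_sites(probe)
#>   first_start first_end second_start second_end spacer span center_distance
#> 1          11        14           22         25      7   15              11

tss_span_length(-120, 17)   # the classic promoter fragment
#> [1] 137

# noiseless synthetic study: relaxation -> tumbling -> radius
spec <- synth_spec(seed = 3, noise = list(shift_ca = 0, shift_ha = 0,
  peak_h = 0, peak_n = 0, peak_i = 0, relax = 0, itc = 0, curve = 0))
res <- relax_pipeline(gen_relaxation_series(spec))
c(tau_c = res$tauc$tau_c, n = res$tauc$n_residues, rh_nm = res$rh_nm)
#>    tau_c        n    rh_nm
#> 8.298751 54.00000  2.09259

# sequential two-site ITC: simulate, then refit from a distant start
sim <- gen_itc_thermogram(spec)
fit <- fit_sequential(sim$thermogram, sim$design, seq_params(1e-7, 1e-6, 5, -2))
c(kd1_nM = fit$params$kd1 * 1e9, dh1 = fit$params$dh1)
#> kd1_nM    dh1
#>     40     10
```

The tumbling values read: 54 rigid residues pass the filters, their mean
R₂/R₁ inverts to τc = 8.30 ns, and the Stokes–Einstein–Debye sphere at
25°C water viscosity gives a 2.09 nm radius — a monomer for a ~10 kDa
protein. The ITC refit recovers the planted site-1 constants (Kd 40 nM,
ΔH +10 kcal/mol — an endothermic, entropy-driven first binding event)
from the biphasic endothermic→exothermic isotherm.

To run the whole study end to end:

```sh
Rscript analysis/01_simulate_inputs.R   # writes results/synth/
Rscript analysis/02_operator_motifs.R
# ... through 08_report.R
```

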