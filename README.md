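# saxsphase

Solution SAXS analysis of nucleoprotein assemblies — shape invariants,
phase classification, lamellar-stack Caillé fitting, pair-distance
distributions, coarse bead-model building and Debye-formula ensemble
fitting.

## The problem

HU, a conserved bacterial nucleoid-associated protein, binds DNA
non-specifically and can either coat a duplex as a **filament** or glue
parallel duplexes into ordered **lamellar bundles**, depending on pH and
ionic strength. These states are distinguishable from one-dimensional
SAXS curves *I(q)*:

* a lamellar phase decays as *I ∝ q⁻²* at low *q* and shows Bragg peaks
  at *q\* = 2π/d* (DNA–DNA spacings of 42, 60 or 70 Å across the
  pH × NaCl phase diagram);
* an HU-coated filament decays as a rod, *I ∝ q⁻¹*, with no peak and a
  pair-distance distribution ending at the duplex length (~270 Å for
  80 bp);
* aggregates decay steeply and featurelessly.

`saxsphase` implements the complete desk-side chain for such data:

| stage | functions |
|---|---|
| profile / model I/O | `read_profile`, `write_profile`, `read_model`, `write_model` |
| shape invariants | `guinier_fit` (ln *I* = ln *I₀* − *q²Rg²*/3, *qRg* ≤ 1.3), `cross_section_rg`, `porod_volume`, `volume_of_correlation`, `normalize_pr` |
| phase calls | `fit_power_law`, `detect_peaks`, `bragg_spacing`, `classify_phase` |
| lamellar model | `caille_structure_factor`, `lamellar_form_factor`, `lamellar_intensity` (*I = 2π P S / q²δ*), `fit_lamellar` |
| real space | `pr_from_model`, `ift`, `rg_from_pr`, `shoulder_positions` |
| model building | `build_bdna`, `place_hu`, `build_bundle`, `build_pool` |
| Debye / ensembles | `debye_intensity`, `fit_scale`, `minimal_ensemble` |
| synthetic data | `simulate_profile`, `scenario_profile`, `saxs_scenarios` |
| shell entry point | `saxs_cli` (wrapper script in `inst/cli/saxsphase`) |

The lamellar intensity is the stacked-sheet Caillé model
*I(q) = 2π P(q) S(q) / (q²δ)* with the uniform-slab form factor
*P(q) = [2 sin(qδ/2)/q]²* and

*S(q) = 1 + 2 Σₙ₌₁^{N−1} (1 − n/N) cos(qdn) exp(−q²d²η[ln(πn)+γ_E]/4π²)*,

η the Caillé disorder parameter (bounded at 0.8 in fits). Bead models
are scored with the exact Debye sum
*I(q) = Σᵢⱼ wᵢwⱼ sin(qrᵢⱼ)/(qrᵢⱼ)* and combined by non-negative least
squares into the smallest ensemble that still fits the data.

## Worked example

Simulate the pH 5.5 / 100 mM NaCl condition of the phase diagram,
classify it, and fit the lamellar model:

```r
library(saxsphase)
sim <- scenario_profile("pH5.5_100mM")
classify_phase(sim$profile)
#> Phase call: lamellar (exponent -1.74 +/- 0.09 over q in [0.01195, 0.08058])
#>   peaks:
#>     q* = 0.0895 1/A  d = 70.2 A  prominence 3.51
#>     q* = 0.1794 1/A  d = 35.0 A  prominence 1.97
fit_lamellar(sim$profile)
#> Lamellar Caille fit: reduced chi2 = 0.9134
#> Lamellar-stack model: d = 70.00 A, delta = 19.99 A, N = 20, eta = 0.100, poly = 0.050
```

The first-order peak sits at *q\** = 0.0895 Å⁻¹, i.e. a 70 Å DNA–DNA
repeat; the second entry is its second-order reflection (35 Å); the full
Caillé fit recovers the generating spacing to 0.01 Å at reduced χ² ≈ 0.9.

The same chain on built models:

```r
duplex <- build_bdna(build_spec(n_bp = 80))
pr_from_model(duplex)
#> P(r): 201 grid points, Dmax = 269.3 A, Rg = 78.87 A
classify_phase(debye_intensity(place_hu(duplex, mode = "saturated"),
                               default_qgrid()))
#> Phase call: filament (exponent -1.14 +/- 0.01 over q in [0.01195, 0.1])
```

An ideal 80-bp B-DNA duplex spans ~269 Å; saturating it with HU-dimer
blobs (one per 9 bp) yields the rod-like *q⁻¹* profile of a
nucleoprotein filament.

From a shell, the same stages chain through the CLI wrapper:

```sh
Rscript inst/cli/saxsphase simulate --scenario pH4.5_150mM -o prof.dat
Rscript inst/cli/saxsphase pipeline -i prof.dat --outdir out/
```

`pipeline` classifies, then routes lamellar profiles to the Caillé fit
and everything else to ensemble fitting against a default duplex pool,
writing JSON reports.

See the methods vignette (`vignettes/saxs-phase-analysis.Rmd`) for the
models, the numerical choices and their rationale, and known
limitations.

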