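# memtopo

Quantitative analysis of how monotopic hairpin membrane proteins are
positioned inside bilayer versus lipid-droplet monolayer membranes.

Hairpin proteins (e.g. the ER/lipid-droplet protein UBXD8) bury a
hydrophobic segment that enters and exits the membrane on the same side.
Whether such a protein stands deeply inserted in a closed "V" or lies flat
in an open, shallow pose decides whether it can partition from the ER
bilayer to the lipid-droplet monolayer. `memtopo` implements the four
quantitative readouts used to make that call, each validated against
synthetic data with known ground truth:

* **PEGylation topology mapping** — per-residue relative PEGylation
  efficiency from gel-band intensities,
  `100 · f(native) / f(detergent)` with `f = (PEG1+PEG2)/(PEG0+PEG1+PEG2)`,
  replicate aggregation, exposed/interface/embedded classification,
  embedded-segment extraction and α-helical periodicity scoring.
* **cwEPR power-saturation depth analysis** — fits of
  `A = I·√P·[1 + (2^(1/ε) − 1)·P/P_1/2]^(−ε)` per relaxant condition
  (N₂, O₂, NiEDDA) and the membrane depth parameter
  `Φ = ln[ΔP_1/2(O₂) / ΔP_1/2(NiEDDA)]`
  with embedded / interface / exposed calls.
* **Membrane geometry** — per-residue insertion depth relative to the
  cytoplasmic phosphate plane, principal-axis tilt, arm-tip Cα distance,
  V-opening angle, and a deep-V / open-shallow classifier (PDB, GRO or
  per-atom CSV input).
* **WHAM free-energy estimation** — a from-scratch self-consistent solver
  for 1-D umbrella-sampling potentials of mean force, with
  window-resampling bootstrap SEM.

A synthetic-data module (`accessibility_spec()`/`gen_accessibility_profile()`,
`gen_saturation_curve()`, `gen_hairpin_structure()`, `gen_umbrella_samples()`,
`gen_crosslink_lanes()`) generates every input with known ground truth, and
`run_pipeline()` chains everything into a reproducible two-context run with
a manifest of seeds, parameters and output checksums.

## Worked example

Fit a power-saturation curve and compute a depth parameter:

```r
library(memtopo)

curve <- gen_saturation_curve(I = 1, P_half = 12, epsilon = 1.5,
                              site = "L118", condition = "O2")
fit <- fit_saturation(curve)
fit
#> <saturation_fit>
#>   I = 1  P_1/2 = 12 mW  epsilon = 1.500 (free)  converged: TRUE

depth_parameter(10, 4, 2, site = "L118")
#> # A tibble: 1 × 6
#>   site  dP_oxygen dP_niedda   phi call     reason
#>   <chr>     <dbl>     <dbl> <dbl> <chr>    <chr>
#> 1 L118          8         2  1.39 embedded <NA>
```

`Φ = ln(8/2) ≈ 1.39 > 0.3`, so the site is called membrane-embedded.

Run the full demo pipeline on the calibrated fixtures:

```r
report <- run_pipeline(list(out_dir = "run1", verbosity = 0))
report
#> <topology_report>
#>   bilayer:
#>     embedded segment: 94-122 (29 residues)
#>     EPR hairpin signature: TRUE
#>     geometry: deep_V (kink depth 2.00 nm, tilt 80.0 deg)
#>     crosslinking (normalized): 100%
#>   monolayer:
#>     embedded segment: 107-108 (2 residues)
#>     EPR hairpin signature: TRUE
#>     geometry: open_shallow (kink depth 0.00 nm, tilt 30.0 deg)
#>     crosslinking (normalized): 50%
#>   concordance:
#>     bilayer: 90% over 10 shared sites
#>     monolayer: 100% over 10 shared sites
```

The bilayer context recovers a contiguous 29-residue embedded hairpin
(residues 94–122) standing steeply (tilt 80°) with its kink 2 nm below the
phosphate plane; the monolayer context shows a fragmented, periodically
exposed core lying flat (tilt 30°) at the membrane surface, with
intramolecular crosslinking reduced to half of the bilayer level — the
quantitative signature of the deep-V to open-shallow transition.

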