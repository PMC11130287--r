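---
title: "Methods: quantifying the intramembrane positioning of hairpin proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the intramembrane positioning of hairpin proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtopo)
```

## The scientific question

Monotopic hairpin proteins such as UBXD8 insert a hydrophobic segment into a
membrane in a loop-like fashion, entering and exiting on the same side. Many
of them live in two very different membranes over their lifetime: the
phospholipid **bilayer** of the endoplasmic reticulum and the phospholipid
**monolayer** surrounding a lipid droplet. `memtopo` implements the
quantitative machinery used to decide *how* such a hairpin sits in each
membrane — how deep it penetrates, how steeply it stands, and how open its
two helical arms are — from four independent kinds of evidence:

1. **Cysteine-accessibility (PEGylation) topology mapping**: per-residue
   gel-band intensities quantify which positions a thiol-reactive PEG label
   can reach.
2. **cwEPR power saturation**: per-site saturation curves under three
   relaxant atmospheres yield a membrane depth parameter $\Phi$.
3. **Structure-based geometry**: insertion depth, tilt, arm-tip distance and
   V-opening angle measured on coordinates relative to the phosphate
   headgroup plane.
4. **Umbrella-sampling free energies**: a from-scratch WHAM estimator with
   window-bootstrap errors quantifies the cost of moving between
   conformations along a reaction coordinate.

Every input the pipeline consumes can be generated synthetically with known
ground truth, so each estimator is validated end to end against the
parameters that produced its data.

## PEGylation topology mapping

For one residue and replicate, the assay produces three gel lanes: a no-label
control, the native membrane lane, and a detergent-solubilised positive
control. Each lane resolves into an unshifted band (`PEG0`) and shifted bands
(`PEG1`, `PEG2`). The lane-level labelled fraction is

$$f = \frac{\mathrm{PEG1} + \mathrm{PEG2}}
{\mathrm{PEG0} + \mathrm{PEG1} + \mathrm{PEG2}},$$

and the **relative PEGylation efficiency** of a residue is
$100 \cdot f_\mathrm{native} / f_\mathrm{detergent}$, clipped to
$[0, 100]$ — the detergent lane defines the maximum achievable labelling and
is set to 100 %. Clipping is a deliberate choice: values above 100 % can only
arise from densitometry noise, and an accessibility cannot meaningfully
exceed its own positive control.

**Reliability rule.** Some positions never label efficiently even after
solubilisation (their local secondary structure blocks the maleimide). A
detergent-lane fraction at or below `control_floor = 0.2` flags the residue
`low_positive_control` and withholds its value rather than reporting a
wildly amplified ratio. The floor itself is a package default; the
qualitative rule (treat a failed positive control as missing, not as
evidence) is what matters.

**Classification.** Residues are labelled `exposed` at $\geq 75\,\%$,
`embedded` at $\leq 25\,\%$, `interface` in between. The symmetric quartile
thresholds separate the fixture regimes cleanly (true values are ~100 %,
~50 %, ~0–10 %) and are exposed as arguments for real data, where the
separation may be weaker. Unreliable residues are **bridged**: they inherit
the label of their flanking reliable residues when both flanks agree
(default on, because positions failing their positive control typically sit
*inside* the embedded core, and calling them `interface` would artificially
split the segment). The embedded segment is the longest contiguous embedded
run; interface residues always break a run.

**Periodicity.** A hairpin lying at the membrane surface exposes one helix
face per turn, so its accessibility profile oscillates with the α-helical
pitch. `periodicity_score()` takes the mean-subtracted discrete Fourier
transform of a profile segment and reports the dominant period over periods
in $[2, n/2]$ residues and its share of non-DC power. At segment length 29
the DFT bins nearest the helical pitch are $29/8 = 3.625$ and $29/9 ~ 3.2$,
so a 3.6-residue periodicity is recovered as a dominant period in roughly
$[3.2, 4.0]$.

## cwEPR power saturation and the depth parameter

The peak-to-peak amplitude of the central EPR line follows

$$A(P) = I \sqrt{P}\left[1 + \left(2^{1/\varepsilon} - 1\right)
\frac{P}{P_{1/2}}\right]^{-\varepsilon},$$

with scaling factor $I$, half-saturation power $P_{1/2}$ and homogeneity
exponent $\varepsilon$ (1.5 for homogeneous, 0.5 for inhomogeneous
saturation). At $P = P_{1/2}$ the bracket equals $2^{1/\varepsilon}$, so the
amplitude is exactly half the unsaturated extrapolation $I\sqrt{P}$ — a
closed-form identity the tests assert for every $\varepsilon$.

Fits run on amplitude versus power (plotting against $\sqrt{P}$ is purely a
display convention) via Levenberg–Marquardt with box bounds
$\varepsilon \in [0.5, 1.5]$. Initial guesses are derived from the data:
$I$ from the median of $A/\sqrt P$ at the three lowest powers, $P_{1/2}$
from where that ratio first halves (geometric mean of the power range as
fallback), $\varepsilon$ starting at 1.0. Standard errors come from the
Gauss–Newton curvature of the residual surface; they are reported but not
used in any call. Optimiser failure sets `converged = FALSE` instead of
raising. $P_{1/2}$ is taken as the fitted model parameter; extrapolating
the linear low-power part of the curve is a legitimate alternative
definition of the unsaturated amplitude, but the fit parameter is
self-consistent with the model and needs no extra heuristic.

Powers are usually recorded as attenuation: $P = P_0 \cdot 10^{-\mathrm{dB}/10}$
with a default source power of 200 mW — the unique value under which the
standard 2–30 dB grid spans exactly 126.2 down to 0.2 mW.

The **membrane depth parameter** contrasts the accessibility increments of a
lipid-soluble relaxant (O$_2$, enriched in the membrane core) and a
water-soluble one (NiEDDA, excluded from it), each over the nitrogen
control:

$$\Phi = \ln\!\left[\frac{P_{1/2}(\mathrm{O_2}) - P_{1/2}(\mathrm{N_2})}
{P_{1/2}(\mathrm{NiEDDA}) - P_{1/2}(\mathrm{N_2})}\right].$$

Positive $\Phi$ means membrane-embedded, negative means solvent-exposed,
and $|\Phi| \leq 0.3$ is called `interface` (the literature says only
"close to 0"; the band half-width is configurable). A non-positive
increment in either numerator or denominator — physically, a relaxant that
failed to increase the relaxation rate — yields `indeterminate` rather than
a complex logarithm. A monotopic hairpin shows a characteristic signature
in the per-site profile: negative-$\Phi$ flanks around a positive-$\Phi$
core, which `phi_depth_profile()` flags.

## Membrane geometry

Coordinates are accepted as PDB, GRO or a plain per-atom CSV, stored in
Angstrom, with depth observables reported in nm. The reference plane is the
arithmetic mean $z$ of the **cytoplasmic-leaflet phosphate atoms** — a
plane, not a point, so depths are invariant under in-plane translation and
rotation. When leaflets are not annotated they are split at the global
P-atom midplane, the leaflet nearer the peptide being cytoplasmic; a P slab
thinner than 1 nm is treated as a single (monolayer) leaflet.

Per-residue depth is the C$\alpha$ offset from that plane, **signed**,
positive into the membrane; the insertion direction is inferred from which
side of the plane holds the peptide's mean C$\alpha$, so files oriented
with the membrane above or below z = 0 measure identically. (Reporting
magnitudes once a residue crosses the plane would be the alternative; the
signed convention preserves the distinction between solvent- and
core-facing excursions.)

Tilt is the angle between the first principal axis of the selected
C$\alpha$ set and the membrane *plane* (90° = perpendicular): a deeply
inserted, nearly vertical hairpin tilts near 80°, a surface-lying one near
30°, which is only consistent with a plane reference. The V-opening angle
is measured at the kink between the two arm principal axes, each oriented
away from the kink. The conformation call is threshold-based: `deep_V`
requires kink depth $\geq 1$ nm *and* tilt $\geq 55°$; `open_shallow`
requires depth $\leq 0.5$ nm *and* tilt $\leq 45°$; anything else is
`ambiguous`. Multi-frame input is averaged over the trailing window of
frames (default last 25 %), mirroring the convention of analysing only the
equilibrated tail of a trajectory.

## WHAM free-energy estimation

Umbrella windows at centers $\xi_i$ with harmonic biases
$U_i(\xi) = \tfrac{1}{2} k_i (\xi - \xi_i)^2$ are combined by
self-consistent iteration of the coupled equations

$$P(b) = \frac{\sum_i n_i(b)}{\sum_i N_i\, e^{(f_i - U_i(b))/kT}},
\qquad
f_i = -kT \ln \sum_b P(b)\, e^{-U_i(b)/kT},$$

until $\max_i |\Delta f_i| < 10^{-7}\, kT$ (at most $10^5$ iterations,
$f_i$ initialised to 0 — the converged profile is invariant to a constant
shift of the initialisation, which the tests assert). The free energy is
$-kT \ln P(b)$, anchored so its minimum over occupied bins is exactly 0;
empty bins are reported missing, never as 0.

Numerical choices: bin width 0.02 nm (five bins per 0.1 nm window spacing —
finer bins lose occupancy, coarser ones blur the profile); $kT$ from
temperature, default 310 K ($\approx 2.577$ kJ/mol); burn-in as a fraction
of each window's samples, default 0.4 (matching the removal of the
equilibration segment from biased simulation windows; synthetic samples are
independent, so validation uses 0). Adjacent windows must share at least
one occupied bin, otherwise the profile is withheld with a gap report
rather than silently stitching disconnected pieces.

**Bootstrap errors** resample the *set of window histograms* with
replacement (not within-window samples), re-solving WHAM per replicate; the
per-bin SD over replicates is the SEM. Replicates solve without the
overlap guard — resampling legitimately drops windows — and with a looser
stopping rule ($10^{-5}\,kT$, capped at $2\times 10^4$ iterations), since
only the replicate spread matters. Sample autocorrelation is *not*
corrected: synthetic samples are independent by construction, and users
feeding real trajectory windows should thin them first.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions the package is validated under:

* **Accessibility**: residues 80–128 (all 49 positions; the mutant library
  the assay emulates is described as 48 mutants over the same interval —
  the generator covers every position and records the discrepancy in its
  ground-truth sidecar), segment plan exposed 80–89 / interface 90–93 /
  embedded 94–122 / interface 123 / exposed 124–128, two replicates,
  multiplicative log-normal densitometry noise (noise scales with band
  intensity). The open-shallow state superimposes a sinusoid of period
  exactly 3.6 residues (canonical α-helix) on the embedded core. Residues
  102, 113, 114 get a failed positive control, exercising the reliability
  and bridging rules.
* **Saturation curves**: the 2–30 dB grid of a 200 mW source, additive
  Gaussian amplitude noise.
* **Structures**: idealised straight-arm C$\alpha$ traces with 1.5 A/residue
  axial rise and kink at residue 102, built to hit the requested kink depth
  (deep-V 2.0 nm / shallow ~0), tilt (80° / 30°) and arm-tip distance
  (20 A / 36 A) exactly, then self-verified through the geometry module to
  2 %. Real helices spiral, bend and fluctuate; these traces do not, which
  is precisely what makes them calibration standards.
* **Umbrella samples**: exact inverse-CDF draws from the biased Boltzmann
  density on a $10^{-4}$ nm grid — no Markov-chain autocorrelation, so WHAM
  validation isolates estimator error from sampling error.

Passing tests on these fixtures shows the estimators are correct and
internally consistent; it does **not** show that real gels, spectra or
trajectories satisfy the generators' assumptions (independent noise, exact
helical pitch, rigid geometry, uncorrelated samples). In particular the
multi-microsecond atomistic free-energy profiles of a real hairpin
transition (~100 kJ/mol barriers) are far beyond desk-scale sampling; the
WHAM validation uses analytic landscapes with known shape instead.

## Problem sizes and runtime

The validation suite uses 49-residue accessibility tables with two
replicates, 15-point saturation curves with a 200-replicate Monte-Carlo
recovery study, 33 umbrella windows with 5000 samples per window for PMF
recovery, and a demo pipeline with 200–400 samples per window and a 4–20
replicate bootstrap. These sizes give stable statistics (PMF recovery RMSE
well under 0.5 kJ/mol; $P_{1/2}$ recovery bias under 5 % at 2 % amplitude
noise) while keeping a full run in the tens of seconds.

## The pipeline

`run_pipeline()` chains the stages — fixture generation, topology mapping,
crosslink quantification, EPR depth analysis, geometry, WHAM — for a
bilayer (deep-V truth) and a monolayer (open-shallow truth) context, and
writes a manifest with every seed, parameter and output checksum so a rerun
is byte-identical. The user-facing surface is the exported R functions;
stage configuration is a single declarative list validated against a fixed
schema (unknown keys are rejected, not ignored, because a typo in
`embedded_max` silently falling back to a default is worse than an error).
The EPR fixture in the pipeline derives each site's true $\Phi$ class from
the same segment plan as the accessibility fixture, except that in the
bilayer the kink-adjacent site 101 is given an interfacial depth parameter
while PEGylation calls it buried — emulating the real-world observation
that the hairpin turn sits near the *opposite* membrane interface, visible
to a depth-sensitive probe but not to a solvent-accessibility one. The
bilayer cross-assay concordance on noise-free fixtures is therefore 9/10
shared sites, not 10/10, by design.

```{r pipeline, eval = FALSE}
report <- run_pipeline(list(out_dir = "run1", seed = 1))
report
```

## Known limitations

* Gel densitometry, image analysis and molecular-weight shift modelling are
  out of scope; the package consumes intensity tables.
* EPR spectral line shapes, rotational-correlation-time fits and hyperfine
  analysis are not modelled; an optional free-text mobility annotation can
  accompany a site instead.
* Trajectory handling is limited to multi-model PDB / per-frame tables: no
  force fields, periodic-boundary unwrapping, or trajectory formats.
* WHAM is 1-D with harmonic biases; no MBAR, no periodic reaction
  coordinates.
* The conformation classifier is a two-threshold rule, adequate for the
  well-separated states it targets; borderline geometries are reported
  `ambiguous` rather than forced into a class.
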