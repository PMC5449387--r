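# oligosizer

Sizing the smallest detectable oligomers of an aggregating peptide in
solution, from three solution-based lines of evidence:

1. **Sedimentation velocity (SV)** — a Lamm-equation simulator for
   sector-shaped centrifuge cells and a regularized c(s)
   sedimentation-coefficient-distribution analysis with peak integration,
   "prior probabilities" refinement and an F-statistics critical-rmsd test
   for minor species;
2. **Small-angle neutron scattering (SANS)** — a four-component intensity
   model (power-law large aggregates, ellipsoid-of-revolution midsize
   species, Beaucage small-oligomer term, fixed-Rg monomer background) with
   curve simulation, wavelength-spread smearing and bounded weighted
   fitting;
3. **Bead-model hydrodynamics** — coarse-grained (one bead per residue)
   oligomer conformers, Kirkwood translational friction, grid volumes,
   Kabsch RMSD and GROMOS-style (Daura) clustering, bridging measured
   s-values to oligomer order.

The motivating application is amyloid-beta (Aβ42), where penta- and
hexamers around s ≈ 2.3–2.6 S and Rg ≈ 2–4 nm are the smallest species
detectable in solution. No raw instrument data are required: every analysis
ships with a seeded synthetic-data generator, so the whole pipeline runs as
a parameter-recovery study.

## The models

**Hydrodynamics.** A species with molar mass *M*, partial specific volume
v̄ and frictional ratio f/f₀ sediments with

    s = M (1 − v̄ρ) / (N_A · 6πη · (f/f₀) · R₀),   R₀ = (3Mv̄ / 4πN_A)^{1/3}

and diffuses with *D* fixed by the Svedberg identity
s/D = M(1 − v̄ρ)/RT. Observed s-values are normalized to 20 °C water
(s20,w) by the usual viscosity/buoyancy ratio; v̄ comes from the
Cohn–Edsall residue table with a 4.25·10⁻⁴ cm³ g⁻¹ K⁻¹ temperature slope.

**c(s) analysis.** Scans are modelled as a non-negative superposition of
unit-loading Lamm solutions on an s-grid,

    min_{c ≥ 0} ‖A c − y‖² + λ² P(c),

with P a second-difference (Tikhonov) or entropy penalty and λ set by an
F-ratio criterion at confidence 0.95. Trace species are then pinned by a
discrete non-interacting-species refinement, re-imposed on the distribution
as prior probabilities, and tested for significance against a critical rmsd
derived from the F distribution.

**SANS.** I(Q) = A·Q^(−d) + ellipsoid-of-revolution term (Rg 10–50 nm) +
Beaucage oligomer term (Rg 1–5 nm) + Beaucage monomer term with Rg pinned
at 1 nm + flat background, fitted by bounded weighted Levenberg–Marquardt.

**Bead models.** Kirkwood's preaveraged approximation
D_t = kT/(N 6πησ) · (1 + σ/N · Σ_{i≠j} 1/R_ij) converts conformer
coordinates to friction, hence s — exactly Stokes for one bead, 4/3·Stokes
for a touching dumbbell.

## Worked example

```r
library(oligosizer)

# the closed-form s-value of a compact hexamer (M = 6 x 4,514 Da)
svedberg_s(27084, vbar = 0.73, f_ratio = 1.27, solvent_conditions(20))
#> [1] 2.560892

# end-to-end: simulate a fluorescence SV run (free dye + labeled monomer +
# 1.4 % labeled hexamer, 60,000 rpm, 2500 RFU total, noise 12 RFU),
# invert it, refine, and test the trace species
rep <- run_scenario(builtin_scenarios(seed = 1)$A)
rep$sv$peaks
#>   window   s_min s_max  sw_S     sw20w_S  signal     fraction_pct
#> 1 dye        0.1   0.5  0.300    0.300     943.9     37.8
#> 2 monomer    0.5   1.2  0.801    0.801    1520.9     60.8
#> 3 oligomer   2.0   3.0  2.337    2.337      34.2      1.37
rep$sv$significance
#>   rmsd_full rmsd_reduced rmsd_critical significant
#> 1      12.1         14.6          12.1        TRUE
```

The oligomer window recovers the generating composition (1.4 % of signal at
2.32 S) and the F-test declares the trace species significant: removing it
pushes the rmsd above the critical value. `autoplot(rep$sv$cs)` draws the
c(s) distribution; `autoplot(rep$sans$fit)` (scenarios D/E) draws the
log-log SANS decomposition.

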