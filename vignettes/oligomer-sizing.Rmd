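---
title: "Sizing small oligomers in solution: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing small oligomers in solution: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligosizer)
```

This vignette documents the science inside `oligosizer`: the models, their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
numerical choices a maintainer should know about.

## The problem

Aggregating peptides such as amyloid-beta populate a wide ladder of
assembly states — monomers, a sparse set of small oligomers, protofibrils,
fibrils. The smallest oligomers matter disproportionately (they are the
putative building blocks of larger assemblies) but are hard to observe:
they are minor species (about 1 % of signal) sitting next to a dominant
monomer, and no single technique pins down both their size and their
stoichiometry. The package implements the three-way strategy used for this
problem in solution: sedimentation velocity gives an s-value; small-angle
neutron scattering gives a radius of gyration; coarse-grained bead
hydrodynamics converts candidate oligomer structures into the same two
observables, closing the loop between them.

## Hydrodynamic core

All conversions run through the Svedberg/Stokes relations with SI
arithmetic and field-standard user units (Svedberg, nm, g/mol, cm³/g, cP).
Pure-water density uses the Kell (1975) rational polynomial and viscosity
the Kestin-type correlation anchored at 1.002 cP / 20 °C; both are valid on
0–40 °C, which covers every protocol here. Dilute buffers (10 mM phosphate
class) are treated as water for density and viscosity — consistent with
quoting s20,w values without a buffer correction.

Sequence-based partial specific volumes use the Cohn–Edsall residue table
at 25 °C, mass-weighted, with the conventional linear temperature slope of
4.25·10⁻⁴ cm³ g⁻¹ K⁻¹. This reproduces the reference pair for the
cysteine-linked 40-residue peptide dimer (0.7316 cm³/g at 20 °C, 0.7295 at
15 °C) to four decimals. Dye-conjugate v̄ values (e.g. 0.7127 cm³/g for a
fluorophore-labeled peptide) are accepted as user input, not computed:
volume increments for synthetic dyes are not derivable from a residue
table. The s20,w correction applies the viscosity/buoyancy ratio with the
*same* v̄ in both terms; temperature adjustment of v̄ itself is left as an
explicit, separate step (`vbar_temp_adjust()`).

## The Lamm simulator

`solve_lamm()` integrates sedimentation–diffusion transport in a
sector-shaped cell with a Crank–Nicolson finite-volume scheme on a uniform
radial grid (default 600 cells between meniscus 6.0 cm and base 7.2 cm).
The finite-volume construction conserves the sector mass integral
∫c·r·dr to machine precision by telescoping fluxes — mass conservation is
structural, not a tuning outcome. Advection at cell faces is centred; the
time step is capped at a Courant number of 0.5 against the fastest face
velocity, which keeps the centred scheme clean for every s in the working
grid (0.1–5 S at 50,000–60,000 rpm). The solver is validated against two
closed forms: the radial dilution law for the plateau
(exp(−2sω²t), to 1 %) and the Faxén boundary position r_m·exp(sω²t) in the
small-diffusion limit (to 0.5 %); halving both steps changes scans by less
than 0.2 %.

The mixture generator adds i.i.d. Gaussian detection noise under an
explicit seed. It emulates: multi-species boundaries, absorbance- or
fluorescence-style scan schedules (60 scans at 90 s or 60 s), and realistic
noise-to-signal (0.5 % of loading, matching an rmsd of ~12 units on a
2500-unit fluorescence signal). It does **not** emulate: optical artifacts,
meniscus mis-setting, time-invariant/radial-invariant systematic noise
(generation is off by default, though the fitter can eliminate such
offsets), rotor acceleration, or the sample losses seen in real cells —
scenario loadings are post-loss values. Passing tests therefore demonstrate
correctness of the inverse problem under ideal instrument behaviour, not
robustness to every experimental pathology.

## c(s) inversion

`fit_cs()` solves the non-negative regularized inversion against a basis of
unit-loading Lamm solutions, one per grid point (default 0.1–5 S at
0.05 S). Numerically it works on the normal equations with a Cholesky
factor and Lawson–Hanson NNLS, with a relative ridge of 1e-10 on the
Gram diagonal for rank safety; an all-zero data matrix is rejected.

**Diffusion tie and the frictional ratio.** Each grid s gets
D(s) from the Svedberg identity through a frictional ratio. Two modes
exist:

* a single global f/f₀ (default 1.4), optionally chosen by a 1-D rmsd scan
  (`optimize_f_ratio()`) — the mode for unknown samples, and standard
  practice;
* a per-species profile (`fit_options(f_profile=)`) interpolating known
  f/f₀ values across the grid — the mode the built-in recovery scenarios
  use, since their generating frictions are known and heterogeneous.

The profile mode matters here for an instructive physical reason: with the
short one-hour scan schedules of the reference protocols, sub-Svedberg
boundaries move far less than they spread, so the data identify a species
mostly through D rather than through boundary displacement. A mis-set
global f/f₀ then biases recovered peak *positions* (not just widths) by
several grid steps. With heterogeneous known frictions the profile removes
that bias; with unknown samples the rmsd scan finds the best compromise and
the remaining bias should be kept in mind when interpreting sub-Svedberg
peaks from short runs.

**Regularization strength.** λ is the largest value whose chi-square stays
below the unregularized optimum times F(confidence; ν, ν), ν = n_data −
n_grid — the variance-ratio convention behind quoting a "confidence level
(F-ratio)" of 0.95. Tikhonov (squared second difference) is the default
penalty; maximum entropy is available behind the same interface and agrees
on peak positions and areas in the tests. A fixed `lambda` (including 0)
can be forced for oracle comparisons.

**Prior refinement.** At the 0.95 bound the smoothed distribution spreads a
1 %-class trace peak over ~0.5 S, which is faithful to how such
distributions look but poor for quantifying the trace window. The package
therefore mirrors the two-stage practice: first the smooth c(s), then a
discrete non-interacting-species refinement (Nelder-Mead over log s with
exact NNLS amplitudes) seeded from the window averages, then
`bayesian_refine()` — a re-fit in which the smoothing penalty is replaced
by a relative-entropy (generalized Kullback–Leibler) penalty against a
prior measure of one-grid-step Gaussians at the refined positions, with λ
re-bisected to the *same* F-bound. The refined distribution concentrates
mass at the prior positions exactly as far as the data allow at the stated
confidence; by construction it can never fit worse than the bound. This is
a documented stand-in for the internal prior-probability scheme of
established analysis software, matching its contract rather than its bits.

**Significance of minor species.** `species_significance()` removes one
species from the discrete fit, refits, and compares the reduced rmsd with
rmsd_full · sqrt(F(confidence; p, ν)·p/ν + 1), p = 2 (the removed s-value
and amplitude), ν = n_data − 2·n_species. With p = 1 this is the textbook
one-parameter F-test; the p = 2 convention is the natural generalization
and is what the tests pin down. On the fluorescence scenario the 1.4 %
oligomer is significant (removing it raises the rmsd from 12.06 to 14.57
against a critical 12.06); a zero-amplitude dummy is not.

## SANS model

The composite intensity is a sum of four physically-windowed terms plus a
flat background. Choices worth recording:

* **Beaucage prefactor.** B = (G·d/Rg^d)·[6d²/((2+d)(2+2d))]^{d/2}·Γ(d/2),
  the standard unified-fit form; the oligomer dimensionality is fixed at
  d = 2 by default (user-overridable), the monomer term's Rg is pinned at
  1 nm always.
* **Ellipsoid parametrization.** (Rg, aspect ratio) with aspect fixed at 4
  and Rg free in [10, 50] nm; only Rg is constrained by the data in this
  Q-window, so the aspect ratio is a declared convention, not a fitted
  quantity. The form factor integral uses 96-node Gauss–Legendre
  quadrature (error well below 1e-6 for these axis ratios).
* **Power-law exponent** restricted to [5/3, 3], the network/gel range.
* **Units.** Q is 1/nm internally; 1/Å input is converted on read
  (instrument range 0.001–0.5 1/Å → 0.01–5 1/nm).
* **Smearing.** Gaussian wavelength-spread smearing with
  σ_Q = Q·(Δλ/λ)/√(8 ln 2) via 21-node Gauss–Hermite quadrature, off by
  default: the recovery scenarios compare unsmeared truth, and at
  Δλ/λ = 0.2 the induced Guinier bias is below 5 % (tested).
* **Amplitudes are arbitrary units**; no absolute-intensity calibration or
  structure factor is modelled, and buffer subtraction is assumed done.

Fitting is bounded weighted Levenberg–Marquardt on residuals
(I_model − I)/σ_I, with uncertainties from the scaled inverse Hessian. The
default starting model is heuristic (lowest-Q intensity seeds the power
law, the high-Q tail seeds the background, mid-range radii elsewhere); on
the reference curves recovery needs no hand-tuning. Separability — the
reason the four-window decomposition is trustworthy — is asserted as a
test: ±50 % perturbation of the large-aggregate amplitude moves the fitted
oligomer Rg by less than 10 %.

## Bead-model hydrodynamics

Conformers are one bead per residue (0.51 nm radius, the residue-shell
convention of rigid-body practice; monomer mass 4,514.1 Da for the
42-residue peptide, v̄ 0.73 cm³/g unless overridden). The synthetic
generator grows each chain as a collapsed self-avoiding walk with exact
0.38 nm bonds, packs chains into a globule with random orientations, and —
when a target Rg is requested — rescales radially to hit the target,
erroring (with the feasible range) rather than violating the quarter-bead
overlap floor. Because narrowly infeasible packings occur stochastically,
generation retries with derived seeds before giving up; results remain
deterministic per seed. These conformers emulate compactness and size
spread of simulation snapshots, not secondary structure, energetics or
realistic contact topology.

Friction uses Kirkwood's orientationally preaveraged approximation, chosen
over a full Rotne–Prager supermatrix inversion for desk-scale speed; its
contract is the oracle suite (single bead = Stokes exactly, touching
dumbbell = 4/3·Stokes exactly, dense spherical shell → Stokes of the shell
radius within 5 %). One documented consequence: for *filled* globules the
preaveraged sum gives a hydrodynamic radius near 5/6 of the envelope
radius, so realized Rh/Rg for compact oligomers sits around 0.95–1.1
(a solid sphere with exact friction would give √(5/3) ≈ 1.29). The
calibration that matters for the science — a compact hexamer at target
Rg 2.1–2.3 nm landing in s ≈ 2.3–2.9 S — holds with the 0.51 nm bead
radius.

Ensemble work: per-conformer targets are jittered by 2.5 % (relative),
chosen so the s-distribution widths come out near ±0.07 S, the scale seen
for simulated oligomer ensembles; compact target radii scale as
order^(1/3) from a hexamer reference of 2.3 nm (the radius the scattering
analysis attributes to penta/hexamers). With 12–30 conformers per order the
mean s-values order strictly tetramer < pentamer < hexamer
(≈ 2.23 / 2.55 / 2.81 S) and adjacent distributions overlap by well under
0.3 S — ensemble sizes are a package choice; the ordering margin (≈ 0.3 S
against a standard error of ≈ 0.015 S) makes larger ensembles unnecessary.
Daura clustering (greedy neighbour counting under a 0.2 nm Kabsch-RMSD
cutoff, ties to the lowest index) is checked against a brute-force
reference on small ensembles.

## Scenarios, seeds and problem sizes

`builtin_scenarios()` fixes six seeded study designs: (A) fluorescence SV
with free dye (0.30 S), labeled monomer (0.80 S, 61 % of a 2500-RFU
loading) and a 1.4 % labeled hexamer (2.32 S) at 60,000 rpm, noise 12 RFU;
(B) absorbance SV with 95 % monomer (0.62 S) and 5 % hexamer (2.56 S) at
50,000 rpm, noise 0.5 % of loading; (C) the covalent-dimer model pair
0.65/0.90 S at equal loading; (D, E) four-component SANS curves with
oligomer Rg 2.3 nm and 4.0 nm, 100 log-spaced Q points on 0.01–5 1/nm, 5 %
relative noise; (F) tetra/penta/hexamer ensembles. SV problems are 60
scans × 600 radii; every stage's RNG stream derives from the scenario seed
by fixed offsets, so reports regenerate bit-for-bit.

`run_scenario()` chains simulate → c(s) → discrete refinement → prior
re-fit → window integration → significance, and for unknown-friction use
falls back to the rmsd-optimizing f/f₀ scan (a deliberate deviation from
fixing f/f₀ a priori: floating it is what practitioners do, and the scan is
1-D and cheap).

## Known limitations

* No interacting-system (reaction-boundary) modelling: every species is
  non-interacting by construction, and the analysis would mis-read a
  rapidly re-equilibrating mixture as a single intermediate boundary.
* No meniscus/base position fitting and no systematic-noise generation;
  real-data use would need both.
* The prior-refinement scheme matches the published method's contract, not
  its implementation; refined peak *widths* are convention-dependent even
  though positions, areas and weight-averages are data-determined.
* Kirkwood preaveraging underestimates friction for dense assemblies by
  ~10–20 % relative to shell-model codes; absolute bead-model s-values
  carry that systematic, while order-to-order *differences* are much more
  reliable.
* Sub-Svedberg peak positions from one-hour runs are D-identified (see
  above); longer runs or known frictions are needed before reading small
  shifts as mass changes.
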