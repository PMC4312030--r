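---
title: "Methods: disulphide photolysis candidates and UV photochemistry kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disulphide photolysis candidates and UV photochemistry kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssphotolysis)
```

## The problem

Ultraviolet illumination of proteins at 280 nm is absorbed almost entirely by
tryptophan, tyrosine and cystine. Excited aromatic residues can transfer an
electron to a spatially close disulphide bond, cleaving it; the photoproducts
(free thiols, dityrosine, N-formylkynurenine) are measurable in solution.
Whether a given disulphide is a plausible photolysis target is therefore a
structural question — is there a Trp or Tyr ring within electron-transfer
range? is the cystine solvent-exposed? does it sit in the strained −RHStaple
geometry associated with redox-active, allosteric bonds? — and the
photochemistry itself is a kinetics question, answered by exponential and
sigmoid model fits to fluorescence traces, thiol assays and thermal melts.

`ssphotolysis` implements both halves as a tidyverse-style pipeline: tibbles
in, tibbles out, broom-style `tidy()`/`glance()` on fitted objects, and
seeded synthetic-data generators for every analysis stage. The motivating
system is human plasminogen (767 residues, 24 disulphides, PDB entry 4A5T),
whose catalytic-domain bond Cys737–Cys765 sits 4.2 Å from Trp761, but every
operation takes an arbitrary structure.

## Structural screening

**Atom selection conventions.** Aromatic proximity uses the ring systems
only: the nine indole atoms of Trp and the six benzene carbons of Tyr (the
hydroxyl oxygen is excluded). A disulphide is represented, by default, by
*all* heavy atoms of both cysteine residues (`convention = "all-atoms"`);
`"sidechain"` (CB+SG) and `"sulfur-only"` are also implemented because the
phrase "all the atoms of the bond" is genuinely ambiguous in the literature
this convention comes from. The choice shifts reported distances by up to
~1–2 Å, so `aromatic_ss_proximity()` exposes the flag; when a reference
structure with published distances is available, running the three
conventions and keeping the one that reproduces the published table is the
recommended calibration. Dityrosine geometry uses the two ortho carbons
(CE1/CE2), the positions through which the crosslink forms. Hydrogens are
excluded from all distance and area computations (crystal structures at this
resolution carry none); they are retained in the atom table and flagged.

**Detection.** Cystines are detected by pairing SG atoms whose separation
falls in a 1.8–2.5 Å window — the ideal S–S bond is 2.05 Å, and the window
absorbs the coordinate error of low-resolution models. Pairing is greedy
nearest-first and each sulfur joins at most one bond; output order is by
residue number so reports are deterministic.

**Stereochemistry.** The five side-chain dihedrals χ1–χ5 are measured along
the N–CA–CB–SG–SG′–CB′–CA′–N′ chain with the IUPAC sign convention (verified
against two independent structural libraries). The 20-class geometry label
is assembled from signs alone: handedness from χ3 (RH if positive), the
Spiral/Hook/Staple motif from whether χ2 and χ4 match χ3's sign (both match:
Spiral; both oppose: Staple; mixed: Hook), and a −/+/+/− prefix from χ1 and
χ5. An angle of exactly 0° has no sign, and such bonds are reported
`unclassified` rather than silently assigned. The torsional strain energy

$$E = 8.37(1+\cos 3\chi_1) + 8.37(1+\cos 3\chi_5) + 4.18(1+\cos 3\chi_2) +
4.18(1+\cos 3\chi_4) + 14.64(1+\cos 2\chi_3) + 2.51(1+\cos 3\chi_3)$$

(kJ mol⁻¹) follows the torsional potential used by the standard
disulphide-analysis tools; it is labelled approximate in the outputs because
its constants are force-field folklore, not a calibrated free energy.

**Solvent accessibility.** Areas are Shrake–Rupley: a deterministic
golden-spiral set of 960 points per atom on a sphere of radius
$r_\mathrm{vdw} + 1.4$ Å, counting points outside every neighbour's expanded
sphere. Radii are C 1.70, N 1.55, O 1.52, S 1.80 Å (configurable). The
discretisation error of an isolated sphere is below $2/\sqrt{960} \approx
6.5\%$ relative in the worst case and far smaller in practice; the test
suite pins the implementation against an independent Shrake–Rupley
implementation to ~0.1 Å² per atom. A half-cystine's side-chain ASA is the
CB+SG sum computed *in the intact structure* — the bond partner occludes —
and is also reported as a percentage of 104 Å², the fully exposed Cys
side-chain area in an extended Gly-Cys-Gly reference. Increasing
`sphere_points` tightens the bound at linear cost.

**Thresholds.** Distances below 5.2 Å are direct van der Waals contact;
6 Å is the "close pair" cutoff used in contact tables; 8 Å (roughly one
residue diameter) is the census threshold for counting aromatics near any
bond; all are `analysis_config()` fields, strict inequalities.

**Tyrosine clusters.** Pair distances are reported between ortho carbons,
but cluster membership is decided on the shortest distance between any heavy
atoms of the two tyrosines (single linkage at 6 Å). These two metrics are
deliberately different: published cluster assignments include pairs whose
ortho–ortho distance exceeds the clustering threshold, which is only
consistent if residues are clustered on whole-residue proximity. The metric
is switchable (`cluster_on = "residue" | "ring" | "ortho"`).

**Disulphide enrichment.** `ss_fraction()` is 100·n_SS/length;
`ss_fraction_profile()` bins a background dataset by chain length (50-residue
bins) and `ss_fraction_enrichment()` flags a query protein whose fraction
exceeds its bin mean by ≥5× (a disulphide-rich outlier such as plasminogen
is ~30× over the ~0.1% background of similarly sized proteins).

## Photochemistry fits

All kinetic models are one three-parameter family,
$y(t) = \mathrm{offset} - \mathrm{amplitude}\,e^{-\mathrm{rate}\,t}$,
reported either as $F(t) = C_1 - C_2 e^{-kt}$ (fluorescence rise/decay) or
$y = y_0 - A e^{-R_0 t}$ (thiol formation); thermal melts use the
sloping-baseline Boltzmann model

$$y = A_2 + B_2 x + \frac{(A_1 + B_1 x) - (A_2 + B_2 x)}{1 + e^{(x - x_0)/dx}}$$

whose midpoint $x_0$ is the melting temperature. Fitting is
Levenberg–Marquardt nonlinear least squares (`minpack.lm`) with a relative
cost tolerance of 1e-10 and three heuristic starts: endpoint plateau,
log-linearised slope, and mid-range half-life (for melts: $x_0$ from the
steepest finite-difference slope, $dx = 1.5$, baselines from linear fits of
the first and last 20% of the window). The best converged start wins.
Non-convergence and windows without an interior inflection are *flagged*
(`converged = FALSE`), never raised as errors, because ill-conditioned fits
are a real experimental outcome: a quasi-linear trace (rate ≈ 0) fits with
standard errors larger than the estimates, and the reported uncertainties
are the honest signal of that degeneracy. A constant signal, by contrast, is
a degenerate input and is rejected. Typical fit windows follow practice for
these experiments: 0–30/0–45 min for traces, 60–90 °C for far-UV melts,
~57–81 °C for near-UV melts.

Supporting arithmetic: Ellman thiol concentration $c = A_{412}/(14150\,\ell)$
(µM for $\ell$ in cm), the theoretical thiol ceiling
(protein concentration × bonds × 1 SH per broken bond), the broken-bond floor
$\lfloor y_0 / c_\mathrm{protein} \rfloor$, chromophore-count extinction
coefficients ($5500 W + 1490 Y + 125 SS$), mean residue ellipticity
(mdeg·MRW/(path·conc), path in mm, conc in mg/mL, MRW = MW/(n−1)), adjacent
averaging (window clipped at the series edges so output length equals input
length; a truncating mode is available), maximum normalization and percent
change.

## Ensemble analysis

Multi-model PDB files are consumed as ensembles (fixed topology, F congruent
frames; a frame-range argument handles equilibration discards).
Superposition is Kabsch rigid-body least squares on a selection (default CA)
with a proper-rotation guard, so mirror-image frames retain positive RMSD;
`reference = "mean"` iterates once against the mean structure. RMSF is the
per-atom root-mean-square deviation from the mean position, averaged per
residue; the default CA selection is a convention, not a claim about what any
particular study used. Side-chain exposure uses the non-backbone heavy atoms,
with the same Shrake–Rupley engine per frame, and distributions are plain
histograms (default 5 Å² bins aligned to zero) normalised so that
$\sum \mathrm{density} \times \mathrm{width} = 1$ exactly — deterministic,
unlike a kernel density. Distribution comparison reports the mean shift and
the overlap coefficient $\sum \min(d_A, d_B)\,w \in [0, 1]$.

## Synthetic data: what it emulates and what it does not

The generators provide exact ground truth for every stage:

- `gen_kinetic_trace()` / `gen_melt_curve()`: the model curves above plus
  additive Gaussian noise. The defaults used in the recovery studies take
  the published fit parameters as truth (thiol: $y_0 = 2.29$ µM, $A = 3.78$,
  $R_0 = 0.037$ min⁻¹ on the 0–112.5 min schedule; fluorescence rise:
  $C_1 = 1.43$, $C_2 = -0.43$, $k = 0.076$ min⁻¹ at 10 s sampling; melt:
  $x_0 = 70.61$ °C with the published baselines over 60–90 °C at 1 °C
  steps). The experiments publish no noise model, so noise is additive
  Gaussian with σ stated as a fraction (1–5%) of the noiseless curve's
  dynamic range on the fitted window — a package choice, made once.
- `gen_disulfide_model()`: NeRF internal-coordinate construction of a
  cystine with prescribed χ1–χ5 and ideal covalent geometry; builder and
  measurer agree to better than 1° across the full sign grid, which is what
  lets the classifier be tested exhaustively.
- `gen_aromatic_probe()`: an idealised Tyr/Trp ring placed by root-finding
  so the ring-to-cystine minimum distance equals the target within 0.05 Å.
- `gen_ensemble()`: per-residue isotropic Gaussian jitter (expected RMSF
  $\sigma\sqrt{3}$) with optional random rigid motions per frame. With rigid
  motions the superposition step absorbs six degrees of freedom, shrinking
  measured RMSF by $\sqrt{1 - 6/(3N)}$ — ~6% for the 18-atom toy models, and
  negligible for protein-sized selections; recovery tests therefore state
  the $\sigma\sqrt{3}$ property on non-superposed ensembles.

Every generator takes an explicit seed and restores the caller's RNG state;
identical specs give identical output. What the generators do *not* emulate:
real photobleaching physics, force-field dynamics, instrument response, or
correlated noise. A passing recovery study shows the estimators are
calibrated for the stated model class and noise level — not that real traces
obey a single exponential.

## Problem sizes and determinism

The shipped test and acceptance studies use 100 noise replicates per
recovery experiment, 271-point traces, 31-point melts, 300–500-frame toy
ensembles and 960 sphere points — sizes chosen so the whole suite runs in
well under a minute on one core while keeping Monte-Carlo error an order of
magnitude below every tolerance tested. Tie-breaks are first-by-input-order
everywhere, outputs are sorted by residue number, and report writers produce
byte-identical files on re-runs.

## Known limitations

- The structural reproduction of the plasminogen survey needs the PDB entry
  4A5T, which is redistributed by the PDB, not bundled; point
  `options(ssphotolysis.4a5t_path = ...)` at a local copy (or drop the file
  into `inst/extdata/`) to run those checks, including the cystine-convention
  calibration.
- Published molecular-dynamics exposure distributions cannot be reproduced
  without the original trajectories; the ensemble module is validated by
  construction (known-σ ensembles) instead.
- Strain energies are comparative, not thermodynamic.
- The PDB reader handles ATOM/HETATM/MODEL/ENDMDL v3 records; mmCIF,
  assemblies and symmetry mates are out of scope.
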