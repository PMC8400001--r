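---
title: "Methods: contact occupancy, assay analytics and injury statistics in catnap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact occupancy, assay analytics and injury statistics in catnap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catnap)
```

catnap post-processes the three kinds of data that a hydrophobic
ion pairing (HIP) nanomedicine study produces: molecular dynamics
trajectories of a protein with ion-pairing agents, bench assay readouts
(catalase activity, BCA protein quantification), and in vivo
brain-injury endpoints. This vignette explains the models and
procedures each layer implements, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
numerical choices that were genuinely open.

## Contact occupancy

The central trajectory statistic is per-residue **occupancy**: the
percentage of frames in which an ion-pairing molecule lies within a
distance cutoff of a protein residue,

$$\%\,\mathrm{occupancy}_i \;=\; 100 \times
  \frac{\#\{\,f : \min_{a \in i,\, b \in \mathrm{ligand}} d_{ab}(f) \le c\,\}}
       {\#\,\mathrm{frames}},$$

with cutoff $c = 4$ Å by default. Three conventions needed fixing:

* **Heavy atoms only** (default): hydrogens are excluded from the
  distance test, the common convention for contact analyses;
  `contact_parameters(heavy_atoms_only = FALSE)` restores all atoms.
* **Boundary inclusive**: a distance exactly equal to the cutoff counts
  as a contact, so the criterion is deterministic.
* **Any molecule counts**: a frame is a contact frame if *any* ligand
  molecule touches the residue. Per-molecule tables are available via
  `compute_occupancy(..., per_molecule = TRUE)` but are not used for
  selection.

Residues whose occupancy strictly exceeds 95% (`select_high_occupancy`;
a residue at exactly 95.0% is excluded) are profiled into five chemical
classes and the class counts normalized by the number selected
(`group_fraction_profile`), so profiles are comparable between
ion-pairing agents. The class mapping (`residue_group_table()`) is a
plain tibble and therefore swappable; the default places His with the
positives because the complexation chemistry of interest happens at
acidic pH (3.7–4.7) where His is protonated, keeps Tyr with the
aromatics (Tyr is polar in some schemes), and files Gly and Cys under
polar. All fractions sum to one whenever the selection is non-empty; an
empty selection yields an all-zero profile with a count of zero rather
than an error.

## RMSD with Kabsch superposition

`rmsd_series()` reports, per frame, the root-mean-square deviation of
the backbone (atoms named N, CA, C — the convention of the common
trajectory tools' "Backbone" group) from a reference structure after a
least-squares rigid superposition. The superposition
(`kabsch_superpose()`) is the SVD solution with a determinant
correction, so a proper rotation is always returned. Fitting and
measurement use the *same* atom selection; this matches the behaviour
of standard tools when the fit group and the output group coincide, and
it makes domain-restricted series (e.g. the three serum-albumin domains,
`albumin_domains()`: residues 1–183, 184–376, 377–583, the canonical
convention — the boundaries are arguments, not constants) independent
of motion elsewhere in the protein. Coordinates are Ångström throughout
(PDB convention); RMSD is reported in nanometers (10 Å = 1 nm), the
unit in which serum-albumin N→F isoform transitions are usually
discussed.

Two analytic facts anchor the test suite: rigid motions of the
reference give identically zero fitted RMSD, and isotropic per-coordinate
Gaussian noise of standard deviation $\sigma$ over $N \gg 1$ atoms
gives expected fitted RMSD $\sigma\sqrt{3}$ (the fit removes only 6 of
$3N$ degrees of freedom, a negligible correction at $N \ge 1000$).

## Solvent-accessible surface composition

`surface_composition()` asks whether two proteins present similar
surfaces to an ion-pairing agent. Per-atom solvent-accessible surface
area uses the numerical sphere-sampling scheme of Shrake and Rupley:
each atom is inflated by the probe radius (1.4 Å, a water molecule) and
covered with a fixed quasi-uniform point set (960 points by default,
golden-spiral construction, deterministic); points inside any
neighbouring inflated sphere are occluded. Van der Waals radii are
Bondi-type. Per-residue SASA is normalized by the residue's theoretical
maximum accessibility in an extended Gly-X-Gly tripeptide (Tien et al.
2013); residues at or above 20% relative SASA are called surface, and
the surface set is profiled into the same five classes. An isolated
atom reproduces the closed-form sphere area $4\pi (r+p)^2$ exactly,
because no point is occluded; this is the sampling scheme's natural
sanity anchor.

## Catalase activity from crossing times

The spectrophotometric catalase assay tracks the decline of A240 as
H~2~O~2~ is decomposed. Activity in active units (AU; 1 AU decomposes
1 µmol H~2~O~2~ per minute) per mL of sample is

$$\mathrm{AU/mL} = \frac{3.45 \times \mathrm{dilution}}
                        {\Delta t_{\min} \times 0.1},$$

where 3.45 µmol is the amount decomposed while A240 falls from 0.45 to
0.40, 0.1 mL is the sample volume added to the cuvette, and
$\Delta t_{\min}$ is the time (minutes) between the two level
crossings. The constants live in `assay_constants()` and are arguments,
not magic numbers. The dilution factor is the sample pre-dilution only
(the cuvette dilution is already inside the 3.45/0.1 calibration). A
trace whose first reading lies outside the substrate-preparation window
(0.48–0.52) is processed but flagged, since the calibration assumes a
properly prepared substrate.

**Crossing times** are the one place the procedure needed a numerical
decision. The trace is scanned for the first downward crossing of each
level; an exact sample hit returns that sample's time; otherwise the
crossing is interpolated between the two bracketing 2-second samples
*linearly in log-absorbance*. For first-order decay — the regime this
assay operates in — log-linear interpolation is exact; plain linear
interpolation biases the crossing interval by up to ~0.5% at fast rates
(k ≈ 0.05 s⁻¹ crosses both levels within a couple of samples), which
would exceed the package's own 0.1% accuracy contract for noise-free
first-order traces. When a bracketing absorbance is non-positive
(possible in noisy tails) the interpolation falls back to linear. If
noise produces several crossings, the first wins.

## BCA quantification, binding efficiency, loading arithmetic

The BCA response is modelled as a straight line over the working range,
fitted by ordinary least squares (`bca_fit()`, a thin wrapper around
`lm` with `tidy()`/`glance()` methods); readings outside the calibrated
absorbance range are extrapolated with a warning. The base-hydrolysis
protocol that releases encapsulated protein (100 µL sample + 50 µL
NaOH + 50 µL PBS) is a fixed 2× dilution, exposed as
`hydrolysis_dilution_factor()`.

Binding efficiency is supernatant depletion,
$(\mathrm{initial}-\mathrm{supernatant})/\mathrm{initial} \times 100$;
negative values (supernatant above initial) are reported with a warning
rather than clamped, so noisy measurements stay visible. Specific
activity converts loadings to AU/mg
($\mathrm{AU/mL} \div \mathrm{µg/mL} \times 1000$) and
`percent_deactivation()` expresses a process's damage as
$(1 - \mathrm{treated}/\mathrm{reference}) \times 100$. Protection
courses normalize activity under protease challenge to the 0 h value.

The ion-pairing stoichiometry inventory (`ion_group_inventory()`)
counts anionic groups offered per protein molecule. Dextran sulfate is
modelled as a dodecamer bearing **24 sulfate groups per molecule** — the
count required for a dodecamer to offer 120 groups at a mole ratio of 5,
comparable to 128 for SDS or taurocholic acid (1 group each) at mole
ratio 128. The count is an argument with these defaults in
`ion_pairing_agents()`, not a hard-coded constant.

## Injury endpoints and statistics

Area loss is the healthy-tissue deficit of the ipsilateral hemisphere,
$(1 - A_\mathrm{ipsi}/A_\mathrm{contra}) \times 100$; it is
scale-invariant, and negative values (ipsilateral larger) warn rather
than error. Gross injury uses the five-point ordinal scale 0–4 binned
by percent lesion. The printed bin edges (1 = <25%, 2 = 25–50%,
3 = 51–75%, 4 = ≥75%) leave a gap at (50, 51) and an overlap at 75;
`lesion_to_score()` resolves them deterministically — 0 only at exactly
zero lesion, [25, 50] → 2, (50, 75) → 3, and the "≥75" clause wins at
exactly 75 — with the inner edges configurable through `score_scale()`.

Summaries are median with IQR; quartiles use linear interpolation of
order statistics (`quantile` type 7, the default of mainstream
statistical software), stated so summaries are reproducible. Group
comparisons use the two-tailed Wilcoxon–Mann–Whitney U test
(`mann_whitney_u()`): exact when the combined sample is ≤ 16 without
ties, else the normal approximation with tie correction and 0.5
continuity correction; the statistic reported is the smaller of the two
one-sided U's. Fully tied degenerate micro-samples (e.g. {1} vs {1})
have zero rank variance and report p = 1. The unpaired Welch t test
(`welch_t()`) covers the complexation/loading comparisons. No
multiplicity adjustment is applied anywhere, matching the unadjusted
pairwise reporting convention of this literature; `injury_compare()`
reports raw p values per comparison.

## Synthetic data: what it emulates, what it does not

Every analysis stage has a generator that produces inputs with exactly
known ground truth:

* `plant_contact_trajectory()` places a ligand atom at a chosen
  distance (default 3 Å) from a residue's CA in exactly
  `round(p × F/100)` seeded-chosen frames and parks all ligands far
  away (≥ 2× cutoff) otherwise, so occupancy recovery can be asserted
  as integer equality. Ligands teleport between frames — physically
  absurd, ideal for counting. The generator *verifies* its own geometry
  and refuses plans where a plant would also graze a neighbouring
  residue (plant distances below ~2.9 Å at a 4 Å cutoff on the toy
  chain) or where a frame needs more simultaneous plants than there are
  ligand molecules.
* `perturb_frames()` produces rigid motions (zero-RMSD null) plus
  optional isotropic Gaussian noise (the σ√3 calibration).
* `gen_kinetic_trace()` samples $A_0 e^{-kt}$ at 2 s and returns the
  analytic crossing times.
* `gen_cohort()` draws lesion percents from a two-component mixture —
  mild N(8, 5) and severe N(60, 15) with severe weight 0.3, clamped to
  [0, 99.5] — mirroring the bimodal, right-skewed injury distributions
  characteristic of the unilateral hypoxia–ischemia model, with ~20
  pups per arm and a near-even sex split (the default arm layout totals
  58 pups: 30 male, 28 female). A per-group `shift` plants a location
  effect. Areas are back-computed so `area_loss()` recovers the latent
  lesion exactly.

All generators draw from a single explicitly seeded source per call
(`withr::with_seed`), so regeneration is byte-identical and nothing
leaks into the caller's RNG state.

What passing tests on these fixtures shows is that the *analytics* are
correct: distances counted exactly, superpositions optimal, formulas
applied faithfully, tests calibrated. It does not show that real
trajectories are well sampled, that real traces are noise-free
first-order, or that real cohorts match the assumed mixture — the
generators have no forcefield, no instrument drift, and no observer
variability in scoring.

## Problem sizes and runtime choices

The suite exercises occupancy recounts on ~50 random systems of at most
~50 atoms and 20 frames, RMSD calibration on a 340-residue chain (1020
backbone atoms, 10 frames), and type-I-error control on 2000 null
cohorts of 40 subjects — sizes at which the brute-force oracles are
exact and the whole suite completes in about a minute on a laptop-class
core.

## Known limitations

* Trajectory input is multi-model PDB (and DCD through
  `read_trajectory_dcd()`); XTC is not supported. PDB carries no time
  axis, so frame times are assigned from `dt_ns`.
* Insertion codes are rejected rather than renumbered.
* The SASA reference table covers the 20 standard residues; modified
  residues would need their own reference values.
* `surface_composition()` operates on a single frame; trajectory-
  averaged surface composition is a loop the caller writes.
* The BCA model is linear only; quadratic standard curves used by some
  kits are out of scope.
* Occupancy uses a dense all-pairs distance computation per frame —
  exact and fast at post-processing scales (10³–10⁴ atoms), but no
  neighbour lists; very large systems would want a cell-list variant.
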