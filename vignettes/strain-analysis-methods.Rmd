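---
title: "Geometric strain analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric strain analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainscope)
```

## The problem

At resolutions well below 1 Å, X-ray data begin to outweigh the stereochemical
restraints used in refinement, and real deviations from idealized geometry
become observable: aromatic rings bent at Cβ, arginine guanidinium groups
twisted out of plane, peptide bonds with ω far from 180°. Such outliers
cluster at functional sites — ligand-binding arginines, portal regions of
β-barrel lipid carriers, conserved aromatics of peptide-binding modules —
and standard validation tools flag them as errors even when the electron
density is unambiguous. strainscope quantifies these distortions with
transparent, degree-valued metrics, detects the weak C–H...O hydrogen bonds
that often accompany them at secondary-structure termini, and analyses
anisotropic displacement parameters (ADPs) for the concerted motions that
local strain hints at.

## Strain metrics

All metrics are heavy-atom-only, signed, reported in degrees, with an ideal
value of 0:

* **arg_twist** — torsion Cδ–Nε–Cζ–Nη1 of the guanidinium group. Under
  IUPAC naming Nη1 is cis to Cδ, so a planar group measures 0°. Deposited
  files sometimes swap the η nitrogens; when |torsion| > 90° the package
  assumes swapped naming, reports the complementary torsion to Nη2 and notes
  the normalization. On an exactly planar group the raw value is 0° or 180°,
  never intermediate.
* **phe_bend** — 180° − angle(Cβ, Cγ, Cζ): deviation of Cβ from the ring's
  para axis. Non-negative by construction; the in-plane versus out-of-plane
  component is deliberately not decomposed.
* **trp_bend** — signed pseudo-torsion Cβ–Cγ–Cε2–Cζ3 of the indole.
* **tyr_bend** — [180° − angle(Cβ,Cγ,Cζ)] + [180° − angle(Cβ,Cζ,Oη)], the
  sum of both arm deviations.
* **omega_dev** — deviation of ω = CA(i)–C(i)–N(i+1)–CA(i+1) from the
  nearest ideal: 180° for trans (|ω| > 90°), 0° for cis. Signed, in
  (−90°, 90°].

Signs are preserved so that compensating distortions of stacked pairs
(a twisted guanidinium against a counter-bent aromatic) remain visible in
reports.

### Outlier thresholds

The literature flags these outliers through validation-tool σ scores, which
are internal to those tools; no numeric degree cutoff is published. The
defaults here are this package's own policy, chosen to be transparent and
configurable rather than to reproduce any σ scale: |arg_twist| ≥ 6°,
phe_bend ≥ 5°, |trp_bend| ≥ 5°, tyr_bend ≥ 6°, |omega_dev| ≥ 10°. Every
threshold is reachable from the plain-text configuration file
(`default_config()`, keys `outlier_*`).

## Coordinate handling

PDB (fixed-column) and mmCIF (`atom_site` / `atom_site_anisotrop`) files are
parsed in-package: no macromolecular coordinate reader exists in the
supported R stack, and the two record families needed are small, stable
formats. Conventions:

* Author residue numbering everywhere, matching how residues are named in
  the field (Arg78, Trp97, ...).
* Deuterium ≡ hydrogen throughout, so perdeuterated and hydrogenated
  structures are directly comparable.
* Alternate conformers: geometry is computed on the highest-occupancy
  conformer per residue (ties go to altloc "A"); the choice is recorded in
  the report. Disordered regions are common in the ultrahigh-resolution
  structures this pipeline targets, and geometry on a mixture of conformers
  would be meaningless.
* Residue classes partition totally: standard amino acids → polymer, waters
  → solvent, every other HETATM group → ligand.
* If ANISOU tensors are present, B_eq = (8π²/3)·tr(U) is checked against the
  recorded isotropic B and a >1 % disagreement warns without failing —
  deposited files are occasionally inconsistent and the tensors remain
  usable.

## Weak hydrogen bonds and capping motifs

Riding hydrogens are placed at ideal geometry (C–H 1.09 Å, N–H 1.01 Å;
tetrahedral/trigonal frames from the heavy atoms; methyl rotors staggered
relative to the preceding bond). Placement covers every sp²/sp³ C–H and the
backbone amide N–H; side-chain N–H and O–H groups are used when observed in
the input (deposited H or D atoms) but are not rebuilt, since their
orientation is rotameric rather than structural. Observed hydrogens always
win over placed ones.

Detection criteria (the source analyses state none; these follow common
weak-hydrogen-bond practice and are configurable): C–H...O requires
d(H...O) ≤ 2.8 Å, d(C...O) ≤ 3.8 Å, θ(C–H–O) ≥ 110°; N–H...O requires
2.5 Å / 3.5 Å / 120°. Acceptors are restricted to oxygen. Loosening any
threshold never removes a reported bond (monotonicity is part of the test
suite).

Secondary structure is assigned from backbone N–H...O=C patterns alone
(DSSP-style minimal rules): helices from two consecutive i→i+4 bonds,
strands from bridge ladders, turns from i→i+3 bonds outside helices, with
priority H > E > T. β turns are operationalized as an i→i+3 backbone bond
whose central residues are not helical. Side-chain C–H...O bonds to
main-chain carbonyls are then classified: turn caps (donor at i+3 of a turn
whose backbone bond coexists — the package tests this coexistence as an
invariant), helix interior caps at i+3/i+4, helix C-terminal caps (donor at
or beyond the helix end), and sheet extensions (acceptor at a strand
terminus, sequence-distant donor). The fraction of turns carrying a
side-chain cap is reported but never tuned: it is a downstream consequence
of the stated criteria.

## ADP analysis

Anisotropy is the PARVATI-convention ratio λ_min/λ_max of the displacement
tensor's eigenvalues — 1 for an isotropic sphere, approaching 0 for extreme
elongation. This is stated explicitly because "anisotropy" has competing
definitions. Group statistics (protein / ligand / solvent) use the
arithmetic mean and, by default, the population standard deviation
(divisor N), matching typical validation output; both the H/D exclusion and
the sd convention are switchable, and non-positive-definite tensors are
excluded with a count. Per-residue principal axes are exported as a plain
text PyMOL CGO script with a deterministic sign convention (positive dot
product with the outward radial vector from the molecular centroid), so the
direction field of concerted motions can be rendered reproducibly.

## The synthetic test bed

`build_residue()`, `build_element()` and `attach_adps()` generate the ground
truth this package is tested against, standing in for crystal structures
that cannot be bundled or downloaded:

* Residues are built from internal-coordinate templates with Engh &
  Huber-style ideal values. Aromatic rings are exact regular polygons, which
  makes the ideal bending metrics exactly zero, and distortions are exact
  rotations about the metric's own axis, so the recorded ground truth equals
  the applied magnitude by construction (for Tyr the bend is applied to the
  Cζ–Oη arm; the metric sums both arms, so the total still equals the
  applied value).
* Backbones are propagated from dihedrals (NeRF), with canonical values:
  helix φ/ψ = −57°/−47°, strand −139°/135°, type I turn (−60°,−30°),
  (−90°,0°), type I′ apex for the hairpin. Dihedrals alone do not determine
  an inter-strand hydrogen-bond register, so sheets are finished by a
  deterministic least-squares placement of the second strand (six rigid-body
  parameters) and turns/hairpins by refining the connecting dihedrals,
  always targeting the construction-defined register from the canonical
  starting point. This is geometry realisation inside the generator — the
  detection criteria are never adjusted to meet it.
* The β-turn fixture additionally draws the i+3 Cβ into C–H...O capping
  range and orients its β hydrogen by a χ1 grid search, emulating the
  turn-cap motif observed in real structures.
* ADP tensors are built from a prescribed λ_min/λ_max ratio, largest axis
  direction and B_eq, with λ₂ halfway between the extremes.

What a green test does establish: the metrics recover constructed
distortions to 0.05° (1 × 10⁻⁹ for anisotropy), detection finds every
constructed bond, and the pipeline is deterministic. What it does not: the
fixtures are geometric constructions with no sterics, no thermal noise, no
disorder and no solvent, so green tests say nothing about robustness to
experimental artefacts — spot checks against deposited ultrahigh-resolution
structures (run locally with user-supplied files) remain the end-to-end
validation.

## Numerical choices

* Angles in degrees, torsions wrapped to (−180°, 180°]; collinearity is
  declared when the cross-product norm falls below 1 × 10⁻¹⁰ × the product
  of the segment lengths, and raises a domain error rather than returning a
  garbage angle.
* Plane fitting is total least squares via SVD; the reported rmsd is the
  root-mean-square perpendicular deviation.
* PDB output quantizes coordinates to 10⁻³ Å and tensors to 10⁻⁴ Ų (the
  format's own precision). In-memory fixtures close their ground truth to
  0.05°; after a PDB round trip the closure is ~0.1°, which the file-based
  tests account for.
* Peptide connectivity requires C(i)–N(i+1) ≤ 2.0 Å; ω bonds across breaks
  are skipped and logged, never interpolated.
* Measurements with missing atoms are skipped with a logged reason — a
  partial side chain produces no number rather than a wrong one.

## Known limitations

* Sulphur-containing side chains are supported in parsing and hydrogen
  placement, but thiol/hydroxyl hydrogens are never placed.
* No symmetry expansion: bonds across crystallographic interfaces are
  invisible unless the input already contains the mates.
* The secondary-structure assignment is intentionally minimal (hydrogen-bond
  patterns only — no geometric κ/α fallbacks), so isolated strands without a
  ladder partner are labelled coil.
* Batch co-reporting across homologs is positional (user-supplied residue
  mapping); no alignment is computed.
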