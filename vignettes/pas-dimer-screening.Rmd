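---
title: "Recognizing PAS folds and classifying sensor-domain dimer orientations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing PAS folds and classifying sensor-domain dimer orientations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pascreen)
```

## The problem

Bacterial sensor histidine kinases work as homodimers. Their periplasmic
sensor domains frequently adopt a Per-ARNT-Sim (PAS) fold: a five-stranded
antiparallel beta-sheet whose strands sit in the spatial order 2-5-1-4-3,
flanked by three alpha-helices, of which the first (alpha1, the
"periplasmic helix") is long and usually continuous with the first
transmembrane helix. In the prototypical sensors (PhoQ, DcuS, CitA) the two
alpha1 helices form the dimer interface. An alternative arrangement puts
the *third* helix (alpha3) at the interface, with alpha1 facing outward
and an N-cap motif at the alpha1 N-terminus taking over the structural role
its transmembrane continuation would otherwise play.

`pascreen` operationalizes the distinction. Given any structure collection
it answers, per pair of nearby chains: is this a parallel dimer, and which
canonical element is buried at the interface? Alongside it quantifies
crystal-contact burial (to flag lattice-driven arrangements), detects
N-cap motifs in structures and in multiple sequence alignments, and
superposes homologs.

## The classification model

A chain pair enters classification only if it has at least `min_contacts`
heavy-atom pairs within `contact_cutoff` (defaults 10 and 5.0 Å — the
screen's operational reading of "nearby"; both are configuration options,
and chain pairs below the threshold report `not_dimer`).

1. **Orientation.** Each chain gets a reference axis: the alpha1 helix
   axis when PAS annotation found one, else the first principal axis of
   all CA atoms, signed N-terminus to C-terminus. A pair is *parallel*
   when the directed angle between the axes is below 45 degrees. The
   directed angle matters: two alpha1 helices running the same way
   (parallel dimer) and two running opposite ways are different biology.
2. **Interface element.** For each chain, the buried accessible area of
   every canonical element (alpha1-alpha3, beta1-beta5) is the isolated
   chain's SASA minus its SASA in the complex, summed over the element's
   residues. The interface element is the element with maximal burial.
3. **Class.** `alpha3_interface` requires a parallel pair with alpha3 the
   top-buried element on *both* chains; `alpha1_interface` analogously;
   everything else is `other_interface` (including chains that are not
   PAS folds, which are still screened).

## Secondary structure and PAS recognition

Secondary structure comes from backbone hydrogen-bond energetics: the
electrostatic model `E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)`
kcal/mol with amide hydrogens inferred at 1.0 Å from N opposite the
bisector of the C(prev)-N and CA-N bonds (crystal structures carry no
hydrogens), a bond counted below -0.5 kcal/mol. Two stacked i to i+4 turns
make a helix; inter-strand bridge bonds in ladders make strands; the three
states H/E/C are all the downstream logic needs. Minimum element lengths
are 4 (helix) and 3 (strand) — the standard conventions; a 3-residue
3-10 bridge helix is therefore not emitted as an element.

Strands cluster into a sheet when their mean nearest-CA distance is below
5.5 Å and at least two inter-strand backbone hydrogen bonds connect them.
The sheet must form a linear adjacency path (branched adjacency means a
fused sheet or barrel and is rejected); the path, read as sequence indices,
is the sheet order. Because the starting edge is arbitrary, the order
string is normalized to the lexicographically smaller of itself and its
reversal, which maps "3-4-1-5-2" and "2-5-1-4-3" to the same topology.

A chain is called PAS when it has exactly one five-stranded sheet with
normalized order 2-5-1-4-3 and at least three helices. Canonical labels:
alpha1 is the longest helix of at least 10 residues wholly N-terminal of
beta1; alpha2 and alpha3 are the next two helices before beta3. This
matches the canonical PAS topology (alpha1, beta1, beta2, alpha2, alpha3,
beta3, beta4, beta5) and transfers to the known alpha3-interface folds.

**N-cap rules.** The residue preceding alpha1's first helical residue (N')
is classed `capping_box` for N' in {S, T, N, D}, `non_traditional` for
N' in {G, P, E, Q, H} (residues seen in known N-caps that are not classic
capping boxes), else `absent`; the residue before that (N'') is classed
L/I, M/V (the other branched hydrophobes), or other. The literature has no
single canonical rule table for the non-traditional tier, so this table is
an explicit, documented choice of this package; the same table drives both
the structural detector and the alignment census, so the two censuses are
directly comparable. A structural capping hydrogen bond is flagged when a
side-chain O/N of N' or N1 lies within 3.5 Å of the backbone N of N2/N3.

## Surface areas and crystal contacts

SASA is Shrake-Rupley with a probe of 1.4 Å over Bondi-style van der
Waals radii, using a deterministic golden-spiral point set (default 960
points per atom) so results are exactly reproducible; a single isolated
sphere is recovered to well under 1% of the closed form 4*pi*(r+probe)^2,
and doubling the point count moves totals by under 0.5%.

Crystal-contact burial expands all symmetry-operator plus lattice-
translation copies with any atom within 5 Å of the asymmetric unit
(operators from REMARK 290 records when present, else from a built-in
table of the common protein space groups) and reports the fraction of a
residue range's isolated-chain SASA lost in the packed environment. Both
the stated-range and the whole-chain readings are returned side by side,
because "fraction of the total solvent accessible area" is ambiguous
between them; on real crystals the two can differ substantially.

## The synthetic study set

The generator produces ground-truth-labeled inputs so every stage is
testable without downloads; the fixtures are idealized geometry, not
physical models, and that is deliberate:

* **Backbones** are extended residue-by-residue from standard bond
  lengths/angles and per-segment phi/psi (NeRF construction), omega fixed
  at 180. Side chains are CB only, plus the Ser OG of the planted N-cap.
* **The PAS monomer** places five 7-residue strands in spatial order
  2-5-1-4-3 at 4.5 Å spacing with registry offsets (±2.0 Å, calibrated
  once so the hydrogen-bond ladders of every adjacent strand pair form), a
  16-residue alpha1 preceded by a Leu-Ser extended tail (the planted
  N''-N' motif), an 8-residue alpha2 and a 12-residue alpha3. Alpha1 and
  alpha3 sit on opposite outward faces so either can be presented as an
  interface. Loops are geometric connectors routed around the sheet edges;
  their chemistry is meaningless and they are expected to assign as coil.
* **Dimers** apply a two-fold rotation that presents the chosen element
  (about the helix axis for parallel pairs — with a per-face 2.0/2.75 Å
  stagger along the axis so the facing helices pack ridge-into-groove
  rather than ridge-on-ridge — and perpendicular to it for antiparallel
  pairs), then translate the copy until the minimum inter-chain heavy-atom
  distance equals the requested separation (default 3.8 Å, a realistic
  van der Waals contact; the test grid uses 3.5, 3.8 and 30 Å, the last
  being the out-of-contact control).
* **Alignments** mutate a seeded random consensus at the per-column rate
  that yields the target mean pairwise identity, then overwrite the N-cap
  and preceding columns with class frequencies planted by largest-
  remainder rounding, so planted counts are exact integers. The default
  census conditions are 321 sequences with 92.2% capping-box and 89.4%
  L/I-preceding frequencies — the composition reported for the natural
  CpxA homolog family.

What passing on these fixtures does *not* show: robustness to the loop
conformations, side-chain packing, missing density, and alternative
conformers of real crystal structures, nor to sheet curvature (the
synthetic sheet is flat). The PDB-facing operations are therefore also
exercised on deposited entries by `analysis/05_validate_published.R`,
which expects locally supplied files.

## Numerical choices

* **Superposition** is closed-form Kabsch (SVD with determinant
  correction, so reflections are never returned); collinear point sets
  are flagged as degenerate rather than silently resolved.
* **Sequence-independent alignment** seeds a correspondence by matching
  same-kind secondary-structure elements in N-to-C order, then iterates
  Kabsch, mutual-nearest-CA re-pairing within 5 Å, and rejection of pairs
  beyond 3.5 Å until the pair set is stable (at most 50 cycles). The
  reported RMSD is recomputed on the final correspondence. This outlier
  rejection mirrors common structure-alignment tools, which report an
  aligned subset rather than all residues.
* **Identity denominators.** Pairwise identity defaults to counting
  columns where at least one sequence is non-gap; the redundancy filter
  visits records by descending ungapped length (query first and always
  kept) and keeps a record only if below threshold against everything
  already kept, which makes the retained set a certified sub-threshold
  set and the filter idempotent.
* **Ties.** Altloc ties resolve to the alphabetically first conformer;
  interface-element ties cannot occur in exact arithmetic and are broken
  by `which.max`'s first-wins rule.
* **Determinism.** The only stochastic steps (global fixture rotations,
  alignment mutation) draw from an explicitly seeded generator whose seed
  is recorded in the ground truth; RNG state is saved and restored so the
  generators never disturb a caller's seed.

## Problem sizes

The shipped analysis and test surface run on one CPU: monomers of ~130
residues (~600 atoms), dimers of ~1200 atoms, a 24-configuration dimer
grid, 321-record alignments of 60 columns, and SASA at 960 points/atom
(480 in some invariance checks, where only differences matter). These
sizes keep every stage's behaviour visible at full parameter defaults.

## Known limitations

* The space-group table covers the common sohncke groups; rarer groups
  require REMARK 290 records in the input file (deposited PDB entries
  carry them).
* Sheet-order computation rejects barrels and fused (branched) sheets by
  design; the screen then reports `other_interface` for such chains.
* The alpha1/alpha2/alpha3 labelling rule assumes the canonical PAS
  element order; circularly permuted folds would mislabel.
* `parallel` is judged on one axis per chain; strongly bent alpha1
  helices would blur the directed angle.
* Stockholm parsing reads sequence lines only (annotations ignored).
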