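---
title: "Counting the noncovalent interactions of backbone carbonyl oxygens"
author: "carbonylNCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting the noncovalent interactions of backbone carbonyl oxygens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonylNCI)
```

## The question and the model

An sp² carbonyl oxygen presents two lone pairs of electrons. In the
unfolded state both are hydrogen-bonded to water, so a folded protein that
satisfies only one of them — the single C=O⋯H–N hydrogen bond of the
textbook α-helix or β-sheet — leaves free energy on the table. This
package counts, for every backbone carbonyl oxygen, all the noncovalent
interactions (NCIs) that could satisfy those lone pairs:

* **NH_bb / NH_sc** — hydrogen bonds from backbone or side-chain N–H;
* **OH_sc** — from Ser/Thr/Tyr hydroxyls;
* **CαH / CH_X** — weak hydrogen bonds from α-carbon or side-chain C–H;
* **HOH** — hydrogen bonds from explicit water;
* **n→π\*** — donation of an oxygen lone pair into the π\* orbital of a
  neighbouring carbonyl carbon (mainchain, or the Asn/Gln side-chain amide,
  reported as `npistar_sc`).

Each interaction is purely geometric: no energies are computed, and a
residue's score is simply the multiset of interactions its carbonyl oxygen
makes. The working hypothesis embedded in the statistics is that a fully
satisfied carbonyl makes **two** NCIs, one per lone pair.

## Geometric criteria and their free parameters

All criteria live in `nci_thresholds()` and every cutoff is inclusive.

| parameter | default | meaning |
|---|---|---|
| `d_NH_max` | 2.44 Å | H⋯O distance cutoff, N–H donors |
| `d_OH_max` | 2.31 Å | H⋯O cutoff, hydroxyl and water donors |
| `d_CH_max` | 2.68 Å | H⋯O cutoff, C–H donors |
| `omega_min` | 90° | donor linearity ∠(X–H⋯O) |
| `rho_min` | 90° | acceptor approach ∠(H⋯O=C) |
| `elevation_max` | 50° | out-of-plane limit, C–H donors only |
| `d_npistar_max` | 3.22 Å | O⋯C distance, n→π\* |
| `theta_min`, `theta_max` | 95°, 125° | Bürgi–Dunitz window ∠(O⋯C=O) |
| `chi_min` | 120° | planarity torsion about the donor C=O |
| `water_contact_max` | 3.5 Å | water-exposure radius for the water rule |
| `prefilter` | 5 Å | heavy-atom candidate prefilter |

The distance cutoffs are electron-density-topology-derived van-der-Waals
style limits per donor class; the angular floors at 90° merely exclude
geometries where the hydrogen points away from the oxygen or the approach
is behind the carbonyl.

Three criteria are genuinely underdetermined by their usual one-line
statements, and we fixed them as follows:

* **ω and ρ.** ω is measured at the hydrogen (donor-heavy–H⋯O) and ρ at
  the acceptor oxygen (H⋯O=C). These are the standard donor-linearity and
  acceptor-approach angles; both are configuration keys.
* **The elevation plane.** For C–H donors the elevation of the hydrogen is
  measured relative to the acceptor's sp² carbonyl plane (Cα, C, O),
  at the oxygen. The criterion limits out-of-plane approach to the π face,
  which is where a C–H contact stops being a lone-pair interaction.
* **The χ torsion.** χ must separate genuine n→π\* approaches from
  geometries that are really hydrogen bonds. We define χ as the magnitude
  of the torsion Cα(donor)–C(donor)–O(donor)⋯C(acceptor): the acceptor
  carbon must approach the donor oxygen in the carbonyl plane, *anti* to
  Cα — i.e. along the in-plane lone pair. On an ideal α-helix the
  canonical O(i)⋯C(i+1) contact measures χ = 155°, comfortably above the
  120° threshold, while candidate definitions that route χ through an
  amide hydrogen measure 36–90° there and would veto the best-attested
  n→π\* in proteins. The atom choice is switchable
  (`chi_mode = "acceptor_amide_h"` restores the hydrogen-based variant).

The published window for θ is printed in a form ("95° ≥ θ ≥ 125°") that no
angle can satisfy; we read it as the closed interval [95°, 125°].

**The water-saturation rule.** A carbonyl whose only qualifying NCIs are
to water (including none at all) *and* that has a water oxygen within
3.5 Å is treated as fully exposed and reported as making exactly two water
hydrogen bonds. This avoids biasing counts by the water model: force-field
water converges on two neighbours per carbonyl anyway, and simulated
proteins tend to be under-solvated. The rule deliberately does **not**
apply to carbonyls with any protein NCI, and a buried, contact-free
carbonyl keeps its honest count of zero.

## Secondary structure

`assign_ss()` implements a Kabsch–Sander core: backbone hydrogen bonds by
the electrostatic energy
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with a bond
below −0.5 kcal/mol; n-turns, helices (two consecutive turns), bridges and
ladders, turns and bends (Cα curvature > 70°), with priority
H > E > B > G > I > T > S. Labels collapse to six classes — α-helix,
β-strand (E and B merged), 3₁₀/π, turn, bend, none — and `little_h` marks
the first and last turn of each helix, the context for the capping motifs.
We do not reimplement any particular assignment program verbatim; on ideal
fixtures the interior labels match the generating template, which is the
property the statistics need. By default secondary structure is assigned
once on the reference structure and reused across snapshots (the
statistics group dynamics by the reference assignment);
`run_ensemble(ss_mode = "per_snapshot")` reassigns per snapshot and takes
each residue's modal class instead.

## Ensembles, topology, and the statistics

Snapshot ensembles (multi-MODEL PDB, a directory of PDBs, or
`perturb_ensemble()` output) are inventoried per snapshot into a complete
residue × snapshot count matrix. Connectivity is captured **once** on the
reference structure (`structure_topology()`) and reused for every
snapshot: distance-based bond inference would randomly drop sites and
donors under coordinate noise, whereas real trajectory snapshots never
change topology. Statistics provided:

* the four count distributions (static; pooled residue-snapshots; modal
  averages; pooled cells of residues with ≥ 50% occupancy at their mode);
* NCI combination frequencies per secondary-structure class, pooled
  per-snapshot for the 2-NCI bulk and modal+occupancy-filtered for the
  1- and 3-NCI tails (the "at least half" occupancy threshold is
  inclusive, ≥ 0.5);
* NCI density (mean count per residue-snapshot, overall or per class) and
  hydrogen bonds per residue (NH/OH/water donors only);
* sustained-motif detection, bifurcated-hydrogen-bond fractions (pooled
  per-snapshot by default; a distinct-bond variant is available because
  the pooling convention is a genuine choice), and the sub-van-der-Waals
  contact scan for 1-NCI residues (O⋯H(N) of the same residue and
  O⋯Hα of the next; in the extended conformation these measure 2.59 and
  2.39 Å, inside the 2.72 Å vdW sum, while in helices the same-residue
  contact is 4.3 Å).

Ties in the modal count break to the **smaller** value, so
over-satisfaction is never inflated by a tie. Combination identity is the
unordered multiset of NCI types; partner identity is kept in the records
but ignored by the combination keys. A water-rule residue contributes the
combination {HOH, HOH}.

## The synthetic generator

`build_peptide()` constructs ideal-geometry peptides from internal
coordinates (N–Cα 1.46, Cα–C 1.52, C–N 1.33, C=O 1.23 Å, ω = 180°,
amide H in the peptide plane anti to the carbonyl, tetrahedral Hα and
side-chain hydrogens, L-configuration verified against real structures) at
canonical φ/ψ: α (−57, −47), 3₁₀ (−49, −26), antiparallel (−139, 135),
parallel (−119, 113), or custom. Sheets are two strands on one chain
(residue numbering leaves a gap); strand B is placed by a deterministic
rigid-body fit that realises the canonical hydrogen-bond registry —
alternating pairs, because the pleat points every other residue away from
the partner strand — reaching d(H⋯O) ≈ 1.95 Å at near-linear ω. Methyl
rotors, which are essentially free, are set to the rotamer that maximally
clears nearby carbonyl oxygens so each template recovers exactly its
designed interaction pattern. `solvate_carbonyls()` plants waters along
the in-plane lone-pair directions (d(H⋯O) = 1.9 Å, donor angle ≈ 165°,
clash-checked), and `perturb_ensemble()` adds seeded i.i.d. Gaussian
coordinate noise — an occupancy model, not physics: it reproduces the
*statistical* fluctuation of interaction counts without torsional
correlations, solvent dynamics, or realistic energetics.

What passing tests on these fixtures shows, therefore, is that the
classifiers, counters and miners are correct on known ground truth — not
that any particular protein behaves like the fixtures. Real structures
add disorder, missing hydrogens, non-ideal geometry and genuinely
ambiguous contacts that only enter through the thresholds.

Motif fixtures are hand-tuned but chemically grounded: the over-satisfied
mid-helix cluster places a threonine methyl by a χ1 rotamer search; the
bifurcated N-terminal cluster uses a uniform crankshaft at
(φ, ψ) = (−49, −50) — a whole corridor φ + ψ ≈ −99° admits both the i+3
and i+4 amide bonds while keeping the i+1 n→π\*; the C-terminal cap puts
a serine at the last helix position with its hydroxyl rotamer
(χ1 ≈ −60°) reaching the i−4 carbonyl. The searches are 5°-grid,
deterministic, and re-verified through the classifier every time.

## Numerical choices and degenerate inputs

* Dihedrals and the elevation are reported as magnitudes; every threshold
  is one-sided. Degenerate geometry (zero-length arms, collinear plane
  atoms) raises an error rather than returning a value.
* Alternate locations keep the highest-occupancy conformer, ties to
  altLoc "A". C-terminal carboxylates are not carbonyl sites (the
  inventory concerns amide carbonyls); incomplete residues are skipped.
* Hydrogens attach to heavy atoms by distance (≤ 1.2 Å), not by name, so
  both PDB v2 and v3 hydrogen dialects work. Waters without hydrogens are
  excluded from donor detection and counted, since the water criterion is
  measured at the water hydrogen — exposure is then underestimated and
  the count is the user's warning.
* The 5 Å candidate prefilter can never change results: the largest
  distance cutoff plus the covalent X–H offset is 3.88 Å, and the
  constructor refuses prefilter radii that violate this margin. The test
  suite additionally verifies exact agreement with a no-prefilter
  brute-force sweep over 50 random structures.
* One NCI per donor group per carbonyl (the best hydrogen), but a donor
  group may bond two different carbonyls — that is precisely a bifurcated
  hydrogen bond. Categories are not mutually exclusive: an oxygen may
  accept hydrogen bonds and donate n→π\* simultaneously, which is what
  the 3-NCI clusters require.
* Interchain contacts are classified and labelled `interchain`; the
  intended inputs are single chains.

## Problem sizes

The shipped tests and the acceptance script run on 6–20-residue fixtures,
ensembles of 5–20 snapshots, and 50-structure random sweeps; a full run of
both takes about a minute and a half on one CPU. These sizes are chosen
because every property being checked — designed-pattern recovery, oracle
equivalence, occupancy statistics, motif closure — is scale-free: the
classifiers are strictly per-pair, so nothing new is learned above the
size where every interaction class and context occurs.

## Known limitations

* No mmCIF input, no hydrogen placement: structures must carry explicit
  hydrogens (ultra-high-resolution crystallography or simulation output).
* The Gaussian ensemble model cannot produce correlated events such as
  concerted secondary-structure changes; occupancy statistics under it are
  a lower bound on realism.
* The ideal flat antiparallel sheet leaves the cross-strand Cα–H⋯O
  contact at 2.72 Å, just outside the 2.68 Å cutoff — real (twisted)
  sheets do form it. Fixture tests therefore assert the NH_bb registry
  only.
* Energies are never estimated; an NCI is a geometric classification, and
  counts weight a water hydrogen bond and a methyl C–H contact equally.
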