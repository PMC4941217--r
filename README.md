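# carbonylNCI

Noncovalent interactions (NCIs) of protein backbone-carbonyl oxygen atoms.

Every backbone carbonyl oxygen is sp²-hybridised and carries **two lone
pairs**, yet textbook depictions of α-helices and β-sheets satisfy it with a
single C=O⋯H–N hydrogen bond. `carbonylNCI` inventories *all* the
interactions those oxygens make — conventional hydrogen bonds from backbone
and side-chain N–H, side-chain O–H and water; weak Cα–H and side-chain C–H
hydrogen bonds; and n→π\* donation of an oxygen lone pair into the π\*
orbital of a neighbouring carbonyl carbon — and asks whether both lone pairs
are satisfied, per residue, per snapshot.

## Who this is for

Structural bioinformaticians and protein designers who want per-residue,
secondary-structure-resolved counts of carbonyl NCIs in hydrogen-bearing PDB
structures or snapshot ensembles, and who want the under-/over-satisfied
outliers (bifurcated hydrogen bonds, helix-capping clusters) mined
automatically.

## Operational definitions

A donor hydrogen H bonded to heavy atom X makes a hydrogen bond to a
carbonyl oxygen O=C when

* d(H⋯O) ≤ 2.44 Å for N–H donors, ≤ 2.31 Å for O–H and water donors,
  ≤ 2.68 Å for C–H donors;
* ω = ∠(X–H⋯O) ≥ 90° and ρ = ∠(H⋯O=C) ≥ 90°;
* for C–H donors, H approaches within 50° of the sp² carbonyl plane.

A carbonyl oxygen O donates n→π\* into an acceptor carbonyl carbon C′ when
d(O⋯C′) ≤ 3.22 Å, the Bürgi–Dunitz-type angle θ = ∠(O⋯C′=O′) lies in
[95°, 125°], and the planarity torsion χ about the donor C=O bond is ≥ 120°
(the acceptor approaches in-plane, anti to Cα — along the in-plane lone
pair). A carbonyl whose only qualifying NCIs are to water is considered
fully exposed and is reported as making exactly **2** water hydrogen bonds,
one per lone pair (the water-saturation rule). All cutoffs are inclusive
and configurable via `nci_thresholds()`.

Ensembles are summarised by the per-residue **modal** NCI count, the
**occupancy** at that mode, and four count distributions (static,
per-snapshot, modal, and occupancy-filtered). Sustained 1-NCI and 3-NCI
residues are matched against named motifs: mid-helix
NH_bb + n→π\* + CH_X; helix N-terminal bifurcated 2×NH_bb (i+3, i+4) +
n→π\*; helix C-terminal NH_bb + Ser/Thr OH_sc + n→π\*; strand
NH_bb + CαH + water.

## Worked example

```r
library(carbonylNCI)

# an ideal 20-residue poly-Ala alpha helix with explicit hydrogens
helix <- build_peptide("alpha_helix", n_res = 20)
inv   <- inventory_structure(helix)
inv
#> <nci_inventory> synth_alpha_helix snapshot 0: 19 carbonyls, 34 records
#>
#>   NH_bb npistar
#>      16      18
summary(inv)$count_distribution
#>  0  1  2
#>  1  2 16
```

Sixteen of the 19 carbonyls make exactly two NCIs — one NH_bb hydrogen bond
from the i+4 amide plus one n→π\* to the i+1 carbonyl, the canonical fully
satisfied helix pair. The stragglers are the C-terminal carbonyls whose
i+4 partner does not exist.

```r
# solvate the exposed carbonyls, perturb into a 20-snapshot pseudo-ensemble
wet   <- solvate_carbonyls(helix, per_site = 2, seed = 1)
snaps <- perturb_ensemble(wet, sigma = 0.08, n = 20, seed = 1)
topo  <- structure_topology(helix)
invs  <- lapply(snaps, inventory_structure, topology = topo)
ei    <- ensemble_from_inventories(invs, ss = assign_ss(helix))
nci_distributions(ei)
#> Percentage of carbonyls making x NCIs:
#>                            0    1    2   3
#> static                   0.0 15.8 84.2 0.0
#> per_snapshot             1.3 26.1 66.1 6.6
#> modal                    0.0 10.5 89.5 0.0
#> modal_occupancy_filtered 1.3 26.1 66.1 6.6
nci_density(ei)        # 1.78 mean NCIs per residue-snapshot
hbonds_per_residue(ei) # 0.99 excluding weak C-H bonds and n->pi*
```

The modal row says ~90% of carbonyls are fully satisfied most of the time
even as individual snapshots fluctuate. `run_static()` and `run_ensemble()`
wrap these stages end to end and write TSV/JSON reports plus a hashed
manifest; `find_motifs()`, `bifurcation_fraction()` and `subvdw_scan()`
mine the outliers.

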