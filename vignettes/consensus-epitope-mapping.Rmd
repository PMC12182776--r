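---
title: "Consensus epitope mapping from antibody-antigen docking ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus epitope mapping from antibody-antigen docking ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimap)
```

## The problem

Protein-protein docking of an antibody against its antigen returns not one
answer but a ranked ensemble of candidate poses, and for flexible binders
such as antibodies the top-scored pose is frequently wrong. Rather than
trusting any single model, `epimap` treats the ensemble statistically: a
receptor residue that appears in the binding interface of many independent
poses is a better epitope candidate than one that appears in few. The
package takes a ranked pose ensemble (e.g. from a swarm-based docking
server), standardizes all poses into one receptor frame, extracts
interface residues per pose, and aggregates them into per-residue contact
frequencies from which consensus epitope lists and spatially clustered
candidate binding sites are derived.

The motivating application is epitope mapping for anti-HER2 monoclonal
antibodies docked against several structural models of the HER2
extracellular domain, but nothing in the code is specific to that system:
any receptor chain plus any set of ligand chains works.

## The procedure

For each docking combination (one antibody x one receptor model):

1. **Standardization.** The receptor of the top-ranked pose defines a
   common frame; every other pose is rigidly superposed onto it via a
   sequence-alignment-guided Kabsch fit on CA atoms
   (`standardize_ensemble()`). Because the transform is rigid, every
   intra-pose distance — and hence every contact — is exactly preserved;
   standardization only aids visual comparison and shared annotation.
2. **Interface extraction.** A receptor residue is an *interface residue*
   of a pose when at least one heavy atom lies within 2.5 Å (inclusive) of
   any heavy ligand atom (`contact_residues()`). Separately,
   *intermolecular contacts* are receptor-ligand residue pairs closer than
   5.5 Å (strict), typed by the side-chain polarity of both partners
   (`intermolecular_contacts()`).
3. **Per-pose interaction reports.** For the best few poses (default 5)
   the package also reports geometric hydrogen bonds, salt bridges, and a
   contact-based binding-affinity estimate (`report_pose()`).
4. **Consensus.** Over the top `n_models` poses (default 100), each
   residue's contact frequency is the number of poses in which it is an
   interface residue — binary membership per pose, so the count is bounded
   by the number of models (`contact_frequencies()`). The 20 most frequent
   residues per combination, residues with frequency ≥ 20 pooled across
   combinations, Venn overlaps of the top-pose interface sets, and a
   cross-combination shared-residue matrix summarize the ensemble
   (`top_residues()`, `threshold_consensus()`, `venn_regions()`,
   `shared_top_matrix()`).
5. **Binding-site nomination.** Consensus residues are clustered by
   single-linkage on CA-CA distances at 15 Å; connected components are the
   candidate binding sites (`spatial_groups()`). Frequencies are also
   written into B-factors for white-to-red rendering
   (`annotate_frequencies()`).

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `residue_cutoff` | 2.5 | Å | interface-residue rule, inclusive (≤) |
| `imc_cutoff` | 5.5 | Å | intermolecular-contact rule, strict (<) |
| `n_models` | 100 | poses | consensus depth |
| `top_k` | 20 | residues | most-frequent list size |
| `min_frequency` | 20 | poses | threshold-consensus membership |
| `linkage_cutoff` | 15 | Å | CA-CA single-linkage connection |
| H-bond cutoff | 3.5 | Å | donor-acceptor heavy-atom distance |
| salt-bridge cutoff | 5.5 | Å | charge-center distance |
| `cycles`, `sigma_cut` | 5, 2.0 | - | superposition outlier rejection |

Boundary semantics are deliberate: the interface rule is inclusive at
2.5 Å while the contact rule is strict at 5.5 Å, matching the wording of
the respective conventions; both are configurable. Distances are measured
between heavy atoms only by default, because docking inputs derived from
electron-microscopy structures carry no reliable hydrogens; consequently
the hydrogen-bond criterion is distance-only on donor and acceptor heavy
atoms rather than angle-aware.

The 15 Å linkage cutoff deserves a comment. Visual grouping of residues
on a structure is common practice but irreproducible; we replace it with
an explicit, deterministic procedure (single-linkage connected
components). 15 Å on CA atoms merges residues within roughly two
side-chain lengths plus backbone breathing — adjacent surface patches —
while keeping sites on different subdomains separate. Group counts are a
*sensitivity output*, not an invariant: users should vary the cutoff and
report the stability of the partition.

Histidine is classed as charged and tryptophan as polar (the convention
of contact-based affinity models); both assignments are switchable in
`classify_residue()` and the salt-bridge detector because published class
tables disagree on them.

## The affinity model

The binding free energy is a linear model over typed contact counts plus
the polar/apolar composition of the non-interacting surface (NIS):

dG = b0 + sum_c w_c * IC_c + w_a * %NIS_apolar + w_q * %NIS_charged

where `IC_c` counts contacts of unordered class pair `c` in {cc, cp, ca,
pp, pa, aa}. The shipped default coefficients are those of the published
contact-based model of Vangone & Bonvin (2015); the model is fully
config-driven (`affinity_config()`) because no single coefficient set
suits every system. The dissociation constant follows from
Kd = exp(dG / RT) with R = 1.9872e-3 kcal/(mol K) and T = 298.15 K
(25 °C) by default; `dG_to_Kd()` and `Kd_to_dG()` are exact inverses.
`correlate()` reports Pearson r and r² to relate dG to contact counts and
docking scores across a report collection.

NIS residues are those with relative SASA above 5 % of the residue's
theoretical maximum in the bound complex — the conventional
buried/exposed boundary. SASA is computed by the Shrake-Rupley method on
a deterministic golden-spiral point lattice (960 points per atom by
default) with element vdW radii C 1.70, N 1.55, O 1.52, S 1.80 Å. One
numerical convention is worth noting: a test point lying exactly on a
neighboring sphere's surface (within 1e-6 Å) counts as half-exposed, so
two coincident identical spheres each report exactly half their isolated
area instead of an arbitrary all-or-nothing split.

## Superposition details

`kabsch()` solves the least-squares rigid superposition by SVD with the
determinant correction that excludes reflections; collinear point sets
are flagged as degenerate. `superpose_structures()` first aligns the
chain sequences globally (BLOSUM62, gap open 10, extend 0.5), fits the
matched CA pairs, then iteratively rejects pairs deviating by more than
`sigma_cut` standard deviations of the current cycle's deviations and
refits, up to `cycles` rounds — mirroring the widely used `align`
behavior of molecular viewers. RMSD is reported over surviving pairs;
rejection never increases it between cycles. The fit is CA-only by
default; all-atom RMSD of two structures can be obtained directly with
`rmsd_coords()` after transformation.

## What the synthetic generator emulates — and what it does not

`make_receptor()` builds a deterministic coarse fold: a CA trace on a
gentle open helix with exact 3.8 Å virtual bonds, minimal backbone (N, C,
O) and a CB placeholder, numbered from residue 23 (the first residue
after a cleaved signal peptide, matching ectodomain conventions). The
fold is chosen so that sequence separation maps onto spatial separation,
making chain-contiguous epitope patches compact and mutually distant —
exactly the property the spatial-grouping stage needs to be testable.

`make_ensemble()` plants contacts geometrically: in each pose every
epitope residue receives a ligand pseudo-atom at a sampled distance
inside the 2.5 Å rule (on the solvent-facing side) with probability 0.3,
and every background residue with probability 0.02; the default epitope
is two 12-residue patches plus one 3-residue patch. Ligand atoms
alternate between two chains so every pose carries a two-chain antibody
stand-in. Scores are monotone decreasing in rank but — by default —
carry no information about contact truth, reflecting the empirical
observation that docking scores and contact-based affinity estimates can
be essentially uncorrelated; `couple_scores = TRUE` links them for power
studies.

Passing tests on this generator demonstrates that the *pipeline
arithmetic* is correct end to end through real distance computation: the
statistics, the geometry, the clustering, the bookkeeping. It does not
demonstrate that real docking ensembles concentrate contacts on true
epitopes — that property belongs to the docking engine, not to this
package — nor does the toy fold capture side-chain packing, glycans,
disordered loops, or realistic antibody geometry.

`make_complex_with_bonds()` builds isolated interaction sites on a wide
grid: donor-acceptor pairs inside 3.5 Å, basic-acidic charge-center
pairs inside 5.5 Å (cycling Lys/Arg/His), and near-miss decoys at 3.55
and 5.55 Å, giving the detectors exact planted ground truth.

## Degenerate inputs and tie-breaks

* Top-k lists break count ties by ascending residue number, then chain
  id; residues excluded only by the tie-break at the k-th count are
  returned in the `boundary_ties` attribute rather than silently dropped.
* Consensus residues absent from the grouping reference (disordered
  gaps) are excluded with a warning and listed in the `missing`
  attribute, never fatal.
* Charged residues with missing side-chain atoms are skipped by the
  salt-bridge detector with a warning.
* Requesting more consensus models than poses counts over all available
  poses with a message, since server-limited ensembles are common.
* Alternate locations resolve to the highest occupancy (ties to the
  first conformer); waters are always excluded, other heteroatoms
  optionally retained.
* Zero-variance inputs to `correlate()` return an explicit `NA`, not NaN.

## Problem sizes used in the shipped checks

The packaged tests and the reproduction script run entirely on synthetic
data: 100 random 40-residue/12-residue complexes for the contact-search
equivalence check, twenty 200-residue ensembles of 100 poses each for
planted-epitope recovery, 50 random point sets for the
quaternion-vs-Kabsch comparison and 1000 random 5-set families for the
Venn partition check. These sizes give stable statistics while keeping a
full run within a few minutes on one CPU.

## Known limitations

* The affinity model is a linear contact model; it ranks poses by
  interface size and composition and should not be read as a calibrated
  absolute affinity for any particular system.
* Hydrogen bonds are distance-only when hydrogens are absent; no
  hydrogen placement is attempted, so bifurcated or angle-strained
  geometries are not distinguished.
* π-stacking, cation-π, halogen bonds and water-mediated bridges are out
  of scope; only hydrogen bonds and salt bridges are detected.
* Cross-combination comparisons match residues by chain and author
  number; receptor models must share a numbering scheme.
* mmCIF files and nucleic acids are not supported.
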