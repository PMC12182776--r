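# epimap

Consensus epitope mapping from antibody-antigen docking ensembles.

## What this package is for

Docking an antibody against its antigen yields a ranked ensemble of
candidate poses, and for flexible binders the single best-scored pose is
often wrong. `epimap` analyzes the whole ensemble instead: it extracts the
receptor residues in the binding interface of every pose and aggregates
them into per-residue **contact frequencies**, nominating as epitope
candidates the residues that recur across many independently generated
models. It is aimed at structural bioinformaticians doing post-docking
analysis of antibody-antigen (or any receptor-ligand) pose ensembles, for
example epitope mapping of anti-HER2 monoclonal antibodies against several
structural models of the HER2 extracellular domain.

## The statistic at its core

For an ensemble of poses ranked 1..N (default N = 100) and a distance
cutoff d (default 2.5 Å, heavy atoms, inclusive), the contact frequency of
receptor residue *i* is

f_i = #{ poses m ≤ N : min distance from residue i to any ligand atom in pose m ≤ d },

a binary per-pose membership count, so 0 ≤ f_i ≤ N. From the frequency
table the package derives the top-20 residue list per docking combination,
threshold-consensus sets (f_i ≥ 20) pooled across combinations, Venn
overlaps of the top-pose interface sets, cross-combination shared-residue
matrices, and spatial groups of consensus residues (single-linkage
connected components on Cα-Cα distances at 15 Å) — the candidate binding
sites.

Around this core the package provides the supporting machinery of a full
post-docking workflow: PDB reading/writing with chain surgery,
sequence-alignment-guided Kabsch superposition with iterative outlier
rejection, typed intermolecular contacts at 5.5 Å, geometric hydrogen-bond
and salt-bridge detection, Shrake-Rupley solvent-accessible surface area,
and a configurable contact-based linear model for binding free energy with
Kd = exp(ΔG/RT) conversion at 25 °C. A synthetic-data module generates toy
receptors and ensembles with planted epitopes so every stage can be
validated end to end without downloads.

## Worked example

A synthetic docking combination under the package's default study
conditions: a 200-residue receptor, 100 ranked poses, a planted epitope of
two 12-residue patches plus one 3-residue patch contacted with probability
0.3 against a 0.02 background.

```r
library(epimap)

cfg      <- sim_config(seed = 42)
receptor <- make_receptor(cfg)
ensemble <- make_ensemble(receptor, cfg)
ensemble
#> <docking_ensemble synthetic-seed42> 100 poses, receptor A, ligand H/L

bundle <- run_combination(
  ensemble,
  consensus = consensus_config(n_models = 100, top_k = 20, min_frequency = 20),
  n_reports = 5, sasa_points = 240)

head(bundle$frequency_table$counts, 5)
#>     key chain resno insert resid count
#> 1  A:67     A    67          VAL    40
#> 2  A:71     A    71          ILE    39
#> 3 A:127     A   127          PRO    37
#> 4 A:126     A   126          PHE    36
#> 5  A:63     A    63          TRP    34
```

Residue A:67 was an interface residue in 40 of the 100 models — the most
consistent contact in this ensemble. The five top-ranked poses get deep
interaction reports (contacts at both cutoffs, hydrogen bonds, salt
bridges, and the contact-based affinity estimate):

```r
bundle$report_table[, c("rank", "dG", "Kd", "imc_total", "n_hbonds", "n_salt_bridges")]
#>   rank         dG           Kd imc_total n_hbonds n_salt_bridges
#> 1    1  -9.367879 1.359197e-07        36        0              0
#> 2    2  -8.650294 4.563276e-07        33        0              0
#> 3    3  -7.037385 6.943045e-06        21        0              0
#> 4    4  -7.843140 1.782076e-06        27        0              0
#> 5    5 -10.521926 1.938019e-08        45        0              0

bundle$correlations
#>    x                  y           r         r2 n
#> 1 dG          imc_total -0.99711198 0.99423230 5
#> 2 dG n_contact_residues -0.99711198 0.99423230 5
#> 3 dG           ld_score -0.06537499 0.00427389 5
```

Predicted binding energy tracks the number of intermolecular contacts
almost perfectly (r² ≈ 0.99, more contacts → more negative ΔG → smaller
Kd) but is essentially unrelated to the docking score (r² ≈ 0.004), which
by design carries no information about the planted contacts. Spatial
grouping of the consensus residues recovers the three planted patches:

```r
for (g in bundle$groups)
  cat(sprintf("group %s: %d residues (%s)\n", g$label,
              nrow(g$members), paste(range(g$members$resno), collapse = "-")))
#> group I: 12 residues (63-74)
#> group II: 12 residues (123-134)
#> group III: 3 residues (183-185)

truth <- attr(ensemble, "truth")
top   <- top_residues(bundle$frequency_table, 27)
sum(truth$epitope_keys %in% top$key)
#> [1] 27
```

All 27 planted epitope residues sit in the top 27 of the frequency table.
`run_combination(..., out_dir = "out/")` additionally writes
`frequencies.tsv`, `top20.tsv`, `interface_reports.tsv`, `venn.json`,
`groups.tsv`, a frequency-annotated `frequency_map.pdb` (counts in the
B-factor column for white-to-red rendering) and a `manifest.json`
recording every parameter. `compare_combinations()` then builds the
cross-combination overlap matrix and pooled consensus unions.

For real data, build the ensemble from a directory of pose PDBs plus a
`scores.tsv` (columns `rank`, `score`, `filename`) with
`read_ensemble(dir, receptor_chain, ligand_chains)`; use `read_pdb()` /
`drop_chains()` to prepare receptor models (e.g. removing a dimerization
partner or bound antibodies from a deposited complex).

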