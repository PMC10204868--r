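# ebdiff

Energy-breakdown differencing for protein design triage.

Designed multi-mutant proteins are cheap to generate and expensive to test.
`ebdiff` compares the per-residue energy decomposition of a designed mutant
against its reference structure and answers three questions a designer
asks before picking mutants for the bench: **what changed** (every gained,
lost or altered pairwise interaction, classified into six categories),
**how much and what kind** (per-score-term deltas in Rosetta Energy Units,
salt bridges / disulfides / hydrogen-bond classes, total versus significant
sums), and **where** (per-residue net energy joined with residue depth
below the molecular surface, separating surface effects from core
effects).

## The model in brief

Inputs are two energy-breakdown score tables (one-body rows per residue,
two-body rows per interacting pair, split into named score terms with a
`total` in REU) plus the two PDB structures, cleaned and renumbered 1..N.
Writing Δ*E*(i,j) = *E*mut(i,j) − *E*ref(i,j) with a missing side counted
as zero, every pair in the union of the two tables is assigned one of:

| | interacts in ref | interacts in mut | mutated member |
|---|---|---|---|
| **A** | yes | yes, ΔE ≠ 0 | no |
| **B** | yes | yes, ΔE ≠ 0 | yes |
| **C** | yes | no | no |
| **D** | yes | no | yes |
| **E** | no | yes | no |
| **F** | no | yes | yes |

The **total** energy change is ΣΔE over selected categories; the
**significant** change keeps only |ΔE| > 1.0 REU (strict), the scale at
which individual changes are chemically meaningful rather than noise.
Physical types are read off the term decomposition (e.g. a salt bridge =
opposite formal charges + active side-chain hydrogen-bond term). Residue
depth is computed from a deterministic dot surface (probe 1.5 Å, 960
samples/atom, orientation-covariant local sampling frames) as the mean
heavy-atom distance to the nearest surface point.

No energies are computed from coordinates: the package post-processes
decompositions produced elsewhere, and ships a synthetic generator with
planted ground truth so the entire pipeline is testable offline.

## Worked example

Everything below is synthetic: a 120-residue protein with 10 point
mutations and 175 planted interaction changes.

```r
library(ebdiff)

plan <- fixture_plan(n_residues = 120, n_mutations = 10, seed = 42)
mock <- make_mock_breakdown(plan)

ref <- parse_breakdown(mock$ref_lines, source_label = "reference")
mut <- parse_breakdown(mock$mut_lines, source_label = "mutant")
ref
#> energy_table: 120 one-body + 145 pair records, 9 score terms (reference)
#>  grand total: -174.886 REU

muts <- detect_mutations(mock$truth$sequence_ref, mock$truth$sequence_mut)
d <- diff_tables(ref, mut, muts)
d
#> diff_result: 175 changed pairs, 10 one-body changes, 10 mutations
#>  categories: A=40 B=30 C=25 D=25 E=25 F=30
#>  significant (|delta| > 1 REU): 110 pairs, sum 14.93 REU
```

110 of the 175 changes exceed the ±1 REU significance threshold and their
sum is +14.9 REU — this particular synthetic "design" is net
destabilizing. The category-by-type grid of significant changes (the
summary a designer scans first):

```r
summary_table(d)$counts
#>   salt_bridge disulfide hb_sc_sc hb_bb_sc hb_bb_sr hb_bb_lr all
#> A           0         1        0        1        2        3  25
#> B           1         0        3        2        1        0  18
#> C           1         1        3        1        0        1  18
#> D           0         0        0        0        0        0  15
#> E           2         0        3        1        1        2  16
#> F           0         0        0        0        0        0  18
```

Drill into one slice — salt bridges newly formed in the mutant (categories
E and F):

```r
sig <- significant_changes(d, categories = c("E", "F"), types = "salt_bridge")
sig$sum
#> [1] -3.5522
sig$changes[, c("resi1", "resi2", "restype_mut1", "restype_mut2",
                "category", "delta_total")]
#>   resi1 resi2 restype_mut1 restype_mut2 category delta_total
#> 1    87   110          GLU          HIS        E     -2.3389
#> 2    84   107          LYS          ASP        E     -1.2133

per_term_breakdown(d, 87, 110)
#>       term   delta
#> 1   fa_rep  0.0057
#> 2   fa_sol  0.0020
#> 3 hbond_sc -2.3466
```

Two new ion pairs contribute −3.55 REU of stabilization, both dominated by
the side-chain hydrogen-bond term, and neither residue was itself mutated
(category E — an indirect effect of nearby mutations). Depth analysis and
CSV reports follow the same pattern: `residue_depth()`,
`depth_energy_join()`, `full_report()`.

A command-line wrapper covers the shell workflow (`exec/ebdiff` after
installation, or `run_cli()` in R): subcommands `clean`, `diff`, `depth`,
`simulate`, `version`; exit codes 0 ok / 1 usage / 2 parse / 3 mismatch /
4 I/O.

```sh
ebdiff simulate --n-residues 60 --n-mutations 6 --seed 7 --out-dir fx
ebdiff diff --ref-pdb fx/ref.pdb --mut-pdb fx/mut.pdb \
            --ref-eb fx/ref_eb.out --mut-eb fx/mut_eb.out --out-dir out
```

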