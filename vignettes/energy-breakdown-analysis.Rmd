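---
title: "Classifying interaction-energy changes between a designed mutant and its reference"
author: "ebdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying interaction-energy changes between a designed mutant and its reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebdiff)
```

## The problem

Computational protein design routinely produces tens to hundreds of
candidate multi-mutants, and experimental testing is the bottleneck.
A useful triage signal is the *energetic* effect of the mutations: which
pairwise residue interactions were gained, lost, or altered, how large the
changes are, what kind of physical contact they correspond to, and where in
the structure (surface or core) they sit. Because the effect of one
mutation depends on the others present (epistasis), the analysis must
compare whole structures, not single point changes.

The inputs are per-residue energy decompositions of the relaxed reference
and mutant structures: for every residue a *one-body* energy (its internal
terms) and for every interacting residue pair a *two-body* energy, each
split into named score terms (attraction, repulsion, solvation,
electrostatics, hydrogen-bond classes, a disulfide term, ...) with a total
in Rosetta Energy Units (REU; for the standard soluble-protein score
function roughly 1 kcal/mol per REU). `ebdiff` consumes these tables — it
never computes energies from coordinates — and produces classified,
quantified differences.

## Interaction categories

Writing "interacting" for "has a pair record with a non-negligible total",
every residue pair in the union of the two tables falls into exactly one
of six categories or is unchanged:

| category | in reference | in mutant | involves a mutated residue |
|----------|--------------|-----------|----------------------------|
| A | yes | yes (energy differs) | no  |
| B | yes | yes (energy differs) | yes |
| C | yes | no  | no  |
| D | yes | no  | yes |
| E | no  | yes | no  |
| F | no  | yes | yes |

C-F capture gained/lost contacts; A and E are *indirect* effects — the pair
itself was not mutated, so the change must be propagated through the
environment. A pair in which *both* members were mutated counts as
mutation-involving (B/D/F); the defining texts only discuss single-member
replacement and never address the case.

Two tolerances operationalize the table. *Presence* (`presence_eps`,
default `1e-9` REU): breakdown calculations omit pairs outside the
interaction graph, so absence from the table is the natural non-interaction
signal, and a recorded total of exactly zero is treated the same way.
*Change* (`change_eps`, default `1e-6` REU): pairs present on both sides
whose totals differ by no more than this are unchanged and receive no
category. Both are exposed as arguments because no published tolerance
exists for either.

## Total versus significant changes

Thousands of tiny deltas can mask the chemically meaningful ones, so two
sums are reported: the **total** energy change (every delta in the selected
categories) and the **significant** change, which keeps only pair deltas
larger than +1.0 REU or smaller than −1.0 REU. The inequalities are strict:
a delta of exactly ±1.0 REU is *not* significant, and the threshold is a
parameter (at threshold 0 the two sums coincide, which the tests assert).
One-body deltas are reported separately and are never run through the
significance filter — the rule is stated for *interaction* (pair) energies.

## Physical interaction types

Types are read off the score-term decomposition of a pair record, not
recomputed from geometry:

* `hb_sc_sc`, `hb_bb_sc`, `hb_bb_sr`, `hb_bb_lr` — the respective
  hydrogen-bond term is negative;
* `disulfide` — both residues CYS and the disulfide term is non-zero;
* `salt_bridge` — one residue basic (ARG/LYS/HIS), the other acidic
  (ASP/GLU), and the side-chain hydrogen-bond term is active. This is an
  operational reconstruction: a charged pair whose side chains form a
  hydrogen-bonded ion pair. Histidine is included in the basic set by
  default because it is frequently protonated in ion pairs;
  `strict_salt_bridge = TRUE` excludes it.
* `all` — every pair.

For pairs present on both sides (categories A/B) the type set is the
*union* of the rule evaluated on each side, so a bond existing in only one
structure is still reported.

## Residue depth

Depth distinguishes surface from core mutations. The package builds a
deterministic solvent-accessible dot surface: every atom is sampled with a
golden-angle spherical lattice at radius (vdW + probe), and points strictly
inside any other atom's expanded sphere are discarded (a `1e-9` boundary
tolerance keeps points lying exactly on a neighboring sphere). A residue's
depth is the mean over its heavy atoms of the distance to the nearest
surface point; hydrogens are excluded for robustness to protonation
differences. Defaults: probe 1.5 Å, 960 samples per atom.

Two properties needed reconciling. Depth should be invariant under rigid
motion of the input coordinates, yet a fixed laboratory-frame sampling
lattice is not; and a single structure-global canonical frame would let a
far-away domain influence local depths. The implementation therefore
expresses each atom's sampling directions in the frame of its own 8 Å
neighborhood (principal axes; eigenvector signs fixed by third moments;
right-handed). Rigid motions rotate every local frame covariantly
(observed invariance ~1e-14 Å) and atoms beyond the cutoff cannot affect a
frame. Exactly symmetric neighborhoods (degenerate principal axes or
vanishing third moments) have no canonical frame and fall back to the
identity, where invariance is only approximate — irrelevant for real
structures, worth knowing for artificial ones.

Two systematic offsets are documented rather than corrected: the
solvent-accessible surface lies roughly one probe radius outside the
solvent-excluded surface that an analytical method would trace, so absolute
depths carry a ~1.5 Å offset (rankings and reference/mutant comparisons are
unaffected); and the depth of any fully exposed atom is exactly
vdW + probe, so depth cannot discriminate *among* fully exposed atoms.

Per-residue **net energy** — the one-body total plus the summed totals of
every pair the residue participates in — is joined with depth for the
net-energy-versus-depth view. By default each pair contributes its full
total to both members (so the sum over residues counts pairs twice);
published per-residue values do not state the convention, so
`half_pair = TRUE` switches to half-shares.

## The synthetic fixture generator

No free implementation of the energy decomposition exists to test against,
so the package carries a generator that *plants* ground truth. A
`fixture_plan()` fixes the study conditions: 120 residues, 10 mutations
(the size of the package's motivating design case), 175 planted changes in
the proportions A=40, B=30, C=25, D=25, E=25, F=30 plus 25 unchanged
distractor pairs — 200 pairs per plan — a type mix dominated by plain
van-der-Waals contacts with ~10% salt bridges and ~30% hydrogen-bond
classes, and 65% significant changes. `make_mock_breakdown()` realizes a
plan as two parseable score files in which every total is constructed as
the sum of its planted terms, and returns independently accumulated grand
totals alongside the labels.

Choices that keep the ground truth exact:

* planted magnitudes are drawn from ±[1.2, 4.0] REU (significant) or
  ±[0.05, 0.9] REU (insignificant) — nothing in [0.9, 1.2], so rounding to
  the four decimals written in the files can never flip a label;
  exact-boundary behaviour at ±1.0 is tested with hand-written tables;
* totals stay ≥ 0.01 REU in magnitude so rounding cannot make a present
  pair look non-interacting;
* typed pairs claim residues no other typed pair uses, so residue-type
  demands (ARG for a salt bridge, CYS for a disulfide, ...) never
  conflict; plain pairs carry no hydrogen-bond or disulfide terms, so they
  can reuse any residue without firing a type by accident;
* a B-category disulfide is planted on the reference side only — the
  mutated endpoint cannot remain CYS — and the union rule still reports
  it;
* one seeded generator stream per plan; no global random state is touched.

What the fixtures do *not* emulate: physically realistic energy
distributions, rotamer-level geometry, correlations between terms, or the
stochastic relax stage that precedes real decompositions. Passing the
planted-recovery tests shows the bookkeeping (presence, mutation flags,
categories, types, sums) is exact; it says nothing about the accuracy of
the underlying energy model, which this package does not implement.

The toy structures serve the geometric tests: `helix` and `extended` give
quick valid PDBs; `ball` packs residues into a sphere along a volumetric
golden-angle spiral (radius ∝ i^(1/3), mean spacing 3.5 Å — a typical
close-packed Cα–Cα distance) with atoms oriented radially, so every
residue sits at a distinct, known burial. Depth tests use homogeneous
poly-ALA sequences on this geometry: composition effects (glycine's
missing CB shifts a residue's mean) are deliberately excluded when the
property under test is geometric. On this fixture the Spearman correlation
between depth and centroid distance is −0.969 at 960 samples per atom
(anti-monotone: buried residues are both deep and central); the magnitude,
not the sign, is the quality measure.

## Parameters at a glance

| parameter | default | unit | meaning |
|-----------|---------|------|---------|
| `threshold` | 1.0 | REU | significance cut, strict inequality |
| `presence_eps` | 1e-9 | REU | below this, a recorded pair is "not interacting" |
| `change_eps` | 1e-6 | REU | below this, a both-sides pair is unchanged |
| `probe_radius` | 1.5 | Å | solvent probe for the dot surface |
| `samples_per_atom` | 960 | – | sphere samples per atom |
| `half_pair` | FALSE | – | halve pair shares in net residue energy |
| `strict_salt_bridge` | FALSE | – | exclude HIS from the basic set |

## Numerical and interface choices

* Residues are renumbered 1..N globally across all chains in file order
  (insertion codes dropped); the renumbered index is the only residue key
  downstream. Per-chain renumbering was the open alternative; global was
  chosen because the analysis treats the structure as one interaction
  graph, and it must be stated to users because multi-chain author
  numbering is lost.
* Sequences of unequal length are rejected, not aligned: the workflow
  compares a design against its template, which shares its length.
* Alternate locations collapse to the highest-occupancy conformer, ties to
  the first listed; only the first model of a multi-model file is read.
* Non-canonical residues in ATOM records (e.g. MSE) are an error, never a
  silent translation.
* Score-term columns are taken verbatim from the file header — nothing is
  hard-coded, so tables from other scoring functions load unchanged; the
  stored totals are never recomputed.
* CSV exports print full precision (`%.17g`) and contain no timestamps, so
  re-reading is bit-exact and repeated runs are byte-identical; run
  metadata (parameters, version, time) lives only in the JSON manifest.
* Output ordering is deterministic: changes ascend by delta (most
  stabilizing first), ties broken by pair key.

## Problem sizes

The test-suite and acceptance workloads are sized for interactive runs:
20 fixture plans of 200 pairs (~4 s for full planted-truth recovery),
and the 60-residue ball at 960 samples per atom (~4 s for surface, depths,
oracle comparison and a rigid-motion recheck). Real use — a few hundred
residues, a few thousand pair records — parses and diffs in seconds; the
dot surface is the most expensive step and scales with atoms × samples ×
local neighbors.

## Known limitations

* Energies are consumed as given: no ΔΔG in physical units, no ensemble or
  dynamics corrections, no statistical testing of changes.
* The salt-bridge and hydrogen-bond rules are term-threshold heuristics;
  they cannot see geometry the score terms do not encode.
* Depth is measured to the solvent-accessible, not solvent-excluded,
  surface (constant ~probe-radius offset), and cannot rank fully exposed
  residues against each other.
* Indels between reference and design are out of scope by construction.
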