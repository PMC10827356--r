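---
title: "PFAS definitions as executable rules: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PFAS definitions as executable rules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pfasdef)
```

## The problem

"PFAS" is not one chemical class but a family of competing boundary
definitions. Regulatory and registry practice has used at least seven
distinct rules: structural definitions built from small fluorinated
substructure units (the OECD 2018 and 2021 definitions, the TSCA 2021
working definition, the EPA PFAS structures list versions, the CCL5
definition) and, more recently, a combined rule that unions substructures
with a molecular-formula fluorine threshold. The same compound can be PFAS
under one rule and not another; constitutional isomers can split under a
purely structural rule while sharing identical formula metrics.

This package encodes those definitions as *data* — substructure patterns,
an optional formula rule, and exclusion filters — evaluated by one engine,
so that definitions can be compared, audited clause by clause, and extended
from a config file.

## The classification model

A definition is a `definition_spec` with fixed combination logic:

> a record is PFAS **iff** (any substructure pattern matches **or** the
> formula rule passes) **and** every exclusion filter passes.

The seven built-ins (`builtin_definitions()`):

* `oecd2021` — at least one *fully fluorinated carbon*: saturated,
  non-aromatic, bearing ≥ 2 fluorines and no attached H, Cl, Br or I.
* `oecd2018` — a perfluoroalkyl moiety of ≥ 3 carbons (`-CnF2n-`) or a
  perfluoroalkylether moiety.
* `tsca2021` — the unit `R-CF2-CF(R')R''`: two bonded saturated carbons,
  the first with ≥ 2 F, the second with ≥ 1 F, no hydrogen attached to
  either (halogen R groups are permitted).
* `pfasstruct_v1` — two adjacent CF2 groups (hydrogen permitted on those
  carbons), gated by formula filters: 4–1000 fluorines, F:C ≥ 0.5, and
  exclusion of charged, radical and isotope-labelled records.
* `pfasstruct_v4` — a six-pattern registry (see the reconstruction note
  below).
* `ccl5` — three units: the TSCA unit, the perfluoroether unit
  `R-CF2-O-CF2-R'`, and the bis-trifluoromethyl quaternary unit
  `CF3-C(CF3)(R)R'`.
* `pfasstruct_v5` — the combined definition: fluorine atom-count fraction
  (hydrogen-free denominator) ≥ 30 % **or** any of four substructures (the
  TSCA unit, adjacent no-H CF2–CF2, the bis-CF3 unit, and `CF2-Q-CF2` with
  Q ∈ {B, O, N, P, S, Si}), excluding free radicals and records without a
  carbon–fluorine bond.

### Formula metrics

Four descriptors drive the formula clauses (`fluorine_metrics()`):

* atom-count fraction excluding hydrogen — the quantity the combined
  definition thresholds at 30 %;
* atom-count fraction over all atoms;
* mass fraction (IUPAC 2021 atomic weights, or integer nucleon masses for
  exact back-of-the-envelope arithmetic);
* fluorine-to-carbon ratio, `NA` for carbon-free formulas.

No rounding happens inside the engine. Report writers round percentages to
one decimal place; comparisons against printed literature integers in the
test suite use a one-percent-point band because printed values mix rounding
and truncation.

### Structure perception

Structures enter as SMILES or V2000 molblocks and are perceived by a
purpose-built reader (see "Scope and limitations"): atoms, bonds, aromatic
flags, formal charges, isotopes, implicit hydrogens from a fixed valence
table, radicals (bracket-atom valence deficit in SMILES, `M  RAD` in
molblocks), and connected components. Every structural predicate is then
computed from a per-carbon profile (`profile_carbons()`): fluorine /
hydrogen / other-halogen neighbour counts, saturation, and carbon
neighbours. The profile is exact by construction:
`n_f + n_h + n_other_halogen + n_other_heavy == n_connections`.

Substructure patterns are parameterised structural kinds
(`pattern_spec()`): `fully_fluorinated_carbon`, `perfluoroalkyl_run`,
`cf2_pair`, `cf2_hetero_cf2`, `bis_cf3`. Each built-in pattern also carries
a SMARTS rendering as a portable annotation; the test suite cross-checks
the native matcher against an OpenBabel SMARTS search on every annotated
pattern, but matching itself never depends on an external toolkit.

### Run lengths

`max_perfluoromethylene_run()` counts the longest chain (or ring) of
consecutive carbons that are saturated, hydrogen- and
other-halogen-free, carry ≥ 2 fluorines, and have only carbon heavy
neighbours besides fluorine. Terminal CF3 carbons satisfy these conditions
and **count toward the run**: perfluorobutanoic acid (CF3–CF2–CF2–COOH) has
run length 3 and therefore meets the OECD 2018 three-carbon threshold, as
standard perfluorocarboxylic acids must. (Under a reading where CF3 termini
are excluded, PFBA would have run length 2 and the 2018 definition would
miss the canonical PFCAs — that reading is rejected.)

### Multicomponent records

Salts and mixtures are multi-fragment records. Substructure patterns are
inherently per-component (an embedding cannot span disconnected
fragments). The formula clause is evaluated per component by default — a
salt is positive when any one fragment is sufficiently fluorinated — or on
the whole-record formula with `policy = "whole_record"`, which matches a
registry search over record-level formulas. Formula-reading *filters*
(fluorine-count range, F:C minimum) always use the whole-record formula;
charge is the net formal charge over all fragments, so a complete salt is
neutral while a bare anion is charged.

### The v4 reconstruction

The substructure registry of the EPA structures list v4 is described in
prose but not published as machine-readable patterns. The package encodes
it as six parameterised defaults (all overridable from a registry config):

| id | unit |
|----|------|
| `s1_adjacent_cf2` | two adjacent CF2 groups, hydrogen permitted (the v1 unit carried forward) |
| `s2_perfluoroethyl` | CF3–CF2 |
| `cf2_cf_unit` | the TSCA 2021 unit |
| `s4_bis_cf3_branched` | CF3–C(CF3)<, hydrogen allowed on the central carbon |
| `s5_cf2_cf_h` | CF2–CF with hydrogen **required** on the CF carbon |
| `cf2_o_cf2` | the perfluoroether unit |

Two reconstruction choices matter and are deliberate:

* S1 keeps the hydrogen-permitted v1 semantics. With a no-hydrogen S1,
  every S1-positive record would also be S3-positive (a strict
  strengthening of the TSCA unit), making S1 redundant *by construction*.
* S5 requires hydrogen on its CF carbon so that it complements rather than
  subsumes the TSCA unit.

Under these choices exactly one pattern is a record-level subset of the
others by construction — S2, since any CF3–CF2 is both an adjacent-CF2 pair
and a TSCA unit. `pattern_overlap()` flags it as *extraneous* (zero unique
hits) on any corpus in which every other pattern has a record only it
captures, and removing it never changes a verdict. This reproduces, at
desk scale, the redundancy analysis that motivated pruning the registry.

### Gap analysis

`gap_candidates()` encodes the pipeline used to find structures a
definition misses: keep records with ≥ 3 fluorines, set aside the
*trivially fluorinated* ones (a lone CF3; or exactly two CF3 groups not
sharing a common carbon — two CF3 on one carbon are kept), and drop
everything the base definition already captures. On the fixture corpus
this recovers tetrakis(trifluoromethoxy)methane — a perfluorinated
orthocarbonate invisible to the v4 registry — as a candidate, while the
hexafluorinated diol is set aside as trivially fluorinated.

## The synthetic generator

`generate_fluorochemicals()` builds seeded random fluorochemical SMILES for
property-based testing. Its defaults are study conditions, not tuned
outputs: scaffolds weighted 40 % linear / 25 % branched / 20 % ether /
15 % aromatic, backbones of 3–10 carbons, per-site fluorination probability
0.45 (so the generated library spans the 30 % threshold from both sides),
chlorine 0.05, bromine 0.01, and a 10 % chance of a second independent
fragment. Alongside each SMILES the generator tallies heavy atoms,
fluorines and hydrogens *while assembling the string* — ground truth that
is independent of the package's parser and formula pipeline, so the two
routes can be cross-checked. All draws are seeded and the global RNG state
is restored afterwards.

The generator's scope is deliberately narrow: acyclic aliphatic scaffolds,
one ether oxygen, benzene rings with at most one alkyl tail, halogen
substituents only. It produces no charges, radicals, isotopes, fused
rings, or exotic valences — those paths are exercised by hand-written
fixtures instead.

## Problem sizes and tolerances

Property tests run at the sizes the package treats as standard: 10^4
generated formulas for the hydrogen-denominator monotonicity property and
10^3 generated structures for the dual-route fully-fluorinated-carbon
check. Printed-integer comparisons use the one-percent-point band
described above; all other comparisons are exact or at numerical
tolerance.

## Worked example

```{r example}
library(pfasdef)

# classify the fixture corpus under every built-in definition
m <- classify_all(paper_corpus(), smiles = "smiles", id = "name")
m$totals

# definition disagreement: combined rule vs the 2021 structural rule
definition_diff(m, "pfasstruct_v5", "oecd2021")$only_a
```

## Limitations

* SMILES support is constitution-level: stereo descriptors are accepted
  and ignored, aromatic perception trusts the input's lowercase/bond
  annotations (no Kekulé normalisation or aromaticity model), and
  wildcard atoms are rejected.
* The v4 registry is a reconstruction; its patterns are defaults meant to
  be overridden from a YAML/JSON config where a historical rendering is
  available.
* Database-scale census counts reported for the definitions in the
  literature depend on a specific registry snapshot and are out of scope;
  the package reproduces the per-compound verdicts and the desk-scale
  analyses only.
* Radical perception from SMILES follows the valence-deficit reading of
  bracket atoms; unusual valences written without brackets are normalised
  to the fixed valence table.
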