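# pfasdef

Rule-based classification of per- and polyfluoroalkyl substances (PFAS).

"PFAS" is not one chemical class: regulators and registries have drawn its
boundary with at least seven different rules, from the OECD's 2021
*fully fluorinated carbon* criterion to substructure registries (the EPA
PFAS structures lists, the TSCA 2021 working definition, the CCL5
definition) to a combined rule that unions four substructures with a
molecular-formula fluorine threshold. The same compound — even the same
constitutional isomer set — can fall inside one boundary and outside
another.

`pfasdef` encodes those definitions as **data** (substructure patterns +
formula rule + exclusion filters) evaluated by one engine, so they can be

* applied to compound libraries (SMILES, SDF V2000, CSV) with per-clause
  evidence for every verdict,
* compared set-against-set over a corpus (overlap, differences, redundant
  patterns, gap candidates), and
* extended or overridden from a YAML/JSON registry config.

## The definitions

`builtin_definitions()` ships seven rule sets. The headline one,
`pfasstruct_v5`, is the combined definition: a record is PFAS iff

> it contains any of four substructures — `R‑CF2‑CF(R')R''`, adjacent
> `CF2‑CF2` (no H), `CF3‑C(CF3)(R)R'`, or `CF2‑Q‑CF2` with
> Q ∈ {B, O, N, P, S, Si} — **or** its fluorine atom-count fraction
> (hydrogen excluded from the denominator) is ≥ 30 %,
> **and** it is not a free radical **and** it has at least one C–F bond.

The others (`oecd2021`, `oecd2018`, `tsca2021`, `pfasstruct_v1`,
`pfasstruct_v4`, `ccl5`) are described in `?builtin_definitions` and in the
methods vignette (`vignette("pfas-definitions")`), including the
reconstruction rationale for the v4 substructure registry.

## Worked example

Perfluorobutanoic acid (PFBA) is PFAS under every definition;
tetrafluoroethene (TFE, the PTFE monomer) is 67 % fluorine but contains no
saturated fluorinated unit, so the structural definitions miss it and only
the combined rule captures it:

```r
library(pfasdef)

r <- pfas_classify(c(PFBA = "OC(=O)C(F)(F)C(F)(F)C(F)(F)F",
                     TFE  = "FC(F)=C(F)F"),
                   definitions = c("oecd2021", "tsca2021", "pfasstruct_v5"))
dplyr::select(r, record_id, definition_id, is_pfas, formula, atom_fraction_excl_h)
#> # A tibble: 6 × 5
#>   record_id definition_id is_pfas formula atom_fraction_excl_h
#>   <chr>     <chr>         <lgl>   <chr>                  <dbl>
#> 1 PFBA      oecd2021      TRUE    C4HF7O2                0.538
#> 2 PFBA      tsca2021      TRUE    C4HF7O2                0.538
#> 3 PFBA      pfasstruct_v5 TRUE    C4HF7O2                0.538
#> 4 TFE       oecd2021      FALSE   C2F4                   0.667
#> 5 TFE       tsca2021      FALSE   C2F4                   0.667
#> 6 TFE       pfasstruct_v5 TRUE    C2F4                   0.667
```

Every verdict carries its evidence — which clause fired, which filters
passed, with matched atom tuples for patterns:

```r
r$evidence[[6]]   # TFE under pfasstruct_v5
#> # A tibble: 7 × 5
#>   kind    id                passed detail                                  value
#>   <chr>   <chr>             <lgl>  <chr>                                   <dbl>
#> 1 filter  no_radical        TRUE   not a radical                          NA
#> 2 filter  require_cf_bond   TRUE   carbon-fluorine bond present           NA
#> 3 formula fluorine_fraction TRUE   fluorine atom fraction (excl. H, per_…  0.667
#> 4 pattern cf2_cf_unit       FALSE  no match                                0
#> 5 pattern adjacent_cf2      FALSE  no match                                0
#> 6 pattern bis_cf3           FALSE  no match                                0
#> 7 pattern s4_cf2_q_cf2      FALSE  no match                                0
```

Cross-definition comparison over the bundled literature fixture corpus
(`paper_corpus()`, 24 named compounds including the PFBA salt series and
the four C3Cl4F4 isomers):

```r
m <- classify_all(paper_corpus(), smiles = "smiles", id = "name")
m
#> <pfas_matrix> 24 records x 7 definitions
#> positives per definition:
#>      oecd2021      oecd2018      tsca2021 pfasstruct_v1 pfasstruct_v4
#>            15             4             7             6             8
#>          ccl5 pfasstruct_v5
#>             7            20

definition_diff(m, "pfasstruct_v5", "oecd2021")  # who disagrees, by record
tidy(m); glance(m)                               # long form / one-row summary
ggplot2::autoplot(m)                             # verdict heat map
```

Formula-only workflows need no structures at all:

```r
fluorine_metrics(c(C6HF9O6 = "C6HF9O6", PFBA = "C4HF7O2"))
#> # A tibble: 2 × 7
#>   id      formula f_count atom_fraction_excl_h atom_fraction_incl_h mass_fraction
#>   <chr>   <chr>     <int>                <dbl>                <dbl>         <dbl>
#> 1 C6HF9O6 C6HF9O6       9                0.429                0.409         0.503
#> 2 PFBA    C4HF7O2       7                0.538                0.5           0.621
#> # ℹ 1 more variable: f_to_c_ratio <dbl>
```

Other entry points: `pattern_overlap()` (which substructures of a
definition are redundant on a corpus), `gap_candidates()` (highly
fluorinated records a definition misses), `generate_fluorochemicals()`
(seeded synthetic libraries with construction-time ground truth),
`load_registry()` (user definitions from YAML/JSON —
see `inst/extdata/example_registry.yaml`).

## Command line

A thin CLI over the same functions ships at `inst/cli/pfasdef.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pfasdef.R",package="pfasdef"))')" \
  classify --input library.smi --definitions pfasstruct_v5,oecd2021 --out report.csv
```

Subcommands: `classify`, `compare`, `overlap`, `gaps`, `corpus`,
`generate`, `metrics`. Exit status 0 on success; a run log on stderr
reports records read / parsed / failed and positives per definition.

## Scope

Structure perception is constitution-level and purpose-built for these
definitions (implicit hydrogens, charges, radicals, isotopes, components;
stereo ignored). It is not a general cheminformatics toolkit — see the
vignette's limitations section. Database-scale census counts tied to
specific registry snapshots are out of scope.
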