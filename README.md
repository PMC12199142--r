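# rnalsc — local stability compensation analysis for RNA secondary structures

RNA secondary structures balance destabilizing loops against the stems that
close them. **Local stability compensation (LSC)** is the principle that this
balance is struck *locally*: a hairpin loop, bulge or internal loop is
stabilized by its immediately adjacent helix (or helices), not by distant
parts of the structure. `rnalsc` implements the complete analysis pipeline
around the statistic at the heart of this idea, the **net free energy** of a
substructure,

```
net ΔG = ΔG_loop + ΔG_stem                   (hairpin loops)
net ΔG = ΔG_loop + (ΔG_stem,5′ + ΔG_stem,3′)/2   (bulges, internal loops)
```

with all component free energies evaluated from the Turner 2004
nearest-neighbor tables at 37 °C (shipped with the package as a documented
text asset, in kcal/mol).

The package is aimed at structural-bioinformatics users who want to

* decompose dot-bracket or bpRNA structure-type (`.st`) files into typed
  substructures (stems, hairpins, bulges, internal loops) with loop↔stem
  adjacency, and write `.ste` files carrying per-substructure energies;
* score substructure databases and quantify compensation: binned
  loop-vs-stem regressions (0.25 kcal/mol bins; median and 5 % quantile), an
  in-structure **rotation control** (loops re-paired with distal stems of the
  same structure) with a variance F-test, kernel density estimates and
  per-family summaries;
* design randomized RNA libraries on a triply bulged hairpin template with
  A/C-only loops, constant-energy distal stems, pairwise Hamming distance
  ≥ 20 and a ±20 % length window;
* quantify folding fidelity from DMS chemical-mapping reactivity tables:
  A/C-restricted AUROC (designed-unpaired positions as positives) in global,
  local and distal scopes, stem/loop reactivity means, per-position stem
  profiles, and a Hill-equation fit of binned AUROC versus net ΔG whose
  AUROC = 0.9 crossing defines the minimum local stability for consistent
  folding;
* generate synthetic data with the statistical structure the analysis
  assumes (linear loop–stem compensation; a two-state local-unfolding
  reactivity model), so every stage is testable without external downloads.

## Worked example

Decompose and score a small bulged hairpin:

```r
library(rnalsc)
s <- parse_dotbracket("demo", "GGAGCGCAACAGCGCCC", "((.((((....))))))")
s
#> rna_structure 'demo' (17 nt, 6 pairs)
#> GGAGCGCAACAGCGCCC
#> ((.((((....))))))
#> SSBSSSSHHHHSSSSSS

en <- annotate_structure_energies(s)
en[, c("label", "kind", "dg")]
#>   label    kind   dg
#> 1    S1    stem -3.3
#> 2    S2    stem -9.2
#> 3    H1 hairpin  4.1
#> 4    B1   bulge  0.5

make_records(en)[, c("loop_label", "loop_type", "loop_dg",
                     "stem_dg1", "stem_dg2", "net_dg")]
#>   loop_label loop_type loop_dg stem_dg1 stem_dg2 net_dg
#> 1         H1   hairpin     4.1     -9.2       NA  -5.10
#> 2         B1     bulge     0.5     -3.3     -9.2  -5.75
```

The hairpin loop costs +4.1 kcal/mol and its closing stem supplies
−9.2 kcal/mol, so the stem-loop folds with a comfortable net −5.1 kcal/mol;
the single-A bulge (+0.5, including the stack through the bulge) averaged
over its two flanking stems nets −5.75 kcal/mol.

Design a library, simulate DMS reactivity from the two-state local-unfolding
model, and fit the fidelity curve:

```r
lib <- generate_library("hairpin", 300, seed = 7)
lib
#> designed_library (hairpin): 300 constructs, seed 7; net dG range [-29.60, 3.70] kcal/mol

prof <- filter_c_repeats(simulate_dms(lib, dms_sim_config(), seed = 8))$kept
fid <- fidelity_records(prof)
fit <- fit_hill(fid)
fit
#> hill_fit: A0 = 0.578, h = 4.98, s50 = 17.10 (s = 10 - net dG); AUROC 0.9 at
#> net dG -11.63 kcal/mol; 124 bins, RSS 0.9763

regress_fidelity(fid, "stem_local")$r_squared    # 0.571
regress_fidelity(fid, "stem_distal")$r_squared   # 0.0002
```

Constructs whose variable loop is stabilized beyond about −12 kcal/mol fold
with AUROC ≥ 0.9 in this simulation, local stem reactivity tracks net ΔG
(r² ≈ 0.57) while distal stems are unaffected (r² ≈ 0.0002) — the
local-versus-distal contrast the pipeline is built to measure.

A command-line wrapper is installed as `exec/rnalsc` with subcommands
`annotate`, `stats`, `design`, `dms` and `simulate`; see
`vignettes/local-stability-compensation.Rmd` for the model, parameter and
design documentation.

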