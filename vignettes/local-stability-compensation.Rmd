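---
title: "Local stability compensation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local stability compensation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnalsc)
```

This vignette documents the scientific model behind `rnalsc`, the
parameters that matter, what the synthetic-data generators emulate (and do
not), and the numerical and design decisions taken where the problem was
genuinely open.

## The net-ΔG statistic

A nested RNA secondary structure decomposes uniquely into stems (maximal
runs of stacked canonical pairs), hairpin loops, bulges, internal loops and
multiloop/exterior segments. Local stability compensation treats the loop
and its adjacent stem(s) as the unit of folding: the **net free energy** of
a loop is

* hairpin: `net ΔG = ΔG_loop + ΔG_stem` (one closing stem);
* bulge / internal loop: `net ΔG = ΔG_loop + mean(ΔG_stem5, ΔG_stem3)`.

The arithmetic mean of the two full stem energies is used for two-way
junctions — deliberately not a per-base-pair normalization — so that a long
stabilizing helix counts in full, mirroring how the loop's closure is
physically supported. This choice overlooks stem asymmetry; a loop flanked
by one strong and one marginal stem receives the same credit as one flanked
by two average stems. A more refined locality model is out of scope here.

## Component free energies

Energies come from the Turner 2004 nearest-neighbor tables at 37 °C,
shipped as two plain-text assets (`inst/extdata/turner2004_dg.txt` and
`…_int22_dg.txt`, kcal/mol stored as decacal integers) transcribed from the
published parameter set. The evaluation rules are the standard ones:

* **stems** — sum of stacking terms over consecutive pair steps;
* **hairpins** — size-dependent initiation plus the terminal mismatch
  (size ≥ 4) or the AU/GU closure penalty (size 3); tabulated
  tri-/tetra-/hexaloop sequences take their exact special value; loops of
  size 1–2 are below the model's minimum and are *unscorable*;
* **bulges** — initiation; a single-nucleotide bulge additionally stacks
  its two closing pairs through the bulge; size ≥ 2 adds the AU/GU penalty
  for each closing pair;
* **internal loops** — exact tables for 1×1, 2×1 and 2×2; dedicated
  mismatch tables for 2×3 and 1×n; otherwise initiation + capped Ninio
  asymmetry + terminal mismatches;
* loop sizes beyond 30 extrapolate with the Jacobson–Stockmayer term
  `1.0786 · ln(n/30)` kcal/mol, truncated to the tables' decacal
  resolution.

Term assignment across components required a decision, because several
nearest-neighbor terms sit at the loop–stem interface. We follow the
accounting under which the component sum over a single-branch structure
equals the standard total energy: the AU/GU closure contribution at
hairpins (size ≥ 4) and internal loops is *embedded in their mismatch
tables* and therefore lives in the loop component; a bulge of size ≥ 2
carries the explicit penalties of both its closing pairs; stems take the
explicit end penalty only where they face the exterior or a multiloop.
`stem_dg()` called standalone penalizes both ends, which is the natural
context-free reading of a helix in isolation;
`annotate_structure_energies()` applies the in-structure accounting. The
identity *component sum = reference nearest-neighbor total* is enforced by
tests against an independent evaluator (`RNAeval -d0`) pinned to the same
tables, and holds to numerical precision (≤ 1e-14 kcal/mol observed).

Auxiliary poly-C hairpin and C-bulge terms exist in some parameter
dialects; the packaged asset sets them to zero (they are absent from the
tables this transcription derives from) while the loader exposes them as
tunable fields for sensitivity checks.

Multiloop, exterior-loop and dangling-end terms are never scored: the
analysis scores only hairpins, bulges, internal loops and stems, so total
energies are defined (and tested) only for single-branch structures.
Pseudoknotted pairs on extended bracket pages are dropped to unpaired with
a warning and analysis proceeds on the nested skeleton; all four
substructure types are nested objects, so no scored component is lost, but
any stabilization a pseudoknot provides is invisible to the statistic.
Components touching ambiguity codes (`N`) are marked unscorable rather than
guessed, and unscorable components propagate as explicit markers, never as
silent zeros.

## Database statistics

`bin_aggregate_regress()` bins records by loop ΔG in left-closed
0.25 kcal/mol bins and regresses the per-bin aggregate of the stem
statistic (median, or the 5 % quantile for the weakest-stem boundary;
linear-interpolation type-7 quantiles) on the bin centers by unweighted
ordinary least squares. Bins holding fewer than 10 records are excluded —
the aggregate of a near-empty bin is noise; both the floor and the
unweighted choice are package decisions where the procedure was
underdetermined, and both are arguments.

The **rotation control** destroys local pairing while preserving marginal
distributions: within every structure contributing more than three loops of
a type (so a loop can never receive its own stems), loops ordered 5′→3′
receive the stem set of the loop `floor(k/2)` positions ahead (cyclically);
if any reassigned set still contains a stem adjacent to its recipient —
possible when neighboring junctions share a helix — the offset increments
until none does, and a structure with no clash-free offset is dropped with
a log entry. The rule is deterministic and seed-free, and maximally
separates donor from recipient. Under compensation the control net-ΔG
variance exceeds the true variance; `variance_f_test()` compares them with
`F = var(x)/var(y)` (unbiased estimators) and a two-sided p-value from the
F distribution (the smaller tail doubled).

Kernel density estimates use a Gaussian kernel with the Scott-style
rule-of-thumb bandwidth (`stats::bw.nrd`); all-identical inputs are an
error (a point mass has no density estimate). Group summaries report
linear-interpolation medians and (n−1) standard deviations, with two-sided
Mann–Whitney U tests for pairwise contrasts — the test is a package
decision, chosen for its robustness to the skewed, heavy-tailed net-ΔG
distributions, and is documented as replaceable.

## Library design

The template is a triply bulged hairpin: three constant-energy stems and
single-A bulges frame one variable slot — the hairpin loop plus its closing
stem, or one junction (bulge or two-sided internal loop) plus both flanking
stems. Constraints follow the published design: variable stems 4–12 bp with
length, GC content and G:U count drawn from grids; hairpin loops 3–11 nt,
bulges 1–9 nt, internal loops 1–9 unpaired nucleotides *in total* with each
side ≥ 1 (a one-sided loop is a bulge; the per-side reading is available by
configuration); loops restricted to A and C so that every loop position is
DMS-readable; pairwise distance ≥ 20 by rejection sampling; constructs
outside ±20 % of the realized mean length removed post hoc. Between
unequal-length sequences the distance is the positional mismatch count over
the shorter length plus the length difference — simple, symmetric and
conservative (it never exceeds the true edit distance by construction of
the template).

Constant stems use G:C/C:G closing pairs, a fixed GC fraction of 0.6 (the
published design fixes the fraction without stating the value; 0.6 keeps
5-bp stems feasible and strongly paired) and no G:U, randomizing only pair
order and orientation: at the template's 5-bp length their free energy
varies with SD ≈ 0.35 kcal/mol across resamples, within the ≤ 0.5 kcal/mol
constancy target asserted in the tests. The flanks (5′ `GG` transcription
leader; 3′ reverse-transcription primer site) are stand-ins with the same
constraint structure as the deposited designs, whose exact constant
sequences live only in the original deposits.

## Reactivity and folding fidelity

Folding fidelity is the AUROC separating designed-unpaired (positive) from
designed-paired (negative) nucleotides by reactivity, computed with
midranks over A/C positions only, in three scopes: global, local (the
randomized region) and distal (its complement). A scope with fewer than two
positives or two negatives yields an undefined marker rather than a
degenerate 0/1 — the threshold is a package decision. Raw mutation
fractions are consumed without normalization (AUROC is rank-invariant to
it; reactivity *means* are on the raw scale). Constructs containing C runs
longer than four are removed before analysis, as such repeats give
unreliable reactivities. Region means restrict to A/C positions;
`log(mean + 1e-4)` is the log transform; distal *loop* means exclude
exterior tails (primer sites are not structural loops), while distal AUROC
follows the all-residues scope definition.

Per-position profiles average reactivity at the k-th pair outward from the
variable loop (position 1 = closing pair, up to position 6), per net-ΔG bin
(−20, −15, −10, −5, 0, 10 edges), averaging the two stems of a junction
where both have a k-th pair, with normal-approximation 95 % confidence
intervals and a 70-nucleotide floor per reported bin.

`fit_hill()` averages local AUROC in 0.2 kcal/mol net-ΔG bins, maps net ΔG
to a positive stability axis `s = 10 − net ΔG` (the offset keeps `s`
positive across the library range; it is a fixed transform constant, not a
fitted parameter), and fits

```
f(s) = A0 + (1 − A0) · s^h / (s50^h + s^h)
```

by bounded Levenberg–Marquardt least squares (`A0 ∈ [0.3, 0.9]`,
`h ∈ (0, 20]`, `s50 ∈ (0, 30]`; plateau fixed at 1). Bin means are
unweighted. The AUROC = 0.9 crossing, `g09 = 10 − s50·(r/(1−r))^{1/h}` with
`r = (0.9 − A0)/(1 − A0)`, is the minimum local stability for consistent
folding; it is reported as undefined when the fitted curve stays below 0.9
over the observed stability range (e.g. flat AUROC ≈ 0.5 data). The
parameterization — baseline fitted, plateau pinned — is one of several
defensible forms and is isolated so alternates can be swapped.

## Synthetic data: what it emulates, and what it does not

`simulate_structure_records()` draws loop ΔG from a truncated exponential
on [0.5, 12] kcal/mol (rate 0.4 — mean near 3 kcal/mol, matching the scale
of hairpin initiation energies) and sets each adjacent stem to
`α·loop + β + family offset + N(0, σ)`; defaults α = −0.8, β = −3.2,
σ = 1 put the hairpin net-ΔG median near −2.7 kcal/mol with spread of
order 1, the regime reported for large structure databases. Records group
into synthetic structures of five loops so the rotation control has
eligible structures; each junction receives its own pair of flanking stems
(no chain sharing), which keeps the generative slope exactly α and is the
one structural simplification relative to a real helix chain.

`simulate_dms()` implements a two-state local-unfolding model: a construct
folds as designed with probability `f = s^h/(s50^h + s^h)`
(`s = 10 − net ΔG`, defaults h = 4, s50 = 14 — midpoint at net
ΔG = −4 kcal/mol, the scale of observed hairpin thresholds). Local
designed-paired positions draw their underlying rate from the paired-state
distribution with probability `f`, otherwise from the unpaired-state
distribution; distal positions always draw from their designed state — the
locality assumption under test, exact by construction. Rates are log-normal
with means 0.01 (paired) and 0.10 (unpaired), typical DMS
mutation-fraction scales; observed reactivity adds binomial counting noise
at Poisson(5000) read depth. A folded-state loop depression factor (0.8)
reproduces the weak negative loop-reactivity trend seen in real data; it is
cosmetic, and the fidelity-recovery acceptance checks run with it disabled,
as recovery truth is defined for the pure two-state model.
`expected_auroc_curve()` provides the independent Monte-Carlo oracle for
that truth (≥ 1e5 draws per grid point).

What passing tests on this generator do **not** show about real data: the
two-state mixture is a modeling choice — real intermediate reactivities may
reflect partial folding, transient folding or a conformational ensemble;
reactivity distributions are idealized log-normals without
sequence-context, adduct-stacking or normalization artifacts; designed
structures are taken as ground truth, whereas real constructs can misfold
globally; and tertiary interactions, ligand effects and non-canonical
pairs are absent from both the generator and the energy model.

## Numerical choices and degenerate inputs

Integer decacal arithmetic with truncating extrapolation keeps energies
bit-identical to the reference evaluator. Bins are left-closed and labeled
by center (regression) or left edge (frequency tables). Lone base pairs
are stems of length 1 (zero stacks), so two-way junction adjacency is
always defined. Empty structures serialize to `.ste` files with zero
energy lines. The Hill fit requires ≥ 6 nonempty bins spanning ≥ 3
kcal/mol; regressions require ≥ 2 usable bins (binned) or ≥ 10 records
with a non-degenerate regressor (per-construct). All simulators take
explicit seeds, restore the caller's RNG state, and are byte-reproducible.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU while every statistical
assertion retains comfortable margins: 120 random structures for the
energy-oracle batch, 1 000 instances for the AUROC oracle, one
3 000-construct library with 20 simulated DMS replicates for Hill-threshold
recovery, n = 2 000 for the locality contrast and rotation control (100
replicate null seeds), a 1 000-construct library for the design-constraint
checks, and n = 20 000 records per slope for regression recovery.

## Known limitations

Multiloop and exterior energetics are out of scope, so net ΔG is undefined
for loops whose closure depends on a multiloop; pseudoknot stabilization is
invisible; the two-way-junction mean obscures stem asymmetry; the Hill
form fixes the plateau at 1 even though perfectly folded constructs show
AUROC marginally below 1 under counting noise (the fitted baseline absorbs
most, not all, of this); and thermodynamic parameters are fixed at 37 °C
with no enthalpy tables, so no temperature extrapolation is possible.
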