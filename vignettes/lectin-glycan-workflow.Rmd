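---
title: "Models and methods behind the lectinspec workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the lectinspec workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectinspec)
```

lectinspec implements the analysis chain used to characterize the
carbohydrate specificity of a two-domain bulb-type lectin: glycan-array
ranking, N-glycan motif classification, one-site calorimetric fitting, CRS
consensus scanning and distance-based phylogenetics. This vignette explains
the models each stage assumes, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Glycan grammar

Structure strings use the condensed-IUPAC dialect printed on CFG mammalian
arrays: residues read left to right toward the reducing end, a linkage token
such as `a1-6` giving the child's anomeric configuration, anomeric carbon
and attachment position on its parent, and a parenthesized group attaching
as a branch to the first residue to its right *at the same nesting depth*
(so nested parentheses denote branches on branches). A trailing `-SpN` tag
names the spacer arm used to print the glycan. Design choices worth
stating:

* **Spacers are opaque labels.** They never count as residues but are
  preserved through the parse/write round trip, because spacer identity is
  known to modulate apparent binding on arrays.
* **Missing root anomers parse as unknown.** Printed strings sometimes omit
  the reducing-end anomer (`...GlcNAc-Sp21`); the parser stores `NA` rather
  than guessing, and motif matching treats unknown as compatible with
  anything (lenient matching).
* **Canonical serialization.** `write_glycan()` orders branches by
  descending attachment position (ties broken lexicographically), so
  structural identity can be decided by string equality and round trips are
  idempotent.
* **The alphabet is configurable.** Defaults cover the monosaccharide
  symbols on v5.0-style arrays; parsing is longest-match, so `GlcNAc` never
  tokenizes as `Glc`.

Parse errors report the offset and offending token, and a vectorized
wrapper collects per-line failures so one bad row cannot abort an array
table.

## Motif matching and N-glycan classes

Subtree matching maps every query node to a distinct tree node, preserving
edges and attachment positions unless wildcarded (`?` works for name,
anomer, carbon or position). The engine enumerates *all* match mappings;
the test suite checks it against an exhaustive brute-force enumeration over
injective node mappings, which is feasible because test trees are capped at
10 residues.

Classification keys on the trimannosyl core pentasaccharide
Manα1-6(Manα1-3)Manβ1-4GlcNAcβ1-4GlcNAcβ anchored at the reducing end:

* no core → `non_core`;
* core present, reducing GlcNAc carries Fucα1-6, and some antennary residue
  beyond the core is non-mannose → `fucosylated_core`;
* all residues beyond the core (ignoring that core fucose) are mannose →
  `high_mannose` — so a core-fucosylated glycan with mannose-only antennae
  is still counted as high-mannose, matching how such structures are
  grouped on printed arrays;
* otherwise → `complex`, which deliberately absorbs hybrid structures
  (one mannose arm, one substituted arm).

`lacnac_counts()` distinguishes terminal lactosamine (the Gal is a leaf)
from internal lactosamine (the Gal is further substituted), the distinction
that separates strong from insignificant binding for this lectin family.
The named motif `lewis_fucosylated_terminal` encodes exactly the
difucosylated terminal unit printed on the array
(Fucα1-2Galβ1-4(Fucα1-3)GlcNAcβ), not the textbook Lewis X antigen; the
conventional nomenclature mismatch is left to the user.

## Array ranking statistics

The ranking model is deliberately simple and fully determined by two
choices:

* **Replicate summarization.** Negative RFUs are floored at zero, then the
  `trim` highest and lowest replicates are dropped (default 1 of 6, the
  usual array convention) before mean and SD.
* **Normalization.** Per concentration, `score = 100 × mean / max(mean)`;
  the average rank is the arithmetic mean of per-concentration scores. This
  percent-of-maximum definition (rather than a percentile position) is what
  makes a glycan that tops only some concentrations land below 100 — the
  behavior seen in real ranked tables where the best binder sits near 88
  rather than at 100.

Binder calling is offered both ways used in practice: a strict
average-rank threshold (default 10 rank units) and a z-score partition in
which `log(mean + 1)` values are standardized over all glycans at one
concentration and calls use `z ≥ z_threshold` (default 1.5; the threshold
used by array web services is not published, so it is a parameter). The
zero-variance degenerate case returns "no binders" with a warning rather
than dividing by zero.

## One-site ITC model

The forward model is the standard one-site (Wiseman) total-heat closed
form with displaced-volume dilution. After cumulative injected volume $v$
into a cell of volume $V_0$:

$$M_t = M_0\,\frac{1 - v/2V_0}{1 + v/2V_0}, \qquad
  X_t = X_0\,\frac{v/V_0}{1 + v/2V_0},$$

$$Q = \frac{n M_t \Delta H V_0}{2}
  \left[A - \sqrt{A^2 - 4X_t/(nM_t)}\right], \qquad
  A = 1 + \frac{X_t}{nM_t} + \frac{1}{nK_aM_t},$$

with per-injection heat
$\Delta Q_i = Q_i + (dV_i/V_0)(Q_i + Q_{i-1})/2 - Q_{i-1}$. Units are
calories throughout (R = 1.987 cal mol⁻¹ K⁻¹), with conversions left to
the I/O boundary. The governing contract is simulator/fitter convention
identity: the fitter minimizes squared residuals of exactly this forward
model, so noiseless round trips recover parameters to machine precision.

Numerical choices: Ka is fitted on the log scale (positivity without
constraints); starting values come from the curve shape — ΔH from the
first-injection heat per mole injected, n from the molar ratio at half the
total heat, Ka from a one-dimensional profile search on log Ka in
[10², 10¹⁰] — which is robust for sigmoidal data; Levenberg–Marquardt
(minpack.lm) does the refinement with tight tolerances; standard errors
come from the fit's curvature, with the SE of Ka delta-method-transformed
from log Ka. Degenerate inputs (all heats ≈ 0, fewer than 5 injections)
error explicitly rather than returning garbage.

The default `titration_scheme()` — 200 µL cell, 50 µM macromolecule,
250 µM ligand, 18 × 2 µL injections, 298.15 K — reaches a final molar
ratio near 1, i.e. roughly three equivalents past saturation for
n ≈ 0.32, the fitted stoichiometry whose reciprocal (≈ 3) is read as the
ligand's functional valency toward the lectin.

## CRS consensus scanning

The core consensus is the 9-mer [QXDXNXVXY] of GNA-related lectins; the
extended form [ZQXDXNZVZY] additionally requires a leading M/I/L/V and
hydrophobic residues flanking the fixed V (the hydrophobic triplet that
packs against mannose). Since the original definition's exact hydrophobic
set is not reprinted here, the default
{A, V, L, I, M, F, W, C, Y} is a parameter. All overlapping matches are
reported; there is no greedy suppression. Coordinates are 1-based
inclusive throughout, matching the `N26–P132` style of domain annotation;
a match counts for a domain only when fully contained in its span. The
diagnostic residue downstream of the CRS — alanine in mannose-binding
lectins, glutamine in the substituted two-domain lectins — is read at a
configurable offset (default 1, since "downstream" is not pinned to an
exact position in the source material).

## Number-of-differences NJ trees

Distances are raw counts of differing columns after *complete deletion*
(every column containing a gap `-` or missing `?` in any row is removed
first) — amino-acid differences per sequence, not per site. The NJ
agglomeration is the textbook Q-criterion algorithm with two explicit
policies:

* **Tie-breaking:** the lowest (i, j) index pair in the current taxon
  ordering wins, making output deterministic; because other
  implementations may order taxa differently, topology comparisons should
  use bipartition sets (`bipartitions()`), never newick text.
* **Negative branch lengths are retained** and flagged via the
  `negative_branches` attribute, not clamped — this is what makes recovery
  from additive matrices exact, which the tests exploit as an oracle
  (path-length matrices of random trees).

`monophyly_check()` answers the question typically asked of such trees —
whether a set of taxa (e.g. one taxonomic order's lectins) is separated by
a single edge — on the unrooted topology, so a clade and its complement
are equivalent.

## Synthetic data: what it emulates, and what it does not

All generators take a seed, return their ground truth, and are
bit-reproducible.

* **Glycan libraries** are random valid trees (depth ≤ 5, branching ≤ 3)
  over a reduced alphabet, with planted members built from a motif string
  and lightly decorated; they emulate the diversity of an array library,
  not its actual composition.
* **Array RFUs** are lognormal (default σ = 0.3), strictly positive and
  right-skewed like scanner intensities. An overall per-concentration
  intensity factor (concentration/max)^h with h = 1 scales *all* spots,
  and planted binders are a constant `fold` (default 20) brighter at every
  concentration. Making fold the binder:background contrast at each
  concentration — rather than letting binders fall to background level at
  the lowest concentration — is what licenses the exact-recovery test and
  mirrors real screens where binder calls stay roughly stable across a
  100-fold concentration range; the percent-of-maximum normalization then
  cancels the overall factor, which is separately asserted as the
  rescaling-invariance property.
* **Isotherms** add Gaussian noise scaled to the peak heat (default 1%).
* **Lectin sequences** plant non-overlapping extended-consensus 10-mers
  (so both scanners find them) with the requested downstream residue;
  backgrounds exclude glutamine and are rejection-sampled (capped at 10⁴
  tries) until the scan finds exactly the planted sites. The default
  geometry — 25-residue leader, domains of 107 and 109 residues with a
  13-residue linker and short tail, 257 residues in total — matches the
  two-domain precursor architecture of the lectin family studied.
* **Alignments** evolve i.i.d. sites down a random topology with
  probability 1 − exp(−rate·branch) of resampling; this is a minimal
  exerciser for the distance/tree stages, not a substitution-model
  simulator.

Passing recovery tests on these generators shows the pipeline is correct
*under its own assumptions* (lognormal noise, independent replicates,
exactly one planted motif class, additive distances). Real array data add
spatial artifacts, spacer effects and printing variability; real
calorimetry adds baseline drift and dilution heats (a constant
per-injection offset is deliberately not fitted by default); real
alignments violate additivity. Conclusions about real data need the usual
caution.

## Problem sizes in the checks

The bundled published table has 23 structures; synthetic studies use
100-glycan libraries (10 planted binders, 3 concentrations, 6 replicates),
18-injection isotherms with 100 noisy replicates for the stoichiometry
recovery study, 1,000 random 40-mers for the consensus-implication
property, 500 random trees of ≤ 10 residues for the matching oracle, and
100 random additive matrices on 4–8 taxa for NJ recovery. These sizes keep
the full suite under a minute while leaving each property comfortably
powered.

## Known limitations

* The grammar does not cover sulfated/phosphorylated residue decorations
  (e.g. `(6S)` tags) or repeat notation; the alphabet is configurable but
  the token syntax is fixed.
* `classify_nglycan()` is rule-based on the core pentasaccharide; it does
  not attempt hybrid/bisecting subtypes beyond the documented precedence.
* The ITC stage fits a single site class only; multi-site and sequential
  models, and baseline integration of raw power traces, are out of scope.
* NJ is distance-based with no bootstrap support values; reproducing a
  published multi-taxon tree requires the original sequence set, which is
  not bundled.
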