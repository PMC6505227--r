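# lectinspec

Analysis toolkit for characterizing the carbohydrate-binding behavior of
plant lectins, built around the workflow used to profile the *Arisaema
tortuosum* lectin (ATL), a two-domain GNA-related (bulb-type, β-prism II)
lectin that has lost simple-mannose specificity and instead binds complex
N-glycans. The package is aimed at glycobiologists who have glycan-array,
calorimetry and sequence data for a lectin and want a reproducible,
scriptable version of the standard analysis chain.

It provides five connected stages:

1. **Glycan grammar** — parse condensed-IUPAC (CFG dialect) structure
   strings such as `Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAcb-Sp13` into
   rooted residue trees, serialize them back canonically, and report
   compositions.
2. **Motif engine** — exhaustive subtree matching with wildcards, detection
   of the N-glycan trimannosyl core pentasaccharide
   Manα1-6(Manα1-3)Manβ1-4GlcNAcβ1-4GlcNAcβ, rule-based classification into
   high-mannose / complex / core-fucosylated / non-core categories, and
   terminal-vs-internal lactosamine (Galβ1-4GlcNAc) counting.
3. **Array ranking** — replicate trimming, per-concentration
   percent-of-maximum normalization (`score = 100·mean/max`), average rank
   across lectin concentrations, strict rank-threshold binder selection, and
   a z-score binder/non-binder partition on log-transformed means.
4. **ITC thermodynamics** — forward simulation and Levenberg–Marquardt
   fitting of the one-site (Wiseman) isotherm with displaced-volume dilution
   correction, and derivation of ΔG = ΔH − TΔS = −RT ln K<sub>a</sub> with
   R = 1.987 cal mol⁻¹ K⁻¹. The reciprocal of the fitted stoichiometry *n*
   is the ligand's functional valency.
5. **Sequence stages** — scanning for the carbohydrate-recognition-site
   consensus [QXDXNXVXY] and its extended form [ZQXDXNZVZY] (Z hydrophobic,
   leading Z ∈ {M,I,L,V}), per-domain counts, the diagnostic
   alanine→glutamine substitution downstream of the CRS, and
   Neighbor-Joining trees from number-of-differences distances with
   complete deletion.

Seeded synthetic-data generators (`gen_*`) emulate each input type with
known ground truth, so every stage is testable end to end.

## Worked example

The bundled table `atl_glycans()` holds the 23 highest-binding array
structures for ATL (CFG mammalian array v5.0, request cfg_rRequest_2313)
with their printed average ranks. Classifying them recovers the published
grouping exactly:

```r
library(lectinspec)
tab <- atl_glycans()
rep <- classify_report(tab$glycan_id, tab$structure)
table(rep$class)
#>          complex fucosylated_core     high_mannose
#>               12                4                7

top <- parse_glycan(tab$structure[which.max(tab$avg_rank)])
top
#> <glycan_tree> 5 residues, spacer Sp13
#>   Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAcb-Sp13
has_core_pentasaccharide(top)
#> [1] TRUE
```

The top binder (average rank 87.6) is the bare trimannosyl core
pentasaccharide itself — 5 residues, 3 Man + 2 GlcNAc.

A synthetic array run with 10 planted core-pentasaccharide binders at
20× background (three concentrations, 6 replicates, lognormal noise
σ = 0.3) is recovered exactly by the ranking pipeline:

```r
core <- "Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAcb"
lib <- gen_glycan_library(100, planted = rep(core, 10), seed = 11)
arr <- gen_array_rfus(lib$glycans, binder_ids = 1:10, fold = 20, seed = 12)
res <- run_array_pipeline(arr$dataset, rank_threshold = 10)
sort(res$binders_by_rank)
#>  [1]  1  2  3  4  5  6  7  8  9 10
```

Fitting a noisy 18-injection one-site isotherm simulated at the fitted ATL
stoichiometry (n = 0.32, i.e. a functionally trivalent ligand):

```r
sch <- titration_scheme()   # 200 uL cell, 18 x 2 uL injections, 298.15 K
g <- gen_isotherm(sch, one_site_params(0.32, 1e6, -1e4),
                  noise_frac = 0.01, seed = 3)
fit <- fit_one_site(g$isotherm, sch)
fit
#> One-site fit: n = 0.3184 (SE 0.0017), Ka = 9.695e+05 1/M (SE 4e+04), dH = -1.01e+04 cal/mol (SE 73)
#> functional valency round(1/n) = 3; converged: TRUE
thermodynamics(fit, sch$temperature)$dG
#> [1] -8166.295
```

The negative ΔG (≈ −8.2 kcal mol⁻¹ here) marks spontaneous association;
ΔG = ΔH − TΔS holds identically by construction.

A two-domain lectin with one CRS per domain and the glutamine substitution
downstream (the ATL-like profile, vs three per domain with alanine in
mannose-binding GNA-like lectins):

```r
g <- gen_lectin_seq(crs_counts = c(1, 1), downstream = "Q", seed = 5)
crs_per_domain(g$record$sequence, g$domains)
#> DOM1 DOM2
#>    1    1
downstream_flag(g$record$sequence, scan_crs(g$record$sequence))$flag
#> [1] "substituted" "substituted"
```

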