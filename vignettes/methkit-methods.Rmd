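---
title: "methkit: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methkit: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methkit)
```

methkit covers the analysis stages that follow alignment and per-cytosine
methylation calling in a plant whole-genome bisulfite experiment. This
vignette documents the statistical machinery, the conventions, and the
places where the design was genuinely open — and what the synthetic-data
generator does and does not establish about real data.

## Coordinates, contexts and levels

Per-cytosine tables carry **1-based positions**, the dominant convention of
on-disk cytosine reports; annotations, DMRs and siRNA loci are **0-based
half-open** (BED convention). The two meet through `pos - 1` at exactly one
boundary inside the package. A cytosine's context is read 5′→3′ on the
strand carrying the C: CG when the next base is G, CHG when the second base
is not G but the third is, CHH otherwise. Ambiguous bases (`N`) count as
"not G", and cytosines within 2 bp of a contig end have no defined context
and are skipped. The methylation level of a site is the read ratio
mC/(mC + non-mC); region levels are **unweighted means of site ratios**, so
deeply covered sites do not dominate (a read-pooled variant is available via
`pooled = TRUE` flags for sensitivity checks).

A site becomes a *called methylcytosine* when it has ≥ 4 covering reads and
≥ 1 methylated read (`call_modified_sites`). Public per-cytosine datasets
rarely state their call rule; this default borrows the only read-support
clause that the DMR criteria make explicit (≥ 4 reads at a methylated
cytosine), and both thresholds are arguments. The per-context "share"
statistic is each context's percentage of all called methylcytosines — the
arithmetic that reproduces published two-tissue summary tables, which the
acceptance script re-derives from the printed counts.

## Metagene profiles

Profiles average site levels in fixed 100-bp bins across 2-kb flanks and in
`n_body_bins` proportional bins across the scaled body, oriented 5′→3′ of
each feature (minus-strand features are flipped; whether flank bins should
instead run along the chromosome is unknowable from published figures, and
feature orientation is the biologically coherent choice). The body bin count
is nowhere standardized; 40 is the default so that body bins visually match
the twenty 100-bp flank bins, and it is configurable. Aggregation is the
mean of per-feature bin means ("feature averaging") so long or densely
covered features do not dominate. Features shorter than `n_body_bins` bp are
excluded with a message rather than interpolated. Bins without covered sites
are `NA`, never 0 — absence of evidence is not hypomethylation. Overlapping
flanks of adjacent features are all counted; no masking rule is applied.

Between-tissue comparisons (`compare_tissue_levels`) run a one-way ANOVA per
region on per-feature mean levels. With two groups this is the squared
two-sample t test; the statistic is computed in closed form
(MSB/MSW) and is checked in the tests against `stats::aov`.

## The DMR caller

A usable site is covered by ≥ 10 reads in *both* samples and called
methylated in at least one. Usable sites chain into **maximal runs** in
which successive positions are < 200 bp apart (`candidate_regions`); each
run faces six criteria in order (`evaluate_region`): length within
40 bp–10 kb; ≥ 5 methylated cytosines in at least one sample; fold change of
mean level > 2 (with a pseudocount ε = 0.001 on both levels so zero-level
regions stay comparable); and Pearson chi-square p ≤ 0.05 on the 2×2 table
of pooled methylated/unmethylated read counts, without continuity
correction, with zero-margin tables rejected as degenerate. The "more than
ten reads" / "more than five methylated cytosines" phrasings common in
methods prose are resolved inclusively (≥ 10, ≥ 5); both are parameters. No
multiple-testing correction is applied across candidates by default — the
criterion is a raw p-value — but `adjust = "BH"` adds one.

**Why segmentation exists.** On a real (or realistically simulated) plant
methylome at ~25× coverage, nearly every CG site is usable, so a whole
chromosome chains into a single maximal run that fails the length bound —
the criteria alone cannot localize anything. `call_dmrs` therefore treats a
failing run with recursive binary segmentation: split at the position
maximizing the CUSUM statistic of per-site level differences (the change
point), recurse into both halves, and emit every segment that passes all six
criteria. Ties in the CUSUM argmax (e.g. two identical samples, where the
difference signal is flat) split at the midpoint, which keeps the recursion
balanced and O(n log n). This is the approach of established change-point
DMR callers. Segmentation never alters a run that already passes, and
`segment = FALSE` gives the literal maximal-run reading, which the test
suite verifies against an independently written brute-force enumerator on
200 randomized small instances.

The caller is symmetric (swapping samples preserves intervals and p-values
and flips every hyper/hypo direction) and monotone (tightening any threshold
never adds a DMR); both are property-tested. Chi-square calibration under
the null is checked on sparse null candidates, where the pass fraction of
the chi-square criterion alone sits within binomial noise of α.

## Expression and siRNA association models

Per-gene covariates are counts of called methylcytosines in the gene-oriented
2-kb upstream flank, body and 2-kb downstream flank, fitted jointly (one
model per context). Expression responses are raw counts; Spearman analyses
use RPKM, with the conventional strength scale (|rho| < 0.2 "very weak" up
to ≥ 0.8 "very strong"; the gap that the usual quotation of that scale
leaves at [0.79, 0.8) maps to "strong"). Expression groups are
non (RPKM ≤ 1), low (≤ 10), middle (≤ 100), high (> 100).

`fit_hurdle` is a two-part model for zero-inflated counts: a logistic GLM
for crossing the hurdle (reported as P(count > 0)) and a zero-truncated
negative binomial with log link for the positives. Whether the positive
part of such published hurdle analyses used Poisson or NB is typically
unstated; NB is chosen for consistency with the overdispersed siRNA model
(`fit_negbin`, a standard NB GLM via `MASS::glm.nb`, with the Poisson limit
substituted when the dispersion estimate diverges on equi-dispersed data).
The truncated-NB likelihood is maximized by BFGS from three deterministic
starts (Poisson-GLM coefficients, intercept-only, method-of-moments
dispersion); the likelihood is evaluated with `log1p(-exp(θ log(θ/(θ+μ))))`
for the truncation term, linear predictors are capped at 30 to avoid
overflow, and standard errors come from the numerical Hessian at the
optimum. Non-convergence sets a flag, never a silent result. Tests check
the fitted likelihood against a zoomed grid-search MLE on tiny instances
and parameter recovery within ±3 SE at n = 2000 on generator output.

`q2_cross_validate` partitions observations into k seeded near-equal folds,
predicts each held-out fold's mean response, and reports
Q² = 1 − PRESS/TSS exactly (the identity is asserted, not re-derived). A
fold that is degenerate for the model (e.g. no zeros for the hurdle) is
retried with one reshuffle, then errors. On the generator's defaults the
hurdle model attains a small positive Q² — methylation explains a sliver of
expression variance, which is the realistic regime.

`sirna_overlap_compare` partitions cytosines genome-wide by 24-nt siRNA
coverage and tests pooled read counts with a two-sided Fisher's exact test
(read pooling rather than site counting is the default because it preserves
coverage information; `unit = "sites"` is the alternative).

## lncRNA positional classes

Published class vocabularies (intergenic, bidirectional, antisense, intronic
sense, intronic antisense, sense) almost never come with operational
definitions. The classifier fixes explicit precedence rules — exonic overlap
before intronic containment, sense before antisense, any gene overlap before
bidirectionality, bidirectional requiring a divergent (head-to-head) 5′ end
within 1 kb of a gene TSS — so every lncRNA receives exactly one class, and
removing all genes maps everything to intergenic. The 1-kb window is the
usual divergent-promoter convention and is the one tunable; "sense" is
interpreted as same-strand exonic overlap (full containment is a plausible
alternative no published proportion table can adjudicate). Distances are
interval gaps, 0 when overlapping.

## The synthetic-data generator

The generator is first-class, tested code and defines the study conditions:

* two tissues with context base levels CG 0.60, CHG 0.40, CHH 0.04 (tissue
  A, leaf-like) and CHH 0.07 (tissue B, root-like) — the published
  two-tissue contrast direction with level magnitudes matching the printed
  per-context means;
* coverage Poisson with mean 25 per cytosine, independent between tissues
  (published depths are genome-wide aggregates ~26–29×; no positional bias
  is modeled), sites with zero draws omitted;
* TE bodies get an additive level boost (+0.15) — TE hypermethylation;
* metagene shaping as piecewise-constant multipliers at 100-bp resolution
  (flank / TSS-dip over ±100 bp / body), matching the profiling interval and
  keeping truth bookkeeping exact rather than smooth;
* 20 planted CG DMRs of 500 bp at levels 0.8 vs 0.2, placed in intergenic
  space ≥ 1 kb apart so truth matching is unambiguous;
* expression from the hurdle model itself (logistic zero part, truncated-NB
  count part) on the true methylcytosine-count covariates, with slopes on
  the per-mC scale of published hurdle coefficients (±0.004–0.012) and RPKM
  derived from counts, gene length and a fixed library size of 10⁶;
* 24-nt siRNA loci at Poisson intensity 5/kb in TEs, decaying exponentially
  with TE-to-gene distance (scale 2 kb), plus a reduced background over gene
  upstream flanks; a third of TEs are placed directly in gene upstream
  flanks so the distance gradient is populated;
* genes of 1–5 exons with ≥ 2 kb spacing, TE families uniform over the ten
  canonical families (class I retrotransposons: Copia, Gypsy, LTR-Other,
  LINE, SINE; class II DNA transposons: DNA-Other, hAT, MULE-MuDR, EnSpm,
  Stowaway), and twelve lncRNAs cycling the six positional classes.

One master seed drives keyed per-stage sub-seeds, so adding a stage never
perturbs earlier stages' draws and identical configurations give
byte-identical outputs.

**What passing tests do and do not show.** The generator draws independent
binomial reads at piecewise-constant true levels. Real methylomes have
bimodal per-site CG levels, spatially autocorrelated methylation states,
mappability- and GC-driven coverage bias, bisulfite non-conversion, allele-
and homeolog-specific methylation — none of which are modeled. Recovering
planted DMRs here shows the caller implements its criteria correctly and
localizes change points at this coverage and contrast; it does not promise
the same recall on noisy real data. Likewise the hurdle-recovery tests
validate the estimator, not the biological claim that methylation drives
expression.

**Default problem sizes.** The stock configuration simulates 2 chromosomes
× 200 kb with 20 genes, 15 TEs, 12 lncRNAs and 20 planted DMRs — enough for
every rule to have multiple instances while a full study simulates in
seconds. Parameter-recovery runs scale to 10 × 2 Mb and 2000 genes with
CG-only reports, the size at which ±3 SE recovery checks have useful power.

## Numerical conventions

* Fold changes use ε = 0.001 pseudocounts on both levels.
* Chi-square is Pearson's without Yates correction (the named test), on
  pooled reads; site-count tables would discard coverage information.
* Histogram bins are left-closed with a right-closed top bin, so level-1.0
  sites land in the tenth bin; windows tile from coordinate 0 and a final
  partial window is kept (flagged when chromosome lengths are known).
* Spearman uses average ranks for ties and the t-approximation p-value
  (exact available for small tie-free samples).
* Hypergeometric enrichment is upper-tailed with BH adjustment across terms.
* BED-style scores cap −log10(p) at 999.

## Known limitations

* The DMR caller assumes two pooled samples (no replicates); a
  replicate-aware dispersion model is out of scope.
* Candidate-level multiple testing is off by default by design (criterion
  fidelity); genome-wide FDR control is the caller's `adjust = "BH"` option,
  not the default.
* The lncRNA class rules are one defensible formalization of an
  under-specified vocabulary; published class proportions cannot distinguish
  rule variants without the underlying data.
* `nearest_gene_distance` and the positional classifier treat annotations as
  literal intervals; fuzzy gene boundaries or nested genes are not modeled.
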