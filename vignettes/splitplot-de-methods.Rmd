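---
title: "Methods: split-plot differential expression across tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-plot differential expression across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitplotDE)
```

## The design and its covariance structure

The package targets studies in which subjects — here RNA pools, each an
equal-mass pool of several animals — belong to one of two physiologic states
(the between-subject factor) and every subject is assayed once in each of
several tissues (the within-subject factor). The default layout is 4 tissues
x 2 states x 4 pools per state = 32 chips, with pools nested in state: pool
1 of the control group and pool 1 of the treated group are different
animals. Dimensions are inferred from the design table, so reduced layouts
(2 tissues, 2 pools) run identically; only the two-state restriction is
fixed, because every downstream contrast is the treated-minus-control
difference.

Chips from one subject share whatever makes that subject different — RNA
quality, pooling composition, animal-level biology — which the model carries
as a subject random effect added to every tissue measurement. With a common
residual variance this is exactly compound symmetry: equal variances, equal
pairwise covariances within a subject. The generator builds its data the
same way (a per-subject normal deviate shared across tissues), so the
assumption holds by construction in every simulated study, and a test
verifies the empirical within-subject covariance is flat.

## Per-gene tests

For a balanced layout the corrected total sum of squares splits exactly into
state, pool-within-state, tissue, interaction and residual components
(`decompose()`, vectorized in `splitplot_fit()`; conservation of the total
is asserted for every gene). The exact F-tests follow the two error strata:

* physiologic state against pool-within-state on `(S-1, S(P-1))` df — with
  the default 4 pools per state this denominator has only 6 df, which is
  why the overall state screen is kept at the permissive 0.05 level;
* tissue and interaction against the within-subject residual on
  `(T-1, S(P-1)(T-1))` df.

These are the uniformly standard exact tests for balanced
compound-symmetric data and coincide with the mixed-model F-tests; the test
suite checks them to 1e-8 against `aov()` error-strata fits and the
REML-based `lmerTest` path.

**Simple effects.** The treated-minus-control contrast inside one tissue
compares observations that differ in subject, so its variance mixes both
strata: `Var = 2 (sigma_resid^2 + sigma_pool^2) / P`, estimated by the
combined error mean square `MS_c = (MS_pool + (T-1) MS_resid) / T`. Because
`MS_c` is a linear combination of two mean squares, the reference t
distribution uses Satterthwaite degrees of freedom. This construction is a
declared choice — a between-within contrast has no single exact test — and
it matches the `emmeans` Satterthwaite contrast to well under 0.1% on
balanced data whenever the moment estimate of the pool variance is
positive. The approximation is very mildly anti-conservative at these
sample sizes (empirical size ~0.012 at nominal 0.01 under the null, within
three binomial standard errors in the 5,000-gene calibration runs).

**Variance components.** Method of moments: `var_resid = MS_resid`,
`var_pool = (MS_pool - MS_resid) / T`. The pool component is reported
unmodified even when negative — clamping would bias the ensemble of
per-gene estimates and has no effect on the F-tests, which use the mean
squares directly. A `clamp_var_pool` flag is available for users who want
the conventional nonnegative summary. Recovery is unbiased within 5% over
5,000 simulated genes.

**Fold ratios.** Ratios are computed on the untransformed scale — the mean
of `2^y` over treated chips divided by the control mean, within a tissue —
because a ratio of anti-logged means is the quantity a bench scientist
compares against qPCR. The chips themselves are the samples; no per-pool
collapsing is applied (each chip already is one pool).

## Detection and annotation filtering

An exon is present on a chip when its detection-above-background p-value is
strictly below 0.01. A gene is expressed when **the same exon** is present
on at least two chips of one tissue x state group. The alternative reading —
any exon of the gene on each of two chips — is implemented behind
`mode = "any_exon"`; the same-exon reading is the default because it is the
stricter quantifier order and the two differ only for genes whose detection
is scattered across exons. Genes with an empty, whitespace or `"---"`
description are dropped as unannotated; genes absent from the annotation
table are treated as unannotated rather than as an error so partial
annotation files do not abort a run. Tested = expressed AND annotated,
exactly.

## Calling, PFP and q-values

A gene is differentially expressed in a tissue when the overall state
effect has `p < 0.05` **and** the within-tissue simple effect has
`p < 0.01`, both strict. The overall screen protects against the four
repeated within-tissue looks; the stringent within-tissue cutoff does the
per-tissue work. The proportion of false positives among a detected list is
estimated as `PFP = cutoff x n_tested / n_detected` — the rejections
expected by chance over those observed — reported at two decimals in
summaries and at full precision in data structures. Per-tissue PFP rows
count genes by the within-tissue p alone, because the dual-threshold list
is a subset of the within-tissue list and both tests address the same gene.

Two q-value modes are provided. The default computes, for each p, the
expected chance positives `p * m` divided by the number of results at or
below p (ties share the rank "count at or below"). This quantity is not
monotone in p; the `step_up` mode enforces monotonicity by the cumulative
minimum from the largest p, which is the standard Benjamini–Hochberg
adjusted p-value (verified against `p.adjust` and a threshold-scan oracle).

One intrinsic property of dual-threshold calling deserves note: for a truly
null gene the overall state p and the within-tissue p are strongly
positively correlated (the state numerator is the average of the per-tissue
numerators, and the tests share denominators), so the probability that a
null gene is called DE somewhere is about 2% — several times the naive
independence product, and the reason detected lists at these thresholds
still carry the PFP levels the estimator reports. The pattern-recovery
check in the acceptance suite measures this rate directly.

## Pattern coding

Per tissue, three factors multiply: the tissue weight (1000, 100, 10, 1 for
liver, duodenum, jejunum, ileum — generally `10^(T-1)` down to 1), a
tendency multiplier (1 if the within-tissue `p < 0.05`, else 0) and a
direction (+1 if the fold ratio exceeds 1, else -1). The tendency threshold
is looser than the DE cutoff deliberately: a gene clearly changed in three
tissues and sitting at p = 0.03 in the fourth belongs in the all-tissue
pattern, not a three-tissue one. The sum over tissues is the gene's code;
genes not called DE anywhere are assigned 0 without computation. The
weights form a signed base: all 81 per-tissue change vectors map to 81
distinct codes (checked exhaustively) and `decode_pattern()` inverts the
map. A gene up in liver, duodenum and jejunum but down in ileum codes to
1000 + 100 + 10 - 1 = 1109. A fold ratio exactly equal to 1 under a
significant tendency is a measure-zero event on real data; it resolves to
+1 with a warning so the pipeline is total. Named groups (up/down in all
tissues = ±1111, up/down in the small intestine only = ±111, up/down in
liver only = ±1000, down in duodenum only = -100) are assigned by exact
code; every other nonzero code is reported under its integer.

## Overrepresentation

Gene sets are tested by the exact hypergeometric upper tail (no chi-squared
approximation at any table size), with membership intersected against the
background before the margins are formed. The default background is the
tested-gene universe — the genes that actually had a chance to appear in a
DE list; a whole-chip universe can be passed instead where a
platform-referenced background is wanted. Curated panels are tested per
tissue with the positive call defined by the within-tissue p alone (default
cutoff 0.01), not the dual-threshold call, since a panel question ("does
this regulon respond in this tissue?") should not be gated on the overall
screen. Panels ship as editable gene lists, not hard-coded biology.

## Reference genes

Candidates are the 20 genes with the smallest coefficient of variation
among those with mean log2 intensity >= 10. The CV is computed on the log2
scale by default — the same scale as the selection floor — with a linear
option. Stability scoring follows the variance-decomposition idea of
NormFinder-style selection: after centering each sample by its mean across
candidates (removing chip-level loading), a gene's score is
`|between-state difference| + within-state SD`, penalizing bias and scatter
in the units of the data. This is a declared, self-contained score in the
spirit of that approach, not a re-implementation of any particular
software. The best single gene is rank 1; `best_pair()` scores every pair's
average profile the same way. The normalization constant is the per-sample
geometric mean of the chosen genes' untransformed intensities, computed in
the log domain (`2^mean(log2)`), with the two computation paths agreeing to
1e-12.

## The generator and what passing tests show

`simulate_study()` draws per-gene baselines (default N(7, 1.5^2) log2),
fixed tissue effects (SD 1), a planted treated-state shift per the
pattern table, subject effects (SD 0.3) and residual noise (SD 0.3) — noise
magnitudes typical of well-normalized array data. Detection p-values are
simulated directly (present exons draw p < 0.01 with probability 0.9,
otherwise uniform); the generator guarantees the filter outcome matches the
truth ledger by rare marginal redraws, so filter tests are exact. Default
fractions (20% undetected, 7.3% unannotated) mirror a full-scale exon-array
study in which roughly 73% of genes survive both filters; the default gene
count is 2,000 for speed, with a `paper_scale` preset at 19,434. A single
root seed drives named substreams per table, so adding a table never
perturbs another's draws.

Default planted effects are 1 log2 unit (2-fold), a realistic median for
strongly responsive transcripts. For the pattern-recovery validation the
planted effect is frozen at 1.5 log2 after a one-time pilot: recovering an
exact four-tissue code requires all four tendency tests to pass
simultaneously, and at 1.0 log2 that joint requirement says more about
multiplicity than about the coding machinery, while at 1.5 the per-tissue
tendency power is near 1 and recovery is comfortably high. Calibration runs use 5,000 genes (null
size and uniformity, variance-component recovery), oracle sweeps use 50
random small designs, and enrichment ranking uses 100 replicates — sizes
chosen so the whole suite runs in well under a minute of fitting time.

What the synthetic studies do **not** emulate: probe-level intensities and
their GC structure (detection p-values are drawn, not derived),
normalization artifacts, heavy-tailed or gene-correlated noise,
mean-variance dependence, and unbalanced or missing chips. Passing tests
therefore demonstrate the correctness of the statistics under the model the
analysis assumes, not robustness to violations of it.

## Numerical conventions and limitations

Strict inequalities at every threshold; p-values are never rounded
internally and are serialized at full precision (tables round-trip to at
least 12 significant digits). Degenerate fits (zero denominator mean
square) report p = 1 when the numerator is also zero, else 0, and are
flagged. Only complete balanced designs are supported — a missing cell is
an error, not an approximation — and only two states. REML/GLS fitting is
used as a test oracle, never in the main path, which is closed-form
throughout.
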