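---
title: "ontodyn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ontodyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontodyn)
```

# The problem

A developmental expression study samples one tissue at an ordered series
of ages with biological replicates and quantifies transcript abundance
as FPKM. The default design in this package is 12 ages (−2, 0, 1, 3, 5,
10, 15, 20, 25, 30, 45, 60 days relative to birth) with three
replicates, i.e. 36 samples. The analysis questions are: which genes are
meaningfully expressed and change with age; what the dominant temporal
programs are; which upstream regulators plausibly drive each program,
singly or in modules; and how isoform usage shifts with age.

All statistics operate on FPKM (or log2 FPKM) abundances. Nothing in
the package touches reads, alignments or count models: the expression
table is the interface.

# Stage models and their assumptions

## Two-stage expression filter

A feature is *expressed* at an age when at least `min_replicates`
(default 2 of 3) replicate FPKM values reach `theta_fpkm` (default 1
FPKM). It is *differential* when a one-way ANOVA on log2(FPKM + 1)
across ages gives a Benjamini–Hochberg adjusted q ≤ α (default 0.05).
The *analysis set* is the intersection: expressed somewhere, and
changing over time.

Assumptions: dense tables (no missing values), ≥ 2 replicates per age,
and approximately age-wise homoskedastic log-scale noise. The
pseudocount of 1 stabilizes the variance of low-FPKM features at the
cost of compressing signals below ~1 FPKM, which is intentional — such
features fail the expression filter anyway. Two degenerate cases are
defined explicitly rather than left to the F statistic: when every age
has zero within-age variance, p is 0 if the age means differ and 1 for
a globally constant series.

## Temporal descriptive statistics

The gene expression rank of a per-age series assigns rank n to the age
of maximal expression and rank 1 to the minimal one, averaging ties, so
each gene's ranks sum to n(n + 1)/2 (78 at n = 12) and are invariant
under any strictly increasing transform of expression. Ranks are
computed on per-age replicate means; a per-replicate variant would
weight noisy replicates individually and is deliberately not the
default.

## Factor-analysis clustering

Each analysis gene's 12 age means (log2 scale) are standardized to zero
mean and unit SD; the genes are then treated as observations of the 12
age variables, and the common-factor model is fitted to the 12 × 12
correlation matrix. Loading columns are therefore temporal profiles.

* **Number of factors.** Horn's parallel analysis compares observed
  eigenvalues to the `quantile` (default 0.95) of eigenvalues from
  `n_sim` (default 200) null matrices. Two details matter. First, the
  null matrices are row-standardized exactly like the data: per-gene
  standardization makes every row zero-sum, which biases the age
  correlations (expected off-diagonal −1/(n−1)), and a null without the
  same structure is anticonservative. Second, exceedances are counted
  from the leading eigenvalue downward and stop at the first failure;
  counting all 12 positions independently would admit a spurious factor
  in roughly 1 − 0.95^12 ≈ 46% of pure-noise datasets.
* **Extraction.** Principal-axis factoring, iterating communalities to
  a 1e-8 fixed point (error after 500 iterations). Initial
  communalities are squared multiple correlations when the correlation
  matrix is invertible; because row standardization makes it exactly
  singular, the fallback is the maximal absolute off-diagonal
  correlation per age — a standard PAF starting value. Maximum
  likelihood (`method = "ml"` via `factanal`) is available for
  non-degenerate inputs.
* **Rotation.** Varimax without Kaiser normalization. The single-start
  pairwise algorithm can converge to a local optimum of the varimax
  criterion on near-degenerate eigenstructures (three planted programs
  of comparable strength make the leading eigenvalues nearly equal), so
  the fit restarts from `n_starts` (default 20) random orthogonal
  rotations with a fixed internal seed and keeps the best criterion
  value. Communalities are invariant to all of this, rotation being
  orthogonal.
* **Assignment.** Each gene's standardized age-mean series is
  correlated with each loading column; the gene joins the factor of
  maximal |r| when |r| ≥ `cutoff` (default 0.7; roughly half the series
  variance explained at n = 12). The sign of r separates the expression
  (+) from the suppression (−) sub-cluster. Age means, not the 36
  individual samples, are used because the loadings are defined per
  age. Zero-variance series are flagged and left unassigned.
* **Labels.** With k = 3 the (factor, sign) pairs map to the six
  temporal groups. Factor order and sign are arbitrary after rotation,
  so the map is derived from loading peak timing — but canonicalizing
  each factor's sign in isolation ("flip so the peak is positive") is
  unstable when a factor's two orientations peak at similar heights
  (typical for the late-rising factor, whose negation has a mid-series
  bump). The package instead solves a small assignment problem: all 8
  orientation combinations × 6 role permutations are enumerated and the
  combination whose peak positions best match early/mid/late targets
  (ages 1, 0.4n, n in index units) wins. The label map is then: early
  factor + → *Prenatal and Neonatal*, − → *Adolescent and Adult*; mid
  + → *Neonatal and Adolescent*, − → *Prenatal and Adult*; late
  + → *Adult*, − → *Neonatal*.

## Set-association statistics

All overlap enrichment reduces to the upper hypergeometric tail
P(X ≥ k | N, K, n), which equals the right-tailed Fisher exact p on the
corresponding 2 × 2 table; the package computes the tail once
(`phyper`) and the Fisher interface simply builds the counts. Activation
z-scores are unweighted sign-consistency sums, z = Σsᵢ/√N over targets
with a known expected direction (sᵢ = +1 for agreement), with |z| ≥ 2
the conventional significance line; a fold-change-weighted variant was
considered and rejected because weights would need calibration the data
cannot provide. Per-age differential direction is the sign of
log2(age mean / geometric mean over ages).

BH adjustment is the standard step-up. It is order-preserving in the
p-value ranks but *not* idempotent (p = (0.4, 0.9) adjusts to
(0.8, 0.9), which re-adjusts to (0.9, 0.9)) — a property worth knowing
before re-adjusting already-adjusted columns.

## Intraclass correlation and regulatory modules

The ICC of m expression series over n ages anchors each series by
standardizing it, then applies the two-way ANOVA decomposition:
ICC = (MSB − MSE)/(MSB + (m − 1)·MSE), clipped to [−1, 1]. With this
anchoring the statistic has clean edge cases — identical series give 1,
exactly opposite pairs −1 — and algebraically equals the mean pairwise
Pearson correlation of the standardized series (the test suite uses
that identity as an independent oracle). Negative ICC captures
diametrical regulator pairs, which are biologically meaningful
(repressors rising as their targets' activators fall).

Module discovery seeds one entry per regulator (its targets restricted
to the temporal group under analysis), then iteratively merges entry
pairs — union of regulators, **intersection** of targets — keeping a
merge when |ICC| ≥ `icc_cutoff` (0.6) and the shared target set has at
least `min_targets` (5) genes. Each cycle pairs the previous cycle's
new entries against everything; entries are de-duplicated by regulator
set (first construction wins, with constraints always re-evaluated on
the merged set); termination is guaranteed because entries are subsets
of a finite regulator set. Intersection (rather than union) of targets
is the right merge semantics because a module's targets should be
co-regulated by *all* members. The target-size constraint is enforced
at every merge by default; `min_targets_seed_only = TRUE` implements
the alternative reading in which only the initial 2-tuples are
constrained.

## Isoform analyses

*Variant usage.* The transcript × age table of per-age mean FPKM is
tested for homogeneity with a chi-square statistic; FPKM acts as the
weight, so highly expressed ages dominate. FPKM is not a count, so the
p-value is a working approximation, not an exact sampling statement —
adequate for ranking genes by usage-shift evidence. All-zero
transcripts and zero-total ages are dropped; if fewer than two of
either remain the test is flagged not-applicable with p = 1.

*Novel-isoform filter.* Candidates must first be expressed in ≥ 1 age.
The survivors' per-age mean log2 series are then tested for positive
temporal autocorrelation with the Durbin–Watson statistic
d = Σ(eₜ − eₜ₋₁)²/Σeₜ² on mean-centered residuals (no regression model
is posited, so centering is the residual definition). Significance is
by permutation of the age order — the classical DW bounds assume
regression residuals and are inapplicable to a 12-point mean-centered
series — one-sided toward d < 2, since temporal coherence is the
selection goal: p = (1 + #{d_perm ≤ d_obs})/(n_perm + 1), n_perm ≥ 999,
one shared seeded permutation set across candidates. BH is applied
across stage-1 survivors only, mirroring the two-stage narrowing of the
candidate pool, and q ≤ α keeps a candidate.

*Splice events.* Transcript models live in 0-based half-open
coordinates; conversion happens only at the GTF boundary (1-based
inclusive), so interval arithmetic is unambiguous. A novel model is
compared to the reference sharing the most splice junctions (ties
broken by exonic overlap in bp, since a skipping variant's new junction
may exist in no reference). Rules: internal reference exon uncovered by
any novel exon and contained in a novel intron → exon skip; novel exon
strictly containing a reference intron and both flanks → intron
retention; internal novel exon overlapping no reference exon →
alternative exon; strand-aware transcription start/end boundary shifts
→ alternative start / termination. Events can co-occur; with no
reference for the gene the event is "unclassified".

# The synthetic-data generator

`simulate_expression` draws, per gene, a class (six archetypes plus
"null"), a baseline log2 FPKM (uniform within ±3 of
`baseline_log2_mean` = 5, i.e. ~4–256 FPKM), an amplitude (uniform on
0.8–2.5), and produces FPKM = 2^(baseline + amplitude·shape(age) + ε)
with ε ~ N(0, `noise_sd`) per sample. Log-normal noise on the log2
scale — not a count model — matches a pipeline whose inputs are FPKM.
The default `noise_sd` = 0.3 puts replicate log-expression correlations
for typical signal genes in the high-0.9s, the range a well-powered
bulk experiment shows. The default mix (six archetypes at 0.125 each,
0.25 null) keeps the archetypes uniform while retaining an unassigned
remainder, as real analysis sets have.

The three base shapes (early-high declining; mid-development peak;
late rise) are configuration data generated by `archetype_profiles`:
qualitative sigmoid/bump seeds refined by alternating projections until
they are simultaneously zero-mean/unit-SD per column, exactly mutually
uncorrelated, of equal row norm at every age, and a varimax fixed
point. The last three properties make the generator self-consistent
with the estimator: correlation-based extraction rescales each age by
its across-gene SD, and unless the shapes carry equal energy at every
age that rescaling warps the factor frame away from the truth;
likewise, unless the truth frame is varimax-optimal, rotation converges
elsewhere and planted labels become unrecoverable *by construction*
rather than by noise. The six archetypes are the three shapes and their
negations, so "group recovery" is a well-posed closed loop. The shapes
are qualitative stand-ins: real temporal programs are not exactly
orthogonal, and real loading profiles are not equal-energy. Passing
recovery tests therefore demonstrates estimator correctness under the
model's own geometry, not performance guarantees on real tissue.

`simulate_network` plants modules by giving each planted regulator its
module group's shape (alternating sign for anti-correlated modules,
amplitude 2, noise SD 0.1) and appending those rows to the matrix, plus
decoy regulators with independent noise and random decoy edges that are
forbidden from colliding with planted edges. `simulate_isoform_series`
contrasts archetype-following series with i.i.d. (age-exchangeable)
white-noise series; `simulate_transcript_events` edits a reference exon
chain by exactly one requested event. A single integer seed drives each
generator through `withr::with_seed`, so fixtures regenerate
independently and bitwise-identically.

What the generator does not emulate: count-level sampling noise and its
mean–variance relation, length/GC biases, litter or sex covariates,
correlated gene–gene noise beyond the planted programs, partially
overlapping regulator programs, and isoform series whose
autocorrelation comes from slow drift rather than a smooth program.

# Numerical choices and degenerate inputs

* Expression tables are written with 15 significant digits; round-trips
  are identity to 1e-9.
* Hierarchical clustering (`hier_cluster_order`) supports Euclidean +
  Ward (hclust `ward.D2`) and correlation + average; Ward with a
  non-Euclidean distance is rejected as an invalid combination. With
  continuous data merges are unique; exact ties fall back to `hclust`'s
  deterministic ordering.
* `oneway.test(var.equal = TRUE)` is the ANOVA engine; the degenerate
  zero-variance rules above bypass it.
* Permutation p-values obey the add-one bound p ≥ 1/(n_perm + 1).
* All validation errors name the offending feature/sample/line.

# Problem sizes in the shipped tests

The test suite exercises the clustering recovery surface at 600 genes ×
5 seeds (noise SD 0.3), module-discovery oracle equivalence on fixtures
of up to 6 regulators against exhaustive subset enumeration, and error
control at 2,000 null features × 3 seeds for both the differential test
and the isoform filter. These sizes make the Monte-Carlo standard
errors small relative to the tested bounds while keeping the default
test run fast; nothing in the methods depends on them.

# Known limitations

* The six-group label map is defined for k = 3; other k values fall
  back to generic factor labels, since the six-group vocabulary has no
  meaning there.
* The variant-usage chi-square treats FPKM as weights, not counts (see
  above); standardized residuals are reported for per-age follow-up
  rather than per-age p-values.
* The activation z-score is unweighted; with a network supplying edge
  confidences a weighted variant would be preferable.
* Module discovery is exhaustive over merge pairs and intended for
  regulator sets of network scale (hundreds), not genome scale.
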