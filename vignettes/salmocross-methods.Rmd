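---
title: "Methods: expression inheritance in wild x domesticated salmon crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression inheritance in wild x domesticated salmon crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmocross)
```

## The design and the question

Escaped farmed Atlantic salmon interbreed with wild populations, so the
transcriptional consequences of domestication — and how they are inherited in
first-generation hybrids — matter for wild-population management. The design
this package implements compares three crosses (wild x wild; domesticated dam
x wild sire, the "hybrid"; domesticated x domesticated) at two fry stages
(sac fry and feeding fry), with six biological replicates per group: 36
hybridisations in total. Each sample is measured on a two-colour microarray
against a common reference pool made from equimolar amounts of every
experimental sample, so all downstream statistics operate on per-probe log2
sample/reference ratios (M values).

Because hybrids here come from only one cross direction (domesticated dam),
dominance toward the domesticated parent is confounded with maternal (egg-
deposited) effects. The package keeps the field's terminology —
"maternal/domesticated dominant" — and makes no attempt to separate the two;
the simulator models maternal effect as dominance toward the dam, with an
optional explicit maternal offset switch left to sensitivity analyses.

## Preprocessing: flooring, lowess, probe retention

Background-subtracted intensities at or below 1 are floored to 1, then each
array is normalised in M/A coordinates: `M = log2(sample/reference)`,
`A = (log2 sample + log2 reference)/2`, and a lowess fit of M on A is
subtracted, removing smooth intensity-dependent dye bias. The lowess span is
0.3 with 3 robustness iterations; both are exposed. The span is a
bias-variance compromise: on a simulated bias curve `0.5*sin(A/4)` a refit of
the normalised output stays below 0.01 log2 units provided the A range is
densely populated. With sparse A tails (a few thousand probes) local
regression develops edge bias of up to ~0.02; the package's own flatness
checks therefore run at 10,000 probes, about a quarter of the 43k-probe
platform the design emulates.

Two numerical points deserve note. First, lowess normalisation is only
identity-preserving on data whose M carries no A-structure; a finite mixture
of null and perturbed probes makes the local mean slightly nonzero, so exact
round-trip reconstruction of planted parameters (used in the tests) goes
through `qc_normalize(normalize = FALSE)`. Second, normalisation is strictly
per array: permuting arrays permutes output columns and nothing else.

Probe retention implements the detection-flag rule: a probe is kept when it
is "positive and significant" on at least 75% of the arrays in at least 2 of
the 6 experimental groups. The 75% is evaluated as
`ceiling(fraction * n_g)` on the post-exclusion group size (a 5-array group
needs 4 of 5); "at least 75%" reads naturally as a ceiling-ed count, and the
rule is monotone — adding a detection never removes a probe. The array-level
screen projects arrays onto the first two principal components and flags
arrays beyond a robust (median/MAD) distance threshold; it never drops
arrays automatically, because outlier exclusion combined software flags with
human judgement in the original workflow.

## Differential expression

Life stages are analysed separately throughout. Pairwise comparisons
(wild–domesticated, wild–hybrid, hybrid–domesticated) use the unpaired
unequal-variance (Welch) t-test. Two criteria are computed per probe:

* strict — `p <= 0.01` and linear fold change `>= 1.3`, uncorrected; these
  lists feed the three-set Venn partitions, per stage and as the union
  across stages;
* lenient — `p <= 0.05` with no fold-change gate; this list feeds the
  pathway analysis, where the gene-set test itself supplies the multiplicity
  control.

Fold changes are computed from log2-scale group means and exponentiated
(whether the original workflow averaged on the log or linear scale is not
documented; log-scale is the package's choice and a linear-scale switch would
be a one-line change around `signed_fold_change()`). Ratios below 1 are
reported as `-1/ratio`, so 0.5 becomes -2 and down-regulation reads on the
same scale as up-regulation.

Gene selection for the inheritance analysis uses Welch's one-way ANOVA across
the three crosses with Benjamini–Hochberg control at 10% FDR, computed across
all retained probes, then collapsed to unique annotated genes (smallest p per
gene, ties by probe id). The BH-then-dedupe order is a deliberate choice: the
FDR statement applies to the tested probe set, and the unique-gene rule is a
reporting convention applied afterwards.

Degenerate inputs follow fixed conventions: zero variance in both groups
gives p = 1 when means are equal and p = 0 otherwise; the same logic applies
per ANOVA row. Row-wise Welch statistics are closed-form vectorised and are
tested against `stats::t.test()` / `stats::oneway.test()` on the same data.

## The directional gene-set test

The set test follows the GAGE idea: a set is perturbed when its genes' fold
changes differ in mean from the background genes' fold changes. The
implementation fixes one scheme among the published variants:

1. one-on-one pair columns — every treatment array paired with every control
   array (6 x 6 = 36 columns of per-gene log2 differences), domesticated (or
   hybrid) as treatment, wild as control;
2. per column, a two-sample Welch t of set genes versus all background
   genes — upper-tailed for `up`, lower-tailed for `down`, upper-tailed on
   |contrast| for `two_way`;
3. per set, the per-column p-values are combined by a Stouffer sum;
4. BH across sets within each direction, significance at q <= 0.1, minimum
   set size 10 (the smallest pathway worth reporting in this design).

Step 3 needs care. Two pair columns that share a treatment (or control)
array share that array's entire measurement, so their set-level mean
contrasts are correlated — exactly 0.5, independent of noise levels, because
the shared array contributes half of each contrast's variance. Summing 36
such z-scores as if independent inflates the variance six-fold and destroys
calibration. The package therefore divides the Stouffer sum by the
structural standard deviation `sqrt(k + 0.5 * S)`, where `S` counts ordered
column pairs sharing an array. A second-order dependence remains (per-set
variance estimates are shared across columns), so when at least 30 sets are
tested the sums are additionally standardised against their own empirical
null — median-centred and MAD-scaled across sets, in the spirit of Efron's
empirical-null inference; the MAD is robust to a minority of genuinely
perturbed sets. Under label-permuted and fully null simulations the
resulting set p-values are indistinguishable from uniform by a KS test.

Even with perfect calibration, a note on interpreting "unique" calls: with
~200 candidate sets, BH at q <= 0.1 will co-call at least one truly null set
alongside an overwhelming true positive in roughly one run in five, simply
because the smallest of 199 uniform p-values falls below `0.1 * 2/200` that
often. Uniqueness of a single pathway call is thus not a stable property of
any FDR-controlled test at this scale.

Significant sets are post-processed as in the esset.grp/essGene pair of
analyses: sets sharing at least half of the smaller set's genes are merged by
transitive closure, each cluster represented by its smallest-p member; and
"essential" genes are members of significant sets whose mean contrast is more
than one standard deviation away from the grand mean of all genes' mean
contrasts. Essential genes are ordered by hierarchical clustering on
`1 - Pearson r` with average linkage (zero-variance genes are reported and
excluded; `hclust`'s deterministic merge order is kept).

Gene sets labelled with an excluded functional group (by default "Human
Diseases", hard to interpret in fish) never reach testing.

## Inheritance-mode classification

For each unique gene with cross means W (wild), H (hybrid), D (domesticated)
on the normalised log2 scale:

* additivity parameter: `alpha = (W - D) / 2`
* dominance deviation: `delta = (W + D) / 2 - H`

`delta/alpha = 0` is perfect within-locus additivity; `+1` is complete
dominance toward the domesticated dam (H = D); `-1` complete dominance toward
the wild sire (H = W). Classification halves the intervals:

| delta/alpha | mode |
|---|---|
| [-0.5, 0.5) | additive |
| [0.5, 1.5) | maternal / domesticated dominant |
| [-1.5, -0.5) | paternal / wild dominant |
| otherwise | overdominant |

Bounds are closed below and open above; the underlying convention uses
strict inequalities, which leaves boundary points undefined — they occur with
probability zero on continuous data, and a fixed convention keeps the
classification total. When `alpha = 0` the ratio is undefined: `delta = 0`
is additive, `delta != 0` overdominant (the hybrid leaves a degenerate
parental range). Classification is invariant to adding a constant to all
three means, and swapping W with D negates alpha and mirrors the maternal
and paternal classes.

The scatter-table export reports per-gene `alpha` and `delta/alpha` with
per-axis SDs obtained by recomputing both quantities on matched replicate
arrays (replicate r of each cross); genes with |ratio| beyond a plot limit
(default 5) are flagged for exclusion from plotting but kept in the table,
mirroring how extreme-ratio transcripts are handled in scatter figures of
this kind.

A quantitative caveat the package's own simulations make explicit: the ratio
`delta/alpha` is noisy when the parental divergence is modest. By the delta
method, for a completely dominant transcript with divergence `2*alpha` and
group-mean standard error `SE`, the ratio's SD is about `2.8 * SE / alpha`.
At a biological SD of 0.25 (plus technical 0.1 per channel), n = 6 and a
1-log2 parental difference this is ~0.33, so 10–15% of truly dominant
transcripts fall outside their half-unit interval; overall mode recovery
plateaus near 85–90% and the recovered dominant fraction is biased downward
by a few points. Reliable (>95%) per-gene mode assignment at n = 6 needs
either a parental divergence of ~2 log2 units or within-group biological SD
below ~0.19. This is a property of the interval statistic itself, not of the
implementation, and it should temper interpretation of per-gene mode calls
on real data of similar depth.

## The simulator

The generator is first-class, tested code; its defaults are the study
conditions. Per gene it draws a baseline log2 level (normal, mean 10, SD
1.5 — a typical mid-range intensity spread for this platform class), plants a
wild-vs-domesticated offset `effect` (default 1.0 log2, sign random) in a
configurable fraction of genes, and assigns each differentially expressed
gene a mode; the default mode mix (45 / 42.2 / 6.1 / 6.7% additive /
maternal / paternal / overdominant) follows the feeding-fry proportions
observed in this system. Overdominant hybrids sit `overdominance_shift`
(default 0.5) log2 units outside the parental range — far enough that
|delta/alpha| exceeds 1.5 whenever the effect is nonzero — on the maternal or
paternal side (symmetric by default; a 3:1 maternal skew is available, as
seen in this system). The reference pool is the equal-weight mean of the six
group means per gene, matching an equimolar pool of all samples.

Noise has three components, all configurable: a biological deviate per gene
and array (default SD 0.25 log2), a technical deviate per probe, channel and
array (default SD 0.1), and i.i.d. Bernoulli detection-flag failures
(default rate 0.05). The magnitudes of the biological and technical
components are not documented for the original experiment; the defaults are
the package's own choices of a realistic signal-to-noise regime for 44k
oligo arrays with pooled-reference hybridisation, and the replicate log-ratio
SD converges to `sqrt(bio^2 + 2 * tech^2)` by construction. An optional
smooth dye-bias curve of A is added to the sample channel to exercise the
lowess step.

What the simulator does not emulate — and what green tests therefore do not
certify on real data: spatial array artefacts, dye-swap structure,
probe-sequence effects, correlated (non-Bernoulli) detection failures,
heavy-tailed biological variation, and cross-gene expression correlation
outside planted pathways. Test problem sizes are chosen to be desk-scale
(2,000–10,000 probes, 10–20 simulation replicates) while keeping every
statistical check at its stated tolerance.

## Defaults at a glance

| parameter | default | where | note |
|---|---|---|---|
| replicates per group | 6 | `build_design` | 36 arrays |
| retention fraction / groups | 0.75 / 2 | `filter_probes` | ceiling on group size |
| lowess span / iterations | 0.3 / 3 | `qc_normalize` | per array |
| strict p / fold change | 0.01 / 1.3 | `pairwise_de` | uncorrected |
| lenient p | 0.05 | `pairwise_de` | feeds set test |
| set-test q / min size | 0.1 / 10 | `gage_set_test` | BH within direction |
| ANOVA FDR | 0.10 | `bh_fdr` | BH step-up |
| plot limit on delta/alpha | 5 | `export_fig4_table` | flag only |
| biological / technical SD | 0.25 / 0.1 | `noise_model` | log2 units |
| flag failure rate | 0.05 | `noise_model` | i.i.d. |

## Worked example

```{r example}
design <- build_design(6)
arch <- simulate_architecture(500, de_fraction = 1, effect = 1, seed = 7)
raw <- simulate_intensities(design, arch,
                            noise_model(biological_sd = 0.1,
                                        technical_sd = 0.05, seed = 7))
expr <- qc_normalize(raw)
rec <- classify_mode(compute_alpha_delta(cross_means(expr, "feeding")))
summarize_proportions(rec)[, c("mode", "n", "percent")]
```

## Known limitations

* One hybrid direction only: maternal effects and domesticated-allele
  dominance are inseparable by design.
* The set test is a GAGE-style re-implementation, not a clone; its pairing
  scheme, dependence correction and empirical-null scaling are documented
  choices, and numerical agreement with any specific GAGE release is not a
  goal.
* Whether the original workflow's exported "normalised intensity values"
  were log2 or linear is not documented; all statistics here use the log2
  ratio scale, with the consequences confined to the fold-change and
  alpha/delta scales.
* Per-gene mode calls at modest divergence are noisy (see the delta-method
  caveat above); stage-level mode proportions are considerably more stable.
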