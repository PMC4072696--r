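---
title: "Detecting deregulated miRNA/TF regulatory loops: models and methods"
author: "mirloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting deregulated miRNA/TF regulatory loops: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirloop)
```

## The problem

MicroRNAs (miRNAs) and transcription factors (TFs) regulate gene expression
jointly, and their joint action is often organized in small network motifs.
The three motifs this package mines are:

* **Type I feed-forward loop (FFL)** — a miRNA simultaneously represses a
  TF transcript and an mRNA that the TF itself regulates;
* **Type II FFL** — a TF regulates both a miRNA and an mRNA that the miRNA
  represses, split into subtype **A** (TF activates the mRNA) and **B** (TF
  represses it);
* **Type III loop** — a miRNA targets both members of a gene pair whose
  proteins interact directly on a signaling-pathway map.

Given log2 expression matrices for mRNAs and miRNAs measured under two
conditions (for example matched normal and tumor tissue), a sample design
table, and regulatory-prior tables (TF→gene and TF→miRNA edges with
regulation sign, predicted and experimentally validated miRNA→gene edges),
the pipeline identifies the loops whose regulator nodes are deregulated
between conditions, scores them, and labels how well the observed
directions of change agree with the loop's wiring.

An FFL is *coherent* when the direct path from the upstream regulator to
the target mRNA carries the same net sign as the indirect path through the
intermediate regulator, and *incoherent* otherwise. Every miRNA→target
edge carries sign −1 (repression); for a Type I loop the coherence
therefore depends only on the TF→mRNA sign (activation ⇒ coherent), and
for Type II on the product of the two TF edge signs.

## Stage 1: differential expression

For feature $i$ the condition effect is
$\delta_i = \mu_i^{t} - \mu_i^{n}$, the difference of mean log2 expression
in tumor and normal samples, estimated by ordinary least squares from the
model *expression ~ intercept + condition (+ surrogate variables)*. The
per-feature residual variances $s_i^2$ on $d$ residual degrees of freedom
are shrunk toward an empirical-Bayes prior, $s_i^2 \sim s_0^2 F(d, d_0)$,
whose hyperparameters $(d_0, s_0^2)$ are estimated in closed form by
matching the first two moments of $\log s_i^2$ (a digamma/trigamma
inversion). The moderated t-statistic

$$ t_i = \frac{\delta_i}{c\,\tilde s_i}, \qquad
   \tilde s_i^2 = \frac{d_0 s_0^2 + d\, s_i^2}{d_0 + d} $$

is referred to a t distribution with $d + d_0$ degrees of freedom
($c$ is the coefficient's unscaled standard error). Two limits anchor the
implementation and are verified in the test suite: at $d_0 = 0$ the
statistic equals the classical equal-variance two-sample t, and at
$d_0 = \infty$ all posterior variances collapse to $s_0^2$. Benjamini–
Hochberg adjustment controls the FDR; features with adjusted values at or
below `fdr_de` (default 0.05, inclusive comparison) are called
differentially expressed, with direction $\pm 1$ taken from the sign of
the moderated t.

**Surrogate variables.** Tissue cohorts carry structured heterogeneity the
design does not record — molecular subtypes (such as gene-fusion status in
prostate tumors) or processing batches. The estimator here is a two-step
SVD/permutation procedure: residualize every feature on the condition
indicator, take right singular vectors of the residual matrix as candidate
covariates, and keep the leading $k$ whose normalized singular values are
significant against a permutation null (each feature's residuals permuted
independently; default 100 permutations, $\alpha = 0.10$, seeded). The
retained vectors are orthonormal and enter the model as fixed covariates.
Under pure noise the procedure keeps a component with probability
$\approx \alpha$, which the suite verifies as a calibration band rather
than a point value. The estimator is deliberately pluggable: any
samples × k matrix can be passed as `covariates`.

**Numerical choices.** P-values are floored at 1e-300 before logs; tail
probabilities are computed on the survival side; features with zero
variance across all samples are dropped with a warning rather than
yielding undefined statistics. Pairing information in the design is
recorded but not modeled by default — the default test is the two-group
comparison; a pairing factor can be added through the covariate interface.

## Stage 2: gene-set rescue (GSEA)

Per-transcript testing misses regulators whose own expression shifts only
modestly. Three set families are tested with a Wilcoxon rank-sum set test
on the moderated t-statistics:

* **TF target sets** — one set per TF *not* called by the per-transcript
  test, containing its directly regulated targets; tested with the
  undirected (`mixed`) alternative, which ranks $|t|$ one-sided toward
  large values.
* **Validated miRNA target sets** — only for miRNAs on an external
  whitelist (miRNAs independently established as deregulated in the tissue
  under study), with at least `min_set_size` (default 8) validated targets
  in the universe; each set is tested one-sided in the direction *opposite*
  to its miRNA's own change, because validated targets have historically
  been ascertained through inverse miRNA–target expression.
* **Pathway sets** — pathway memberships restricted to the universe,
  tested with the `mixed` alternative.

For universes of at most 10 features the p-value is computed by exact
enumeration of all rank splits; otherwise by the normal approximation with
tie-corrected variance and a 0.5 continuity correction. Across random
balanced configurations at the enumeration boundary the two routes agree
to about 0.01 on average (worst case ≈ 0.025); the continuity correction
was chosen once as the dialect that tracks enumeration most closely.
Whether the undirected test ranks $|t|$ or $t^2$ is immaterial for a rank
test (the transform is monotone on $|t|$); `mixed` on $|t|$ is the
implemented reading of "enrichment for deregulation".

BH adjustment is applied *within each family separately* (the three
families answer different questions and are reported separately), at
`fdr_gsea` (default 0.25). Regulators with a significant set are merged
with the per-transcript calls into combined deregulation lists; a feature
significant by both routes is listed once with source `MHT`, and
GSEA-rescued entries take the direction of their own moderated t.

## Stage 3: loop construction

The prior database is first restricted: TF edges survive only if the TF is
in the combined mRNA list (and the target is measured), miRNA edges only
if the miRNA is in the combined miRNA list. Both regulator nodes of a loop
must therefore be deregulated, while the *target* mRNA need not be — TF
deregulation does not force target deregulation, and incoherent loops can
cancel at the target. Loops are then formed by relational joins: Type I
joins (TF, mRNA) pairs with miRNAs targeting both the TF transcript and
the mRNA; Type II crosses (TF, miRNA) pairs with shared targets; Type III
takes direct interaction edges of pathways flagged by the enrichment stage
whose two expressed endpoints are both targeted by a combined-list miRNA
(indirect interactions are excluded). Construction is deterministic,
order-invariant in the prior rows, and never invents an edge — properties
enforced in tests against brute-force triple enumeration. Pathway pairs
are unordered and reported in lexicographic order.

## Stage 4: scoring, consistency, evidence

**Fisher score.** Each Type I/II loop combines the three *unadjusted*
per-transcript p-values of its nodes:

$$ T = -2(\ln p_1 + \ln p_2 + \ln p_3), $$

referred to the upper tail of a $\chi^2_6$ distribution (2 degrees of
freedom per combined test). The three node tests are not independent in
general, so the upper-tail probability is used as a *ranking score* —
lower is more significant — not as a formal p-value; dependence-aware
combinations (Brown, Kost) are out of scope. Under independent uniform
nulls the score is uniform, which the suite and the acceptance script
verify by simulation. Within each of the seven output groups (Type I
coherent/incoherent, II-A and II-B coherent/incoherent, III) the FFLs are
ranked by ascending score, ties broken lexicographically on
(miRNA, TF, mRNA) for reproducibility. Type III loops involve genes
rather than specific loop-node transcripts and carry no score or rank.

**Consistency.** Species joined by an activating edge should change in the
same direction; species joined by a repressing edge in opposite
directions. A loop is labeled *consistent* when (a) the regulator–
regulator edge obeys this rule and (b) the miRNA and its target mRNA are
anti-correlated. For coherent loops this pairwise rule is provably
equivalent to all three edges holding simultaneously; for incoherent loops
the three relations can never hold at once, so the pairwise rule is the
operative definition — an interpretation made deliberately, and one that
leaves every subtype with exactly 2 consistent assignments of the 8
possible direction triples (an enumeration test). Node directions are the
signs of the moderated t regardless of significance.

**Evidence.** Each miRNA→mRNA edge is categorized from its prior
provenance: predicted *and* validated ⇒ `true_positive`; validated only ⇒
`false_negative` (the predictive route missed it); predicted only ⇒
`novel`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fdr_de` | 0.05 | BH FDR for per-transcript calls (inclusive) |
| `fdr_gsea` | 0.25 | BH FDR within each gene-set family |
| `min_set_size` | 8 | minimum members of a validated miRNA target set |
| `min_predictors` | 2 | minimum prediction-algorithm support per predicted edge |
| `fc_threshold` | 2 | linear fold change for the reporting filter (`2^δ ≥ 2` or `≤ 0.5`) |
| `n_permutations`, `sva_alpha` | 100, 0.10 | surrogate-variable permutation test |

The two-predictor filter balances false-positive against false-negative
predictions: one-predictor support admits mostly noise, three-predictor
support discards most true targets. Validated edges bypass the filter.

## The synthetic study generator

Every stage is testable without downloads through a generator that
emulates the structure of a matched two-condition microarray study with a
hidden binary subtype factor. Baseline log2 levels are uniform on [4, 12]
per feature with i.i.d. Gaussian noise; a chosen set of features is
shifted by ±`effect` in tumor; a fraction of gene features additionally
carries a subtype effect whose sample assignment can be aligned with the
condition to a chosen degree. The reference conditions used throughout the
validation are 2000 genes and 40 miRNAs over 20 samples per condition,
100 DE genes and 10 DE miRNAs with |log2 effect| 2 and noise sd 0.25 —
effect-to-noise characteristics in the range of strongly deregulated
transcripts on RMA-summarized arrays.

The prior generator plants two loops of every FFL subtype (one designated
consistent, one inconsistent) plus two Type III loops among the DE
features, with edge signs drawn from each subtype's sign table and node
directions chosen to honour the designated consistency state; planted
miRNA-target edges cycle through the three evidence states. Decoy loop
skeletons with identical wiring are added among null features, along with
under-supported predictions (single-predictor) that the input filter must
drop. The planted pathway's gene set is seeded with DE members so the
enrichment stage flags it.

For the confounding experiment the package uses a deliberately harder
regime — |log2 effect| 1.0, noise sd 0.5, subtype effect 2.0 on 40% of
features, subtype 70% aligned with condition, 10 samples per arm — chosen
as the setting where unmodeled subtype structure plausibly masks true
signal; there, recovery with surrogate-variable adjustment consistently
exceeds recovery without it.

What the generator does *not* emulate: probe-level effects, correlated
noise between co-regulated transcripts, mRNA–miRNA cross-platform
dependence, or count-based noise models. Passing the planted-recovery
suite therefore demonstrates the pipeline's relational and statistical
correctness under its own model, not performance on real arrays, where
effect sizes are smaller and priors far noisier.

## Validation problem sizes

The test suite and the acceptance script work at desk scale: three to five
replicate studies at the reference conditions for end-to-end recovery,
10 replicate studies of 1500 genes for the confounding experiment, 10^5
uniform p-value triples for score calibration, 1000 random vectors for
the BH oracle, 5000 features for hyperparameter recovery, and 200 null
draws for the surrogate-variable calibration band. These sizes make every
distributional claim measurable with binomial/KS error bounds while each
run stays in seconds.

## Known limitations

* The Fisher score ignores between-node dependence and is a ranking
  device only.
* Consistency for incoherent loops rests on the pairwise interpretation
  described above.
* The attribution summary counts only targets that are themselves DE by
  the per-transcript test (its denominator is the DE mRNA count); both
  choices are interpretations of "transcriptome deregulation" and are
  isolated in `mirna_attribution()`.
* One row per gene/miRNA is assumed; probe-to-gene collapsing is the
  caller's responsibility.
* Missing values are rejected, not imputed.
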