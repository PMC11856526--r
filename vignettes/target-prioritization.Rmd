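---
title: "Prioritising cell-surface therapeutic targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising cell-surface therapeutic targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfrank)
```

## The problem

An antigen suitable for cell-directed immunotherapy must satisfy two
competing demands: high, consistent expression on tumour cells, and
near-absence everywhere the therapy could do harm. Neurological and
pulmonary on-target, off-tumor toxicities make brain and lung expression
disqualifying on their own; a protein shed into plasma will absorb the
therapeutic before it reaches the tumour. `surfrank` encodes this
reasoning as an explicit, auditable computational screen over public
annotation resources, followed by a quantitative ranking across
independent expression cohorts and a single-cell co-expression analysis
of the winning candidate. This vignette records the model, the tunable
parameters, and the design decisions taken where the procedure was
genuinely open.

## The shortlisting chain

`run_shortlist()` applies six per-gene predicates in a fixed order and
records, for every excluded gene, the first stage that rejected it.

| stage | field | rule (defaults) |
|---|---|---|
| brain | RNA brain regional distribution | only `not_detected` passes; `unknown` fails |
| lung | consensus lung NX | fails if NX > 1.5 (strictly) |
| tissue distribution | RNA tissue distribution | `detected_in_all` / `detected_in_many` fail |
| tumour expression | cancer-specific FPKM | passes if FPKM > 50 (strictly) |
| surface localisation | ranked subcellular annotation | plasma membrane must be the *unique* top-confidence site |
| blood | mass-spectrometry plasma detection | any detection fails |

Numerical conventions worth making explicit:

* **Strict inequalities.** "Above 1.5" is read strictly, so a gene at
  exactly NX 1.5 passes, and symmetrically FPKM exactly 50 fails the
  tumour-expression stage. Whether boundary values occur in real exports
  is unknowable from the published counts; the strict reading follows the
  wording of the thresholds.
* **Missing values.** A gene with no lung NX entry passes with a warning
  (consensus tables always carry lung, so absence indicates a partial or
  synthetic table, and we decline to exclude on absent evidence). A gene
  with no tumour FPKM entry is treated as 0 and fails — that stage
  demands positive evidence of high expression.
* **Top-site ties.** A plasma-membrane/extracellular confidence tie fails
  (the protein is plausibly in transit for secretion). We extend the same
  logic to *any* tie at the top confidence: "top site" is read as
  requiring uniqueness, since a membrane annotation that shares its
  confidence with, say, cytosol does not establish the membrane as the
  primary location.
* **Unparseable categories** normalise to `unknown`, which the brain
  stage excludes — consistent with treating unknown brain status as
  disqualifying.

Because each predicate is a pure function of one gene's annotation, the
final survivor set is the intersection of the per-stage pass sets and is
invariant to stage order; only the audit narrative (intermediate counts,
first-failure attribution) depends on the order. The test suite checks
this invariance on random fixtures. Applied to the real Human Protein
Atlas v20.1 liver-cancer longlist (not shipped here), the chain is
documented to reduce 12,948 genes to 8 through the intermediate counts
1,246 → 731 → 585 → 99 → 10; packaged tests use synthetic tables with
planted outcomes instead.

## The rank-aggregation statistic

Within each cohort, candidates are ordered by median expression in case
samples only (the screen asks what is abundant in tumours; control
samples inform other analyses). The gene ranked $k$-th from the bottom
receives a rank score $RS = k \cdot s$ with step $s = 0.1$, and scores
are normalised per cohort, $NS = RS / \max(RS)$, so every cohort's top
gene scores exactly 1 regardless of how many candidates it carries. With
$m$ transcript cohorts and $n$ protein cohorts,

$$\bar{x}_{TP} \;=\; \frac{m\,\bar{x}_T + n\,\bar{x}_P}{m+n},$$

where $\bar{x}_T$ and $\bar{x}_P$ are the per-gene means of transcript
and protein NS. With the study shape of three transcript cohorts and one
protein cohort the weights are exactly 3/4 and 1/4, and $\bar{x}_P$
equals the single protein NS.

Decisions taken here:

* **Ties** (the source procedure is silent): tied medians share the mean
  of their tied ranks' scores. This conserves the total score, makes the
  result independent of input order, and reduces to the untied scheme
  otherwise. The tests verify the tied value equals the average over all
  strict orderings of the tied genes.
* **Beyond eight genes**: $RS = k \cdot s$ with $NS = RS/\max(RS)$
  reduces to $NS = k / g$ for $g$ candidates, reproducing the published
  arithmetic exactly at $g = 8$ while extending naturally.
* **Rounding**: reported values are rounded half-away-from-zero at three
  decimals (`round_half_away()`), the convention under which 0.5625
  prints as 0.563; ordering always uses unrounded values. One published
  transcript mean (0.580 for a gene whose three NS values average to
  0.583) disagrees with its own inputs; the package computes 0.583, and
  the gene's combined score is unaffected because the unrounded mean
  feeds the weighting.
* **Missing genes**: a candidate absent from a cohort's platform is
  excluded from that cohort with a warning, and — because $\bar{x}_{TP}$
  is only comparable across genes measured everywhere — dropped from
  aggregation if missing anywhere.

The statistic is invariant to rescaling any cohort's expression values
(only ranks enter) and monotone: raising one gene's median in one cohort
can never lower any of its scores. Both properties are property-tested,
and the whole chain is checked against an independent brute-force
implementation (sort-based medians, comparison-counting ranks, explicit
arithmetic) to 1e-12 on 200 random instances.

## Single-cell correlation modules

`correlate_target()` composes four steps.

**QC** (`qc_filter()`) is single-pass in a fixed order: features present
in fewer than 200 cells are dropped; then cells with fewer than 500
expressed features or zero total count; then cells whose mitochondrial
percentage exceeds the 99th percentile, computed over all remaining cells
pooled (not per sample). Single-pass semantics means a surviving feature
is not guaranteed to remain above the prevalence threshold after cells
are removed — each rule held at the moment it ran, which is what the
tests assert, and which matches common single-cell toolkit behaviour.
The percentile is interpreted with strict exceedance, so with one extreme
cell among many that cell alone falls above the cutoff.

**Log-normalization** is the standard library-size transform
$\log\!\left(1 + c_{ij} \cdot S / \sum_j c_{ij}\right)$ with scale
$S = 10{,}000$; totals are positive after QC, zeros stay zero, sparsity
is preserved.

**Per-group correlations** restrict to cells of one group whose *raw*
target count is positive — cells not expressing the target are
uninformative about co-expression with it — and correlate every other
gene's normalized vector with the target's. The exclusion is applied per
group independently. Correlations are computed on normalized values: the
procedure normalises before all downstream analysis, and raw-count
correlations would be dominated by library size. Genes with zero
variance among the eligible cells have no defined correlation and are
omitted rather than reported as 0.

**Module resolution** applies the cutoff r ≥ 0.6 in each group and keeps
the two gene sets disjoint: a gene above the cutoff in both groups joins
the group with the strictly higher correlation (this reproduces the
published handling of a gene at 0.630 in controls vs 0.602 in cases,
which entered the control set only); an exact tie above the cutoff drops
the gene from both with a warning. The `≥` comparison follows the
procedure's stated cutoff; the figure-caption phrasing "> 0.6" is treated
as loose, and both comparison modes are exposed (`comparison = ">"`).

## Normality-gated comparisons

`compare_two_groups()` runs Shapiro-Wilk on each group; both normal at
α leads to the unpaired (pooled-variance) t test, anything else to
Mann-Whitney — including the case where exactly one group is non-normal,
for which the source is silent and the conservative nonparametric route
is taken. `compare_many_groups()` does the same with one-way ANOVA plus
Holm-Šidák-adjusted pooled-variance pairwise t tests, or Kruskal-Wallis
plus Dunn's rank-based pairwise z tests (tie-corrected, Bonferroni-style
multiplication). The gate uses the same α as the main test (default
0.05, two-tailed), another silent point decided here. Holm-Šidák and
Dunn's test are implemented in the package — both are short closed-form
procedures — while Shapiro-Wilk, t, Wilcoxon, ANOVA and Kruskal-Wallis
come from `stats`. Mann-Whitney uses the normal approximation with
continuity correction so tied data never errors. Under a fully normal
null the gated two-group procedure holds its nominal type-I error; the
suite verifies a rejection rate of 0.05 ± 0.02 over 1,000 simulated
null datasets.

## The synthetic-data generators

The generators exist so that every stage has a deterministic,
download-free test surface with known truth; they are first-class,
tested code.

* `simulate_annotations()` draws each gene's fields so every predicate
  evaluates exactly to a planted label (e.g. a fail-lung gene draws NX
  uniformly above the threshold, a fail-surface gene draws one of the
  three failure modes: extracellular tie, different top site, or no
  annotation). Default labels are independent per-stage Bernoulli draws
  with pass probability 0.7 — chosen once so a 1,000-gene table retains
  a survivor set large enough to exercise every stage (roughly 12% of
  genes survive all six).
* `simulate_bulk()` draws case samples log-normally with per-gene
  log-locations spaced 0.5 apart along a planted median order and noise
  SD 0.25; at the default cohort sizes (366/35/225/165 cases, emulating
  the study's shapes) the sampling error of a median is an order of
  magnitude smaller than the spacing, so the planted order is preserved
  with overwhelming probability. Controls sit one log-unit lower,
  mirroring tumour-over-normal overexpression at an effect size that
  two-group tests detect comfortably at 35 samples per arm. Log-normal
  noise was chosen because expression values are positive and
  right-skewed, and because the ranking consumes only medians, which the
  location parameters control directly.
* `simulate_single_cell()` uses a negative-binomial observation model
  (default mean 2, size 2 — overdispersion typical of droplet data) on
  1,000 genes. In case cells the target and the 20 module genes share a
  standard-normal per-cell latent factor; the loading is calibrated
  empirically — binary search over pilot simulations that mimic the
  pipeline's own transform (library-size normalization, log1p,
  target-expressing cells only) — so the realised target–module
  correlation approximates the requested `module_rho`. There is no
  convenient closed form for this chain, hence calibration rather than
  derivation. Control cells have no shared factor. A tenth of case cells
  are forced to zero target count to exercise the exclusion rule, and 5%
  of genes carry the `MT-` prefix and mito flag. An optional extra gene
  can be planted to correlate with the target in both groups, to
  exercise the overlap-resolution rule.

What the generators deliberately do **not** emulate: pathway structure,
cell-type composition, batch effects, doublets, ambient RNA, or any real
liver biology. Passing the recovery tests therefore demonstrates that
the pipeline's statistics behave as specified on data with the planted
structure — not that the biological conclusions of any particular screen
are correct, nor that real data meets the generators' assumptions.

## Problem sizes and runtime

The shipped tests run the shortlist at 1,000 genes, ranking-oracle
equivalence on 200 random instances of up to 6 genes × 4 cohorts, module
recovery at 2,000 case + 1,000 control cells × 1,000 genes across three
fixed seeds (sensitivity ≥ 0.95 at ≤ 1% false positives), and test
calibration over 1,000 simulated null datasets — sizes chosen to match
the study conditions where the statistics are scale-sensitive (cells,
candidates per cohort) and to keep the full suite in the tens of
seconds elsewhere. All fixtures are generated in code at test time;
nothing binary ships with the package.

## Known limitations

* The shortlist consumes pre-computed annotation categories; it does not
  re-derive consensus NX from raw HPA/GTEx/FANTOM5 data, and its output
  is only as good as the annotation vintage supplied.
* The rank statistic ignores effect sizes: a gene narrowly below another
  in every cohort ranks strictly lower regardless of margins. This is
  faithful to the screen it implements, not a recommendation.
* Correlation modules are computed on per-gene normalized values without
  batch correction; whether integrated values would be preferable is
  left to the user, and per-sample batch structure is not modelled.
* GO enrichment itself, clustering/UMAP, doublet detection and survival
  analysis are out of scope; module gene sets are exported as TSV for
  external tools.
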