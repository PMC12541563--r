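---
title: "Meta-program discovery across single-cell cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-program discovery across single-cell cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Tumors — and tumor-derived model systems such as patient-derived organoids
(PDOs) — are not transcriptionally homogeneous. Within one sample, subsets of
cells occupy distinct expression states: cycling cells, stressed cells with
elevated translation, stem-like cells, and states private to one patient.
When several samples are profiled by single-cell or single-nucleus RNA-seq,
the recurring question is which of these intra-sample expression programs
are *shared across the cohort*. A program that recurs in most patients (a
**meta-program**, MP) is a candidate biological state; a program seen in one
patient only is either patient-specific biology or noise.

`metaprogramr` implements the standard discovery pipeline for this question
and pairs it with a synthetic-cohort generator so that every stage can be
validated against planted ground truth.

# The pipeline

For each sample with non-negative normalized expression matrix
$X \in \mathbb{R}^{g \times n}_{\ge 0}$ (genes by cells):

1. **Gene filtering** — genes detected in fewer than `min_cells` (default 3)
   cells are removed.
2. **Normalization** — counts are scaled per cell to counts-per-10k and
   log-transformed: $x_{gc} = \log\!\big(1 + 10^4\,\mathrm{count}_{gc} /
   L_c\big)$ with $L_c$ the cell's total count. This keeps the matrix
   non-negative, as NMF requires. NMF runs on all filtered genes; no
   highly-variable-gene selection is applied by default, because adding one
   would be a second, unforced modeling choice. Library sizes are computed
   within each sample, matching the per-sample factorization.
3. **NMF** — $X \approx WH$ with $W \in \mathbb{R}^{g \times k}_{\ge 0}$,
   $H \in \mathbb{R}^{k \times n}_{\ge 0}$, $k = 15$ per sample by default,
   fitted by Lee–Seung multiplicative updates minimizing
   $\lVert X - WH \rVert_F$.
4. **Programs** — each factor contributes one program: its `n_top` = 50
   highest-loading genes.
5. **Per-cell scoring** — every program is scored on every cell of every
   sample with a binned-control module score (details below), giving a
   pooled cells × programs score matrix. With 9 samples and $k=15$ this is
   the cohort's 135-program score matrix.
6. **Correlation and clustering** — programs are correlated (Pearson, over
   all pooled cells) and clustered by agglomerative clustering on
   $d = 1 - r$; the dendrogram is cut at height 1.3.
7. **Meta-programs** — qualifying clusters become MPs; each MP is summarized
   by the 50 genes occurring most frequently across its member programs'
   top-50 lists, and every cell is assigned to its best-scoring MP.

## The module score

A cell's score for a gene set $S$ is

$$\mathrm{score}_c = \frac{1}{|S|}\sum_{g \in S} x_{gc}
  \;-\; \frac{1}{|C|}\sum_{g \in C} x_{gc},$$

where the control multiset $C$ contains, for every member gene, up to
`n_ctrl` = 100 genes sampled without replacement from the member's
expression bin (`n_bins` = 24 equal-frequency bins on mean expression,
member excluded). Matching controls by expression bin removes the dominant
mean-expression axis, so a random gene set scores near zero and the score is
invariant to adding a constant to all genes of a cell. Bins are
equal-frequency rather than equal-width because mean expression is heavily
right-skewed. Control draws are seeded *per member gene* (scoring seed plus
the gene's row index), which makes scores independent of the order in which
programs are scored and lets a gene shared by two programs reuse its
controls.

Scoring is per sample: each sample's cells are scored against that sample's
own bin structure, and a program from sample A is scored on sample B through
the genes present in B's filtered universe. Scoring on a merged cohort
matrix would entangle between-sample level differences with program
activity, so the per-sample route is the default.

## From 135 programs to a handful of MPs

The dendrogram cut at height 1.3 (on $d = 1 - r \in [0, 2]$; heights above
1 require anti-correlated blocks) partitions all programs, but not every
cluster is a meta-program. Three filters decide which clusters qualify:

* `min_programs` = 3 member programs — a pattern supported by a single
  factor is not recurrent;
* `min_samples` = 2 distinct samples — an MP is by definition cross-sample;
* `min_coherence` = 0.5 mean pairwise member correlation — an MP is a block
  of *mutually correlated* programs. Requiring coherence separates the
  tight red blocks one draws boxes around in a program-correlation heatmap
  from loose aggregates glued together near zero correlation.
* `min_support` = 0.5 consensus support — the mean, over the candidate's
  would-be consensus genes, of the fraction of member programs containing
  the gene. Summarizing an MP by its most frequently occurring genes
  presupposes that those genes recur; in a genuine MP the top consensus
  genes appear in most members (support near 1), whereas clusters of
  residual NMF factors (factors that model leftover baseline expression
  after the strong states are captured) have diverse top-gene lists and
  support well below one half. In calibration runs on synthetic cohorts
  this statistic separates the two populations by a wide margin
  (roughly 0.6–1.0 versus 0.15–0.35) and is the decisive filter.

Linkage is configurable; the package default is **Ward** (`"ward.D2"`).
Two properties motivate the choice. First, the cut height must be
reachable: under average linkage the merge heights of a $1 - r$ tree are
dragged toward 1 by the mass of near-uncorrelated residual programs, the
whole tree tops out near 1.2, and any cut above that returns a single
cluster regardless of block structure. Second, tight blocks should not be
absorbed en route: under complete linkage a program block joins the
residual mass whenever no strongly anti-correlated pair spans the gap,
which happens sporadically from seed to seed. Ward's merge cost grows with
the size and tightness of the clusters being joined, so well-formed blocks
stay separate and the flat cut is stable. (`"average"` and `"complete"`
remain available, and the linkage, cut height, and every other parameter
are recorded in the run's provenance block.)

Consensus tie-breaks: genes with equal occurrence counts are ordered by
better (lower) mean within-program rank, then lexicographically, so
consensus lists are deterministic.

Cell assignment averages an MP's member-program score columns and takes the
arg-max, ties toward the lower-numbered MP.

# The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate a multi-sample
single-nucleus cohort with planted structure. For cell $c$ and gene $g$,

$$\mathrm{count}_{gc} \sim \mathrm{Poisson}(L_c\, p_{gc}), \qquad
  p_{gc} \propto b_g\Big(1 + \sum\nolimits_p a_{cp} w_{gp}\Big),$$

with log-normal baselines $b_g$ and library sizes $L_c$, program weights
$w_{gp}$ equal to `program_weight` on a program's member genes, and
activities $a_{cp}$ that are a Bernoulli(`active_fraction`) gate times a
Gamma(`activity_shape`, `activity_scale`) magnitude. $p_{gc}$ is
renormalized within each cell so that the library size stays interpretable
no matter how much program load a cell carries. Program gene sets are
disjoint by construction, making Jaccard-based recovery scoring
unambiguous. All randomness descends from one integer seed through a single
stream consumed in a fixed, documented order (baselines, memberships, then
per sample: library sizes, gates, activities, counts), so a seed pins the
cohort bit-for-bit.

## Default study conditions

The defaults describe a cohort of 9 tumor-organoid samples — 4 shared
programs (mirroring cohort-recurrent states such as cell cycle,
stress/translation, stem-like, plus one unannotated) and 1 private program
per sample — at desk scale: 500 cells and 2,000 genes per sample, 50 genes
per program. Library sizes are log-normal around 5,000 counts per cell
(`libsize_log_mean = log(5000)`, sd 0.25), baseline rates log-normal with
sd 0.6.

Program effect sizes are calibration choices, not estimates from any
dataset: `program_weight = 8`, `active_fraction = 0.25`,
`activity_shape = 3`, `activity_scale = 1`. They were chosen so that the
generated cohorts reproduce the qualitative structure the pipeline is built
for — tight within-state correlation blocks, visibly *negative* correlation
between different states' programs (driven by cells committing their
library to one state at the expense of others), and a correlation range
reaching roughly $-0.6$ to $1$ — at which point a dendrogram cut above 1
separates blocks. A sparse gate (rather than dense gamma activity in every
cell) is what creates distinguishable active/inactive populations; a higher
active fraction makes multi-state cells common and measurably weakens the
anti-correlation between states.

## What the generator does not emulate

No doublets or ambient RNA, no batch effects, no overlapping program gene
sets, no dropout beyond Poisson sampling, no gene–gene correlation within
the baseline, and no chromatin modality. Passing recovery tests on this
generator therefore demonstrates that the pipeline's stages compose
correctly and recover planted structure under Poisson noise — not that any
particular biological dataset contains four states.

# Numerical choices

* **NMF initialization** is seeded uniform scaled by $\sqrt{\bar X / k}$,
  which puts the initial product on the scale of the data. One restart by
  default; `restarts = r` takes the best of $r$ seeded runs.
* **Stopping**: relative objective decrease below `tol` = 1e-4 over one
  iteration, or `max_iter` = 500. At the default problem size fits converge
  in roughly 80–150 iterations. The objective is computed by the trace
  identity $\lVert X-WH\rVert_F^2 = \lVert X\rVert_F^2 - 2\langle W, XH^\top
  \rangle + \langle W^\top W, HH^\top\rangle$, avoiding the full $WH$
  product.
* **Denominator floor** 1e-10 in the multiplicative updates prevents
  division by zero; factors stay finite and non-negative for any valid
  input.
* **Factor ordering** by $\lVert W_j\rVert_2 \lVert H_j\rVert_2$ with W
  columns normalized to unit L2 norm makes "top genes per factor"
  well-defined and comparable across runs and seeds.
* **Ties** in program extraction (equal loadings) and consensus selection
  break deterministically (lexicographic gene id; mean-rank first for
  consensus).
* **Constant score columns** (zero variance) get correlation 0 with
  everything rather than NA, with a logged message.
* **Zero-count cells** are dropped at normalization with a warning;
  a filtering result with zero genes is an error, not an empty matrix.

# Verification strategy and problem sizes

The test suite checks every stage against an independent oracle at small
scale: entrywise recomputation of the normalization formula; SVD for the
rank-1 NMF error (valid because the leading singular pair of a positive
matrix is non-negative); exhaustive-control brute force for the module
score; direct covariance computation for Pearson correlation; brute-force
agglomeration on a two-block matrix for the dendrogram cut; brute-force
frequency/rank sorting for consensus sets; exhaustive enumeration for the
recovery matching. End-to-end tests run the full default cohort (9 samples
× 500 cells × 2,000 genes, about half a minute per run) and check that the
number of programs entering correlation equals samples × rank, that
recovered MP counts and matched Jaccard overlaps against planted truth meet
the recovery bar across generator seeds, and that identical seeds reproduce
artifacts byte-for-byte. These sizes were chosen so the whole suite runs on
a laptop in minutes while leaving every stage's behavior observable.

# Known limitations

* Multiplicative-update NMF converges slowly near the optimum; the default
  tolerance targets program extraction (top-gene ranking stabilizes long
  before the objective's last digits), not high-precision factorization.
* The coherence filter assumes residual factors are less mutually
  correlated than true meta-programs. Data whose residual structure is
  itself strongly modular (for example uncorrected batch effects spanning
  samples) could pass the filter; such structure should be removed upstream.
* Cross-sample scoring silently restricts a program to the genes present in
  the target sample's universe (with the shrinkage logged). Programs built
  from genes absent in most samples will score weakly everywhere.
* The pipeline fixes the NMF rank per run. Robustness across ranks is out
  of scope and would need to be layered on top.
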