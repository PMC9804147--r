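---
title: "Cross-model transcriptomic concordance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-model transcriptomic concordance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txconcord)
```

# The problem

Disease models disagree. A mutant human cortical organoid line and a mutant
mouse cortex each produce a list of differentially expressed genes (DEGs)
against their own controls, measured with different platforms, depths and
power. `txconcord` quantifies whether the two dysregulation signatures
agree — in membership, in direction, and in effect size — without ever
comparing raw expression across models. Everything operates on
gene-level DE summary tables (log2 fold change in mutant-vs-control
orientation, raw p, BH-adjusted p) plus each model's *tested-gene
universe*, joined through a 1:1 ortholog map.

# Overlap enrichment with a defined universe

The central statistic is the enrichment of the overlap of two
direction-specific DEG sets $A$ and $B$ against the joint universe $U$ —
the ortholog pairs whose members passed the DE testing filter in *both*
models. Over that universe,

$$\mathrm{fold} \;=\; \frac{n_{11}\,U}{|A|\,|B|},
\qquad n_{11} = |A \cap B|,$$

the ratio of observed to expected overlap under independence. The same
quantity is the geometric mean of the two conditional enrichments
$\frac{n_{11}/|A|}{|B|/U}$ and $\frac{n_{11}/|B|}{|A|/U}$ (an algebraic
identity the test suite asserts numerically), hence the name geometric
mean enrichment (GME). Significance is the one-sided Fisher exact test on
$[[n_{11}, n_{10}], [n_{01}, n_{00}]]$, computed as the hypergeometric
upper tail $P(X \ge n_{11})$; the test suite checks this against an
exhaustive `choose()`-based tail sum for every table with $U \le 30$.

Two choices deserve comment:

* **The complement cell.** $n_{00} = U - n_{11} - n_{10} - n_{01}$, the
  standard contingency construction in which the four cells partition the
  universe. A literal variant with the fourth cell equal to *all* genes
  not in $B$ (which double-counts and whose rows no longer sum to $U$) is
  available as `quadrant_counts(..., literal = TRUE)` for comparison only.
* **Fold versus odds ratio.** The reported enrichment is the
  observed/expected fold above, not the Fisher conditional odds ratio; the
  odds ratio is carried alongside in every `gme_result` for transparency.
  The two agree in direction but not magnitude, and conflating them is a
  common source of irreproducible "fold enrichment" numbers.

Degenerate tables are defined, not special-cased downstream: if either
marginal is empty the fold is `NaN` and $p = 1$; zero overlap with
non-empty margins gives fold 0 and $p = 1$ (the upper tail at the minimum).

All four direction pairs are computed (`gme_all_quadrants()`). Concordant
models enrich up–up and down–down; transcriptomic reversal — the pattern
expected when, say, a perinatal time point has compensated an embryonic
signature — enriches up–down and down–up instead.

# DEG calling and the low-power fallback

Thresholds are strict: `log2fc > 0.25` and `FDR < 0.05` for upregulation,
the mirrored `log2fc < -0.25` for downregulation (the mirroring is an
explicit symmetry assumption; the convention states one positive
threshold). A gene sitting exactly at a threshold is excluded, and the
boundary behaviour is pinned by tests at `log2fc = 0.25`, at 9 versus 10
FDR DEGs, at exactly 10 cells per sample, and at exactly 200 genes per
cell.

Comparisons with very low power produce near-empty FDR DEG sets that make
every overlap vacuous. The fallback rule re-calls DEGs with raw
`p < 0.05` whenever the table yields fewer than `fallback_min_degs = 10`
FDR-significant DEGs. The trigger count itself applies the
fold-change magnitude filter (`|log2fc| > 0.25`): the convention's wording
is ambiguous on this point, and counting with the filter keeps the
trigger consistent with the downstream DEG definition. The behaviour is
configurable through `fallback_min_degs` and `fallback_p`.

Replicated calling across two isogenic lines (`shared_degs()`) intersects
the per-line direction-specific sets; a gene with opposite signs in the
two lines lands in neither output.

# Regression and sign consistency

`lfc_regression()` fits ordinary least squares of model-B log2FC on
model-A log2FC over A's pooled DEGs, optionally filtered by a raw-p or FDR
threshold on B; `r2` is the squared Pearson correlation of the plotted
points (asserted to 1e-10 against `cor()^2`). No errors-in-variables
correction is applied — both axes are noisy estimates, so the slope is
attenuated and should be read qualitatively. Fits on fewer than 3 points
or with a degenerate axis are flagged invalid rather than extrapolated.
`threshold_sweep()` runs an ordered loose-to-strict list of thresholds;
`n_genes` is non-increasing along the sweep by construction.

`sign_consistency()` asks a weaker question for genes too underpowered to
reach significance: does the raw sign of the target-model fold change
agree with a hypothesised direction? A zero fold change counts as
disagreement. The attached exact two-sided binomial test at $p = 1/2$ is
an extension beyond the descriptive count — the convention reports the
count alone — and is labelled as such.

# Single-cell preparation

QC follows the standard marker-gene workflow: genes detected (count > 0)
in at least 3 cells are kept; then cells with 200–7500 expressed genes and
at most 10% mitochondrial reads (gene-id prefix `MT-`, configurable) are
kept. The order is gene-then-cell in a single pass, *not* iterated to a
fixpoint; the order matters (an unsupported mitochondrial gene is removed
before mito fractions are evaluated) and is part of the tested contract.
Normalization scales each cell to `norm_scale = 10000` transcripts and
applies `log1p`; the identity
$\sum_g \mathrm{expm1}(x_{gc}) = 10000$ per cell is asserted to 1e-6
relative in the tests.

# The rank-based DE engine

The internal engine (`run_de()`) exists so the burden procedure and the
synthetic pipeline have a valid, self-contained within-dataset test; it is
*not* a reimplementation of hurdle-model engines with latent covariates
(mitochondrial fraction, read depth, batch), and externally produced DE
tables can be substituted anywhere a `de_table` is accepted.

* Effect size: $\log_2\!\frac{m_A + 1}{m_B + 1}$ with $m$ the group mean
  of depth-corrected expression (`expm1` of the normalized layer). The
  pseudocounts bound the statistic for genes absent from a group.
* Test: two-sided rank-sum. With both groups of size at most 8 the p-value
  is exact by enumeration of all $\binom{n_A+n_B}{n_A}$ labelings using
  average ranks, so ties are handled exactly; larger groups use the normal
  approximation with tie correction and a 0.5 continuity correction.
  All-tied input returns $p = 1$. The exact branch is validated against
  `wilcox.test`'s exact distribution on tie-free data and the approximate
  branch against its corrected normal formula.
* Gene filters: only genes expressed in at least `min_pct = 5%` of one
  group's cells form the universe, and only universe genes with
  $|\mathrm{log2fc}| > 0.25$ are tested, mirroring the fold-change
  threshold semantics of marker-gene engines. Untested genes are reported
  untested, never assigned p-values.
* Multiple testing: BH is applied to the tested p-values **with the
  universe size as the number of tests**. This is a deliberate design
  choice, not an oversight: the fold-change pre-filter selects genes whose
  p-values are conditionally small (the same sampling fluctuation that
  inflates an observed fold change also shifts the rank statistic), so a
  step-up adjustment across only the few dozen surviving genes does not
  control the false discovery rate on null data — in simulation it passes
  on the order of 0.1 false DEGs per null comparison. Charging the
  adjustment for the full universe restores calibration (the null
  fixture yields zero FDR DEGs in at least 95 of 100 seeds in the
  acceptance suite), and is the same reasoning by which production
  marker-gene tools correct over all genes in the dataset.

# Burden and composition

`burden()` ranks clusters by transcriptomic disruption while controlling
for cell-number bias. Eligibility is strict — more than
`burden_min_cells = 10` cells in *every* sample, assessed over all samples
in the matrix — and the downsampling depth $k$ is the minimum eligible
(cluster, sample) count unless fixed explicitly. Each of
`burden_iters = 10` iterations downsamples every (cluster, sample) to $k$
cells without replacement, pools samples within line, tests mutant against
control per cluster, and counts DEGs in both directions (directionality is
not split, matching the single-count-per-cluster convention); iteration
counts are averaged. One master seed spawns independent per-iteration
streams, so iteration $j$ is reproducible without replaying $1..j-1$ and a
fixed seed gives a bitwise-identical result.

The averaged counts retain some selection-driven inflation: genes that
clear the fold-change pre-filter by chance ride the planted genes'
adjustment bar, which is precisely the "selection bias" the iteration
averaging is meant to damp. Burden means are therefore comparative
(cluster rankings), not absolute DEG inventories.

`composition()` reports, per cluster, replicate-level per-sample
proportions (mean ± SEM; each sample's proportions sum to 1 exactly) and a
two-sided Fisher exact test on the pooled in/out-of-cluster counts of the
two lines. Pooled counts treat cells as independent, which overstates
certainty relative to the replicate-level spread; both views are emitted
so the tension stays visible, and neither is claimed to be the "right"
p-value.

# Synthetic data: what it emulates and what it does not

`simulate_bulk_pair()` draws, per gene, a latent log2 effect that is
shared (concordant), sign-flipped (discordant) or absent across the two
models, observes it with independent Gaussian noise of known standard
error, and converts to p-values through the known-SE normal model. This
gives closed-form truth: with magnitude $|\theta| \sim N(\mu, \sigma)$ and
fractions $f_c, f_d$, the population squared correlation of the two
observed log2FC vectors is

$$r^2 = \frac{\big((f_c - f_d)\,M\big)^2}
{\big((f_c+f_d)M + se_a^2\big)\big((f_c+f_d)M + se_b^2\big)},
\quad M = \mu^2 + \sigma^2,$$

implemented as `bulk_population_r2()` and recovered by simulation within
±0.05 at $G = 5000$. Defaults ($G = 5000$, $f_c = 0.10$, $f_d = 0.05$,
$\mu = 1.5$, $\sigma = 0.4$, $se = 0.3$, 5% ortholog dropout, 2% universe
dropout) describe a well-powered bulk comparison with a strong planted
signature. Human-style upper-case and mouse-style title-case ids are
emitted so the case-heuristic ortholog path is exercised. What this
generator does *not* emulate: count-level noise, mean–variance coupling,
correlated genes, or refitting a DE model to replicates — p-values are
exactly normal by construction, which is the point (calibration tests need
analytic truth).

`simulate_sc()` draws negative binomial counts (single shared dispersion
0.5; variance $= \mu + 0.5\mu^2$) around cell size factor × cluster
profile, with cluster identity from upweighted marker genes, per-line
composition multipliers, planted per-(cluster, line) DEGs multiplying the
mean by $2^{\pm\delta}$, and `MT-`-prefixed genes at a 5% target fraction
so QC is exercised. Defaults emulate the replicated organoid design:
a control line plus two mutant lines × 5 biological replicates, five
clusters named for the cortical populations they stand in for, 50–90
cells per cluster per sample, on a compact 1000-gene panel (a full
transcriptome is unnecessary for the procedures under test; panel size is
a realism/runtime trade-off chosen once). Not emulated: batch effects,
integration artifacts, doublets, per-gene dispersion, or real cluster
expression signatures. Passing tests therefore demonstrate procedural
correctness and statistical calibration on a faithful *abstraction* of
such data, not performance on any real dataset.

# Numerical and degenerate-input conventions

* All DEG thresholds are strict inequalities; boundary genes are excluded.
* Gene identifiers are opaque, case-sensitive tokens everywhere except
  `default_symbol_map()`, which is explicitly a case heuristic restricted
  to 1:1 matches (colliding ids are dropped, with a message).
* Ortholog maps are restricted to 1:1 pairs; many-to-many pairs are
  dropped with a reported count to avoid double-counting in the 2×2
  tables.
* `rank_test` on all-tied data, GME on empty margins, sign consistency on
  an empty gene set, and regression on fewer than 3 points all return
  defined, documented values instead of erroring mid-pipeline.
* Downsampling with $k$ equal to the cluster size returns the full
  cluster without consuming randomness.

# Problem sizes used by the test suite

The suite validates invariants at the following scales, chosen to keep the
default run within a few minutes of CPU time while leaving the statistical
assertions well-powered: exhaustive GME oracle up to $U = 30$; 2000 null
bulk pairs at $G = 2000$ for calibration; 50 seeds at $G = 5000$ for
planted-concordance recovery; 20 seeds for the threshold-sweep and burden
properties (burden fixtures: 300-gene panel, 3 clusters, 2 lines × 5
samples, 30–45 cells per cluster per sample, 10 iterations); 100 seeds of
a 200-gene, 60-cells-per-group null fixture for DE-engine calibration;
exhaustive binomial enumeration up to $n = 20$; and 1000 random vectors
for the BH oracle.

# Known limitations

* The internal DE engine ignores covariates; analyses of real single-cell
  data should feed externally produced DE tables into the concordance
  layer instead.
* The case-heuristic symbol map is a stand-in; a curated ortholog table
  (two-column TSV via `read_ortholog_map()`) is the principled path.
* Burden compares line against control with samples pooled per cluster;
  paired per-sample designs are out of scope.
* Composition analysis uses raw proportions; compositional-data
  transforms (log-ratio models) are out of scope.
* Whether printed fold enrichments in the comparative literature are
  observed/expected folds or Fisher odds ratios is often unstated; this
  package reports both, clearly named.
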