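---
title: "Network-based discovery of tumor-infiltrating Treg markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based discovery of tumor-infiltrating Treg markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregmark)
```

## The analysis in one paragraph

Tumor-infiltrating regulatory T cells (TI-Tregs) suppress anti-tumor
immunity, and surface proteins expressed specifically on TI-Tregs — not on
circulating or splenic Tregs, and not on conventional CD4+ T cells — are
candidate targets for antibody-based therapy. `tregmark` implements a
marker-discovery screen around that idea: differential expression of a
target population against every other population with two complementary
engines, intersection of all resulting DEG sets restricted to a
cell-surface catalog, cross-species confirmation through reciprocal-best-hit
orthologs, a Treg-specific coexpression network whose *context-associated
centrality* (CAC) ranks genes by how strongly their network neighborhoods
are enriched for a context signature, and survival/response stratification
of candidate markers normalized by FOXP3 as a proxy for Treg abundance.
Because the original inputs are external repositories, the package ships
seeded generators that emulate each data regime with planted ground truth,
so every stage is testable end to end.

## The screen

For a target population $T$ and comparison populations $R_1,\dots,R_k$, the
screen computes $2k$ DEG sets — one per comparison per engine — and takes

$$\mathrm{candidates} \;=\; \Big(\bigcap_{j,e} \mathrm{DEG}_e(T, R_j)\Big)
\;\cap\; \mathrm{Surface}.$$

With the six bulk CD4+ T-cell populations (TI-Treg and TI-Tconv from
tumor-bearing mice, splenic Tregs and Tconvs from tumor-bearing and normal
mice) this is a 10-set intersection. A gene qualifies as a DEG when its
fold change exceeds 2 with $p < 0.01$ (Welch engine), or when its
characteristic score exceeds the uniform model $1/n$ with a positive sign
(Characteristic Direction engine, below). The two engines fail in
complementary ways — a per-gene test ignores covariance, the multivariate
direction has no per-gene error control — which is why the screen demands
agreement from both.

### Characteristic Direction

`characteristic_direction()` treats differential expression geometrically:
the direction vector is the normal of a regularized linear-discriminant
hyperplane,

$$b \;\propto\; \big(\gamma I + (1-\gamma)\hat\Sigma\big)^{-1}
(\mu_T - \mu_R), \qquad \|b\| = 1,$$

with $\hat\Sigma$ the pooled within-group covariance. A gene's score is
$b_i^2$ (the scores sum to one) and its sign marks the side of the
hyperplane. Numerical choices:

* **Shrinkage** defaults to $\gamma = 0.5$. With genes $\gg$ samples
  $\hat\Sigma$ is singular, so $\gamma > 0$ is required; $\gamma = 0$ is
  rejected with an instructive error.
* **Reduced subspace.** When genes outnumber samples the solve is done
  exactly in the span of the within-group residuals via the Woodbury
  identity; a test verifies it agrees with the dense solve where both
  apply.
* **Orientation.** The sign of $b$ is chosen so that
  $b^\top(\mu_T-\mu_R) > 0$, which makes "positive score = induced in the
  target population" operational; without this convention the hyperplane
  normal is defined only up to sign.

### The single-cell engine

For zero-inflated counts the package uses a two-part test per gene:
Fisher's exact test on the zero/non-zero table, a Wilcoxon rank-sum on the
non-zero values after total-count normalization, combined by Fisher's
method ($\chi^2$, 4 df). When one part is undefined (a group with no
detected cells) the other part's p-value stands alone. This is a
deliberately transparent surrogate for specialized zero-inflated mixture
engines; matching their internals is a non-goal, the screen only consumes
the resulting DEG sets (fold change > 2, $p < 0.01$).

## Signatures and orthologs

DEG-set algebra is explicit and provenance-tracked: the chronic-infection
Treg signature subtracts acute-vs-naive DEGs from chronic-vs-naive DEGs
(genes responding to any infection are not tumor-like), and the core
TI-Treg signature intersects the bulk TI-Treg DEGs with that
chronic-specific set. Ortholog transfer uses reciprocal best hits from a
user-supplied similarity table; tied best scores drop the pair rather than
resolving arbitrarily, keeping the map deterministic and one-to-one.
Overlap significance between two sets in an explicit universe is the
one-sided hypergeometric upper tail; the universe is always an argument,
never guessed.

## The Treg-specific network and CAC

The network stage mirrors standard coexpression practice: genes whose
maximum expression does not exceed that of negative-marker genes (B-cell
and macrophage markers, which should not express in sorted T cells) are
removed; each gene's profile is scaled to unit root mean square; and every
gene pair receives a Pearson correlation whose significance comes from the
$t$ transform $t = r\sqrt{(m-2)/(1-r^2)}$ with an edge kept at $p < 0.01$.
Choices worth flagging:

* RMS normalization is applied per gene (per row). Correlations are
  invariant to it; it is kept because the downstream edge list then refers
  to scale-free profiles, and per-sample scaling would be a different
  (normalization) operation already handled upstream.
* The threshold of the expression filter is the **maximum** over negative
  markers of each marker's maximum (the strictest reading of "no higher
  than a silent gene"); `rule = "mean"` is available.
* Perfect correlations are capped just below $|r| = 1$ so the statistic
  stays finite; constant genes are flagged and contribute no edges.

Network quality is assessed by within-group connectivity: the number of
edges internal to a gene group, compared with groups of the same size drawn
uniformly at random. The phrase "random links for the same group size"
admits two readings (random node groups vs random edge sets); the
node-group reading is implemented because connectivity is a node-group
statistic. The empirical p-value uses an add-one correction,
$(1 + \#\{\text{draws} \ge \text{obs}\})/(1 + N)$, so 100,000 draws bottom
out at $p = 10^{-5}$, and exhaustive enumeration replaces sampling whenever
$\binom{n}{k} \le 10^5$, making small cases exact.

**CAC.** Each network gene is scored by the one-sided hypergeometric
enrichment of its neighbors among context-signature genes, against a
universe of all network nodes minus the focal gene (the focal gene can be
neither its own neighbor nor its own signature witness). P-values are BH
adjusted across genes and $\mathrm{CAC} = -\log_{10}(q)$. Ranking breaks
ties deterministically (ascending $p$, then descending overlap, then gene
id) so top-decile membership is reproducible. The universe could
alternatively include all measured genes; all-nodes was chosen because the
neighbor draw is only defined within the network.

## Outcome evaluation

The marker score is $\log_2\frac{\text{marker}+1}{\text{FOXP3}+1}$ — a
ratio rather than a difference because bulk expression is
multiplicative in Treg content, with pseudocount 1 guarding zeros. Subjects
strictly above the upper quantile cut form the High stratum, strictly below
the lower cut the Low stratum; ties sitting exactly on a cut are excluded
and counted, a rule chosen over arbitrary tie assignment. Kaplan–Meier
curves and the two-sided log-rank test come from the `survival` package
behind the module interface; hand-computed small fixtures in the test suite
pin the expected values. Waterfall deltas are deviations from the cohort
median, and stage comparisons use the Mann–Whitney U test — exact by
enumeration when the combined sample is at most 12 without ties, the
tie-corrected normal approximation otherwise.

## What the generators emulate — and what they do not

All four generators are deterministic given `sim_config(seed = )`.

* **Bulk** (`simulate_bulk`): negative-binomial counts, log-normal gene
  base means (log2 mean 6, sd 1.5), log-normal library sizes (CV 0.2,
  forcing the size-factor path to matter), common dispersion 0.01, three
  replicates per population. Planted markers gain `marker_log2fc` (default
  2, i.e. 4-fold) in the target population only. Module genes share a
  Gaussian latent factor on the log2 scale: the hub carries the factor,
  members load with $\sqrt{r}$, so the latent member–member correlation is
  exactly the configured $r$ and hub–member correlation is $\sqrt{r}$ —
  a closed form the tests check against empirical correlations.
* **Single-cell** (`simulate_singlecell`): the same NB law at lower means
  with logistic detection — an entry survives with probability
  `plogis(intercept + slope * log2(mu + 1))` — so dropout falls with
  expression and the intercept tunes the global zero fraction.
* **Microarray** (`simulate_microarray`): Gaussian log2 intensities over
  naive/acute/chronic conditions, with a chronic-specific and a
  shared (chronic+acute) planted set to exercise the subtraction rule.
* **Cohort** (`simulate_cohort`): a latent per-subject score (standard
  normal plus a stage effect), marker expression = FOXP3-like normalizer
  times $2^{\text{score}}$, exponential event times with hazard
  $0.1 \cdot \mathrm{HR}^{\text{score}}$, and independent uniform censoring
  whose horizon is calibrated by root finding so the expected censored
  fraction equals `censor_rate` — the simplest mechanism satisfying the
  non-informative censoring the Kaplan–Meier estimator assumes.

Two generator defaults deserve justification because they decide whether a
3-replicate design can support the screen at all. The Welch engine at
3 vs 3 has roughly 4 degrees of freedom, so clearing $p<0.01$ in five
simultaneous contrasts needs a per-contrast noncentrality around 10; at a
4-fold planted effect that requires a residual log2 sd of about 0.2, i.e.
dispersion near 0.01 at counts above ~100. Hence (i) dispersion defaults to
0.01 — defensible for sorted, near-pure populations from inbred mice — and
(ii) planted markers and module genes get a base-mean floor of $2^7$
counts (`planted_floor_log2 = 7`): real screens search for markers among
detectably expressed surface genes, and network modules are by construction
genes that survive the expression filter, so planting either at the noise
floor would emulate data the method never claims to handle.

What the generators deliberately do **not** model: batch effects, UMI and
ambient-RNA artifacts, doublets, gene-length bias, correlated background
(outside the planted modules), competing risks, or informative censoring.
Passing tests therefore demonstrate that the pipeline's logic recovers
planted structure under its stated assumptions — not that those assumptions
hold in any particular public dataset.

## Replicate counts and problem sizes

The default study conditions are 2,000 genes, six populations of three
replicates (replicate counts are configurable; three is a deliberate,
conservative default for bulk designs of sorted populations), 30 planted
markers, five 20-gene modules at $r = 0.9$ with 60% module–signature
overlap, 200 cells per single-cell population, five microarray replicates,
and 300-subject cohorts with hazard ratio 2.5 and 30% censoring. The test
suite exercises smaller versions of the same conditions for speed; the
acceptance script (`scripts/acceptance.R`) re-runs the full defaults,
including 100 seeded network/CAC replications and 1,000-cohort null
calibration.

## Known limitations

* The Welch and two-part engines are surrogates for dedicated count-model
  engines (negative-binomial GLMs, zero-inflated mixtures, moderated
  t-statistics); they share selection rules, not internals.
* Edge significance assumes independent samples; replicate structure within
  populations is not modeled in the correlation test.
* CAC inherits the network's detection noise: at few samples, module edges
  are detected with probability well below one, so centrality ranks are
  stable only for sufficiently large modules.
* `stratify()` refuses all-equal scores rather than guessing a split.
* The connectivity null draws node groups uniformly; degree-preserving
  rewiring nulls are out of scope.
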