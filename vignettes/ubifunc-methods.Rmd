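---
title: "Methods: from PSM evidence to ubi-site functional scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from PSM evidence to ubi-site functional scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubifunc)
```

This vignette documents the models and procedures behind each stage of the
pipeline, the tunable parameters and their defaults, the numerical choices
made where the design was open, and what the synthetic-data generators do
and do not emulate.

## Site catalog

### Collapse model

A PSM covering a candidate ubiquitination site contributes a joint score
$s = p_{\mathrm{loc}} \cdot p_{\mathrm{PSM}}$, the product of its
localization probability and its PSM-level identification probability. A
PSM that covers the position without carrying the modification contributes
$s = 0$ (encoded as $p_{\mathrm{loc}} = 0$). Evidence is first reduced to
peptidoforms by taking the maximum $s$ within each peptidoform — repeated
spectra of the same peptidoform are redundant measurements, not
independent observations — and the site probability is then the mean of
the peptidoform scores:

$$ P(\text{site}) = \frac{1}{N}\sum_{j=1}^{N} \max_{i \in \text{pf}_j} s_i $$

where $N$ counts the covering peptidoforms. This realizes the idea of
comparing ubiquitination events against the total evidence for the
position; because the exact published collapse formula this stands in for
is not restated anywhere accessible, `collapse_psms_to_site()` is
deliberately small and isolated so the formula can be swapped without
touching the rest of the catalog.

### Decoy-alanine FLR

False localization rates come from decoy amino-acid competition: alanine
positions offered as localization candidates cannot truly carry the
modification, so decoy placements surviving a probability threshold $t$
estimate the false placements among surviving targets:

$$ \mathrm{FLR}(t) = \frac{\#\{\text{decoy} \ge t\} \cdot \rho}
                          {\#\{\text{target} \ge t\}} $$

clipped to $[0,1]$, with $\rho$ (`residue_ratio`, default 1) correcting
for the frequency ratio of target lysines to decoy alanines in the
searched database. Two conventions are fixed here: a threshold surviving
zero targets reports FLR 0 (nothing is being claimed, so nothing is
falsely localized), and per-site FLR assignment uses the monotonized
curve `flr_curve()` — the running minimum of the raw estimate as the
threshold rises, exactly analogous to q-value monotonization — because
the raw count ratio can jitter upward at sparse thresholds while the
quantity it estimates cannot.

Tiers then summarize per-dataset FLRs: Gold needs two independent
datasets below 1% FLR, Silver exactly one, Bronze at least one below 5%
with none below 1%. Ambiguous peptides resolve to the byte-wise
(C-locale) first accession: locale-dependent collation would make the
catalog irreproducible across machines, which outweighs any aesthetic
preference for case-insensitive ordering.

## Conservation levels

Human sites are mapped through orthologue alignments by ungapped-position
bookkeeping (`map_site_to_column()` and its inverse). Lysine conservation
at a column is the fraction of **non-human residues** that are lysine; we
read "residues" literally and exclude gap characters from the denominator
(a flag restores the gaps-count-as-non-K convention), and a column gapped
in every non-human member has undefined conservation, leaving the site
unassigned.

The level rules leave two gaps that had to be closed:

* The published thresholds ("< 10%", "> 10% and ≤ 50%") leave exactly
  10% uncovered; we close the boundary downward into level 2, so level 1
  is $c < 0.10$ and level 2 is $0.10 \le c \le 0.50$.
* A site detected in a distant species (chicken/fly/worm/yeast) but not
  in mouse or rat matches no rule. Such sites fall back to the
  conservation-based levels 1–3 and are flagged (`fallback` attribute and
  a warning) rather than silently promoted — the fallback is an explicit
  package decision, not an interpretation of intent.

Detection dominates sequence conservation: levels 4 and 5 are assigned
regardless of the lysine fraction, which the tests assert over random
conservation values.

## Domain hotspots

The observed signal for a column is the number of ubi marks in a centered
5-column window divided by the realized window width (truncated at the
alignment ends), i.e. an average number of ubi-sites per position. The
null model permutes each instance's marks uniformly over that instance's
lysine columns, preserving both the per-instance mark count and the
alignment's lysine landscape. The alternative — pooling marks across
instances before resampling — is available behind `global = TRUE`, but
per-instance permutation is the default because it conditions on exactly
the marginals that are not under test.

Column significance is $z = (\text{obs} - \text{median}_\pi)/
\text{sd}_\pi$ mapped through the standard-normal survival function:
only enrichment counts. Degenerate columns with zero permutation sd get
$z = 0$ when the observation equals the null and $z = +\infty$ when it
exceeds it, avoiding division blow-ups while keeping forced placements
(an instance with as many marks as lysines) exactly neutral.

Multiplicity is controlled by a **global** Bonferroni bound: `n_tests` is
the total column count over all eligible domains in a run, not per
domain. A column is called only if it additionally exceeds the effect
cutoff of 2 ubi-sites per position (strict inequality). Contiguous
significant columns merge, regions extend ±2 columns, and overlapping
extensions merge again. Eligibility (≥15 instances, ≥50 marks) is
checked before any statistics are computed.

## Perturbation regulation

Peptide-level log2 fold-changes average to sites within replicates, then
over replicates; conditions quantifying fewer than 500 sites are dropped
(strictly fewer — 500 survives). Pearson correlations use
pairwise-complete sites with a minimum overlap of 100 sites per pair
(the overlap floor is unstated in the procedure this mirrors; 100 keeps
the sampling error of $r$ below ~0.1). Clustering is complete-linkage
hierarchical clustering on $1 - r$, cut at $k = 4$.

Combining replicate conditions uses median/IQR normalization: each
column is centred on its median, scaled by its IQR (linear-interpolation
quantiles, R type 7), then mapped to the common scale via the median of
the column IQRs and medians before element-wise averaging. A single
column passes through bit-identically (the affine maps cancel
algebraically, so the implementation short-circuits), and zero-IQR
columns are excluded with a warning.

Regulated-site flags use the 5% tails per condition with non-strict
comparison against the interpolated quantiles — on tie-free complete
data this flags exactly $\lceil 0.05 n \rceil$ sites per tail — except
when the two quantiles coincide (an all-equal column), where strict
comparison yields zero flags. `n_regulations` excludes proteasome
inhibition conditions (their response reflects degradation flux rather
than signaling) while `n_quantifications` includes them.

The competitive set test is a two-sided Wilcoxon rank-sum test of set
members against the remaining quantified sites (exact for small untied
samples, normal approximation with continuity correction otherwise),
BH-adjusted across all (condition, set) pairs, with signed
$-\log_{10} p_{\mathrm{adj}}$ averaged within perturbation groups. The
activity-association filter applies three steps in order: BH-adjusted
Pearson correlation with parent-protein activity ($p_{\mathrm{adj}} <
0.05$), removal of sites accumulating under proteasome inhibition
(mean log2FC > 0), and — for positive correlations only — OLS
residualization of both site abundance and activity on protein abundance
followed by re-correlation (drop at unadjusted $p \ge 0.05$).

## Functional score

Preprocessing log-transforms the five heavy-tailed features
(pathogenicity, nearby PTMs, regulations, quantifications, protein
length), using `log1p` for any of them that contains zeros and the plain
natural log otherwise (the base only rescales weights). Missing
conservation levels are imputed with the overall mean computed on the
full table **before** any row dropping and cached with the transform;
rows missing any other feature are removed; everything is centred and
scaled. The fitted parameters travel as an attribute, so preprocessing a
processed table is a no-op and new data at prediction time reuses the
training transform.

Cross-validation is protein-grouped: all sites of a protein share a fold
(protein-level features would otherwise leak), and positives are
balanced across folds by a greedy bin-packing — proteins sorted by
positive count descending, each assigned to the currently lightest fold,
ties broken by a seeded shuffle. There is no canonical algorithm for
class-stratified grouped folds; this one is deterministic given the seed
and provably leak-free, which the tests assert over all 25 splits.

The model is logistic regression with inverse-class-size weights
$w_i = N / (2 N_{\mathrm{class}(i)})$ fitted by Newton/IRLS with step
halving. A ridge penalty of $\lambda = 10^{-6}$ on the non-intercept
coefficients (settable to 0) exists purely so the optimum is finite
under complete separation; at this magnitude it perturbs coefficients
well below the ensemble's seed-to-seed variation. One model per split
gives $5 \times 5 = 25$ fits; every model scores every site and the
functional score is the per-site median, with per-feature weight means
and standard deviations summarizing the ensemble. XRCC5 (P13010) is
excluded from training — its many jointly-derived annotations would let
the model memorize one protein — but still receives scores.

Architecture evaluation instead uses one 5-fold plan with five negative
subsamples per split at 10× the positive count, each fit scored by
rank-based ROC AUC (ties credited 0.5) on the untouched held-out fold.
The subsampled evaluation and the weighted final fit answer different
questions (generalization ranking vs. final scoring) and their AUCs are
reported without reconciliation.

## Synthetic data: what it does and does not show

Every generator is a pure function of `sim_config(seed = ...)` and emits
sidecar truth tables that the data files never contain. The reference
conditions and the reasoning behind them:

* **PSM generator** — 2,000 sites, 3 datasets, 10% planted false
  localization. Mislocalized and decoy records share one (lower) score
  distribution, distinct from correct placements; this is the matched-
  quality assumption under which decoy counts estimate false
  localizations, and it is what the FLR calibration property tests.
* **Orthologue generator** — ten species, 120-column alignments with
  per-member random indels; each group plants one site per level with the
  residue composition and detection pattern of exactly one rule. All
  residue content is fixed before any coordinate is derived, since
  planting a column un-gaps it and would otherwise shift previously
  recorded positions.
* **Domain generator** — 30 instances × 60 columns, lysine density 0.25,
  background mark rate 0.06 per lysine; the planted 5-column region is
  all-lysine and marked at 8× background (≈14 observed ubi-sites per
  position against ≈0.45 background), the power regime the acceptance
  check targets. Null calibration runs use enrichment 1 with a raised
  background rate (0.15) so the set stays above the 50-mark eligibility
  floor.
* **Fold-change generator** — four perturbation groups sharing latent
  responses (within-group $r$ well above between-group), planted
  regulated sets at +2 log2 units, 20% block missingness, one deliberately
  sparse condition (400 sites) for the coverage filter, and a positive
  proteasome-inhibition shift confined to the low-conservation stratum.
* **Feature generator** — 5,000 sites on 300 proteins at 1:50 imbalance.
  Labels are drawn from a logistic model on the *preprocessed* design, so
  weight recovery is well-posed; the intercept is solved numerically so
  the marginal positive rate hits the target. Per-site Bayes
  probabilities are emitted for AUC ceilings.
* **Activity generator** — 100 samples and four site classes (coupled,
  confounded, degradation-driven, null) whose fate under the three-step
  filter is known by construction.

Passing tests on these data show the algorithms do what they claim under
their own assumptions: correct rules, calibrated nulls, recoverable
planted effects, deterministic outputs. They do not show robustness to
what real compilations contain — correlated mislocalization, alignment
errors, batch effects between studies, non-logistic label noise, or
feature distributions matching real ubiquitinomes — and the marginal
feature distributions here only loosely imitate the real feature types.

## Problem sizes

The validation suite uses the sizes above throughout: 50-seed batteries
for hotspot calibration/power and the activity filter, 20 seeds for FLR
calibration and score recovery, 1,000 draws for the exact-oracle and
null-uniformity checks. These sizes make the binomial noise on each
checked rate small relative to its acceptance margin while keeping the
whole suite runnable in minutes on a laptop.
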