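---
title: "Cooperative regulatory networks and regulator influence: methods"
author: "coregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative regulatory networks and regulator influence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcription factors (TFs) are often activated post-transcriptionally —
by phosphorylation, complex formation, or ligand signalling — so their own
mRNA can stay flat while the genes they control shift en masse.  A
differential-expression analysis of TF transcripts therefore misses many of
the regulators that actually drive a condition.  `coregulon` implements
the complementary, network-based route:

1. infer a *cooperative* gene regulatory network (GRN) from a reference
   expression compendium: every target gene gets a local program, a pair
   `(A, I)` of co-activator and co-repressor TF sets;
2. integrate external evidence (TF-binding/ChIP edges, protein-protein
   interactions) to re-score candidate programs and to quantify how
   evidence-enriched the network is;
3. map a query experiment onto that fixed reference network and compute,
   per regulator and per sample, an **influence score** — a latent proxy
   for regulator activity read off its regulon rather than its own mRNA;
4. test regulators for **differential influence** between conditions
   (DIRs), genes for differential expression (DEGs), and gene sets for
   hypergeometric over-representation;
5. extract the co-regulatory **node**: the connected group of up-influenced
   regulators that share targets and interaction evidence.

A synthetic-data module generates datasets with a planted cooperating
regulator node so that the whole chain can be validated against known
ground truth.

## The influence score

For a regulator $r$ with activated regulon $A^r$ and repressed regulon
$I^r$, the influence in one sample is the Welch-type contrast

$$
\mathrm{Influence}(r) \;=\;
\frac{\overline{E(A^r)} - \overline{E(I^r)}}
     {\sqrt{\mu_{A^r}^2/|A^r| + \mu_{I^r}^2/|I^r|}},
$$

where $\overline{E(\cdot)}$ are the mean expressions of the two regulons in
that sample and $\mu$ their (unbiased) standard deviations.  A regulator is
*active* in a sample only when this value is strictly positive — activated
targets above repressed targets, as the network model expects.  A value is
computed only for regulators that regulate at least `min_targets` genes
(default 5, counting both regulon sides; a per-side reading is available via
`rule = "per_side"` because the qualitative phrase "activates or represses
at least five genes" admits both).

Two practical choices deserve note:

* **One-sided regulons.**  Many inferred regulators only activate (or only
  repress).  The two-group contrast is then undefined; by default the
  nonempty side is contrasted against all profiled genes that are not
  targets of that regulator, and the value is flagged
  `one-sided-fallback`.  `one_sided = "strict"` excludes such regulators
  instead.  Excluding them silently would hide most of a typical network.
* **Query standardization.**  The query dataset usually comes from a
  different platform than the compendium the network was inferred from, so
  each query gene is centred and scaled before scoring
  (`standardize = TRUE`).  The influence is a within-sample contrast
  across genes, so per-gene standardization removes baseline offsets
  without touching the between-sample structure the DIR test uses.

## Network inference

The inference is LICORN-like: cooperative, discrete, local.

* **Discretization.**  Each gene is standardized across samples; states are
  $+1$ ($z \ge 1$ SD), $-1$ ($z \le -1$), else $0$.  Zero-variance genes
  are all-0.
* **Co-regulator mining.**  A regulator set is *jointly active* in a sample
  when all members are $+1$ or all are $-1$; all sets up to
  `max_set_size` with support $\ge$ `min_support` are found by an
  apriori level-wise search (support is anti-monotone).
* **Local programs.**  For each target, candidate $(A, I)$ pairs are built
  from the mined sets (either side may be empty, not both).  A pair's
  *discrete fit* is the mean absolute difference between the observed
  target state and $\mathrm{sign}(s_A - s_I)$, where $s_A, s_I$ are the
  median collective states; fit lives in $[0, 2]$ and programs with fit
  above `fit_cutoff` are not admitted.
* **Numerical selection (the hybrid step).**  Discrete fits alone do not
  discriminate well at realistic noise: many spurious pairs tie with the
  true program on 40 samples of three-state data.  Admitted pairs are
  therefore ranked by the correlation between the target's standardized
  expression and the pair's net regulator signal, and the final selected
  program is refined by best-subset regression on the `subset_shortlist`
  most correlated regulators (subsets scored by BIC plus `bic_penalty`
  per coefficient; members join $A$ or $I$ according to the sign of their
  regression coefficient).  The purely discrete ranking remains available
  as `score_method = "discrete"`.

On noiseless single-activator data this recovers the generating network
exactly (edge F1 = 1); under the default noisy study conditions the
20-seed mean edge F1 is about 0.62 — both checked in the test suite.

## Evidence integration

External evidence arrives as plain edge lists: directed regulator-to-gene
binding/ChIP edges and unordered regulator-regulator interaction pairs.
For every retained candidate program the *evidence support* is the mean of
(a) the fraction of its regulator-to-target edges present in the TF-target
evidence and (b) the fraction of its internal regulator pairs present in
the PPI evidence (a one-regulator program has no pairs; the mean is then
just the edge fraction).  Programs are re-selected by

$$\mathrm{score} = (1 - \mathrm{fit}/2) + \lambda \cdot \mathrm{support},$$

with $\lambda \ge 0$ exposed (`lambda = 0` reproduces fit-only selection;
the additive form makes the preference monotone in $\lambda$).  Evidence
sources are pooled — binding-site and ChIP edges land in one TF-target
table with their source tags retained.

Network-level enrichment in evidence is tested with the hypergeometric
upper tail, under two universes because either convention appears in
practice: all unordered pairs of network regulators (`mode = "ppi"`), or
all network-regulator-by-network-target pairs (`mode = "tfbs"`).

## Differential analysis

Both feature types use per-feature Welch tests with
Benjamini-Hochberg control across features:

* **DIRs:** per regulator, influence values of condition B vs A;
  `delta` is the raw difference of condition means.  Classified `up` when
  `adj_p < 0.05` **and** `delta > 0.5`, `down` symmetrically; both
  inequalities strict.
* **DEGs:** per gene, log2 expression of B vs A; `up` when
  `adj_p < 0.05` and fold change strictly above 1.5
  (`log2_fc > log2(1.5)`).

A moderated (variance-shrunk) test is not the default: at the simulated
group sizes (20 vs 20) the per-feature Welch test is well calibrated — the
null simulations in the test suite bound the empirical DIR rate at the
nominal level.  For small designs an empirical-Bayes option
(`moderate = TRUE`) squeezes per-feature variances toward a common prior
and uses moderated t statistics with augmented degrees of freedom; at the
default group sizes the two orderings agree closely.
The `delta` reported is the plain condition-mean difference, the most
transparent reading of an "average difference in influence".

Over-representation of a gene set in a query list is the hypergeometric
upper tail $P(X \ge \mathrm{overlap})$; batch mode BH-adjusts across sets
and reports gene ratios (overlap / query size).

## Co-regulatory graph and the regulatory node

DIR-classified regulators become nodes (with their target counts and
influence differences); two nodes are connected when they co-occur in at
least `min_shared_targets` local programs.  Edges carry one or more types:
`ppi_evidence`, `transcriptional_evidence` (one regulator's own gene is an
evidenced target of the other; direction preserved), or `inferred_only`.
The **regulatory node** is the largest connected component of the
up-classified subgraph (ties broken by lexicographically smallest member);
its **mean group influence** is defined here as the arithmetic mean of the
members' influence differences — a deliberate, documented interpretation,
since group influence admits several formalizations.  Graphs export to
GraphML (attributes and edge direction preserved; re-import reproduces the
graph) and SIF (one row per edge type).

## The synthetic-data generator

The generator emulates a two-condition activation study on a log-like
expression scale:

* regulator activities $a_{r,s} \sim N(0,1)$, with a shift $\delta$ added
  for the `planted_node_size` cooperating regulators in conditions whose
  `condition_effects` multiplier is 1 (inhibitor-like conditions set it
  back to 0);
* regulator mRNA is activity plus $N(0, \sigma)$ noise; with
  `decouple_mrna` the planted regulators' mRNA omits the shift while
  their targets still respond — the post-transcriptional activation the
  influence score exists to detect;
* each target's expression is a weighted sum of activator activities minus
  repressor activities plus noise; the planted regulators co-activate a
  dedicated block of targets (default 30) so node extraction is testable;
* evidence is a corrupted view of the truth: a coverage fraction of true
  TF-target edges plus spurious ones, and PPI records for all planted
  pairs plus random pairs;
* `simulate_query()` draws a fresh dataset on an existing ground-truth
  topology, reproducing the reference-network/query-experiment split of a
  real mapping study.

Defaults — 30 regulators, 300 targets, 20+20 samples, $\delta = 2$,
$\sigma = 1$, a 3-member node, edge weights uniform in $[0.8, 1.2]$, 1–3
activators and 0–2 repressors per background target, evidence coverage
0.8 with 10% spurious edges — describe a moderate-sized, moderately noisy
activation experiment: unit noise on unit-variance activities, shifts of
two noise SDs, and regulon sizes small enough that the $\ge 5$-target
eligibility rule bites.  What the generator does *not* model: count noise
and mean-variance dependence (inputs are assumed normalized and
log-scale), batch effects, chained TF-TF regulation, and feedback.
Passing the planted-recovery tests therefore demonstrates the machinery is
correct and calibrated under additive Gaussian conditions, not that it
overcomes RNA-seq count artefacts.

Randomness is organised in named sub-streams (topology, weights,
activities, noise, evidence), each seeded from the one user seed, so a
change that consumes more draws in one phase cannot silently shift another
phase's output; identical configuration and seed give byte-identical
datasets and pipeline output directories.

## Numerical and degenerate-input choices

* Unbiased ($n-1$) variances everywhere, matching the Welch conventions.
* A regulon side with fewer than two profiled genes has no variance; the
  influence value is undefined (`NA`) rather than guessed.
* Zero-denominator contrasts (both regulon sides constant) are flagged
  `zero-denominator`.
* Exact-zero regression residuals in best-subset selection are treated as
  exact fits; size-ascending enumeration with strict improvement then
  prefers the smallest exact subset, which makes the noiseless case
  reproducible across platforms.
* Missing expression cells follow an explicit policy: `fail` (default) or
  `gene-mean` row-mean imputation.  Nothing more elaborate is attempted —
  latent-signal estimation of unobserved genes is out of scope.
* All classification inequalities are strict, so boundary values
  (`delta = 0.5`, `adj_p = 0.05`, fold change exactly 1.5) are `ns`.
* Ties anywhere in selection are broken deterministically
  (score, then fit, then size, then lexicographic key).

## Problem sizes used in validation

The packaged tests and the acceptance script run the full chain at the
default study conditions: 20 seeds for network recovery and planted-node
recovery, 20 seeds for the decoupled-query analysis, 50 no-shift runs for
null calibration, 200 random instances for the influence-formula check,
and 1,000 random vectors for the BH step-up check.  These sizes give
Monte-Carlo error well below the decision margins involved while keeping a
complete validation run in the minutes range on one core.

## Known limitations

* Edge-level recovery at the default noise level is capped well below 1
  (mean F1 ≈ 0.62): with 40 samples and unit noise, part of the edge set
  is genuinely unidentifiable; the influence layer is robust to this
  because regulon contrasts average over many targets.
* The regulatory node is a connected component, not a density-based
  cluster; on very dense DIR graphs it can absorb weakly attached members.
* The evidence model treats all sources alike; no per-source reliability
  weighting.
* Multi-factor designs and paired tests are out of scope; contrasts are
  explicit ordered condition pairs.
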