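---
title: "Methods: metabolome-guided multi-omics analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolome-guided multi-omics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(guideomics)
```

# The analysis model

`guideomics` analyses paired multi-omics profiles of one stool-sample
cohort with three diagnosis groups (HC, iRBD, PD). Its central idea is that
feature-level differential analysis should be *guided* by the omics layer
that separates the diagnosis groups without being associated with measured
confounders, and that the metabolites found there should then be traced
back — through a reaction universe — to the genes, transcripts, taxa and
network positions that could produce them. This vignette documents the
statistical machinery, the tunable parameters, the synthetic study the
package generates for itself, and the design decisions taken where more
than one defensible choice existed.

## Data model

* `omics_table` — one feature-by-sample abundance matrix per layer
  (taxMG, taxMT, taxMP, funMG, funMT, funMP, MM), non-negative, with a
  `normalized` flag. Sum normalization divides each sample column by its
  sum; it is idempotent, and all-zero samples are rejected rather than
  silently propagated.
* The meta-metabolome arrives in three blocks (untargeted, targeted SCFA,
  targeted bile acids). Each block is sum-normalized *first* and the
  normalized blocks are then concatenated, so each block's sub-columns sum
  to 1 and a merged column sums to 3. We deliberately do not re-normalize
  after merging: the alternative (one more sum normalization over the
  merged matrix) would weight blocks by their feature counts rather than
  equally; per-block normalization keeps the three measurement platforms
  on equal footing. The block of origin and the identified/unidentified
  status travel with the features.
* `reaction_universe` — KO → reactions → (reactant, product) compound
  sets, compound names, and a cofactor list. It is serialized as a single
  JSON document; parsing raw database dumps is out of scope, which keeps
  the artifact small, offline-testable, and format-stable.
* `taxon_tensor` — genus × KO × sample expression array whose
  genus-collapsed margin reproduces the funMT rows of its KOs.
* `cohort_metadata` — per-sample diagnosis group (never missing), sex,
  age, constipation and recruitment cohort (confounders may be missing;
  they are dropped per factor at analysis time).

# Stage 1: diversity and guide-layer selection

Alpha diversity is the Shannon index in natural log units ($H = \ln n$ for
$n$ equally abundant features); the base is a convention choice and is
stated here because downstream fold changes of $H$ depend on it. Beta
diversity is Bray-Curtis, computed through `vegan::vegdist` with an
explicit rejection of all-zero samples (their distance is undefined).

PERMANOVA is implemented in the package (and cross-checked against
`vegan::adonis2` and exhaustive enumeration in the test suite) because the
permutation engine needs three behaviours in one place:

* vectorized permutations — the within-group quadratic forms of all
  permuted label assignments are computed with three matrix products, which
  keeps 100-replicate screens with 1000 permutations each in seconds;
* exhaustive enumeration when a two-group design has at most `n_perm`
  distinct assignments, in which case $p$ is the exact fraction of
  assignments (including the observed one) with $F^\pi \ge F$;
* a regression (Gower-matrix) form for numeric factors such as age:
  $G = -\tfrac12 C D^{(2)} C$ is projected on the centred covariate and
  $F = SS_{model}/(SS_{res}/(n-2))$ — algebraically identical to the
  categorical decomposition when the covariate is a dummy coding.

Sampled permutation p-values use the add-one estimator
$p = (1 + \#\{F^\pi \ge F\})/(1+n_{perm})$, so $p \in [1/(n_{perm}+1), 1]$
and is never zero. Permutations are free (unstratified): no blocking
scheme across the two recruitment cohorts is applied, since the cohort
label is carried in the metadata and can be screened like any other
factor. Defaults: `n_perm = 1000`, `alpha = 0.05`.

`select_guide_layer()` declares a layer *eligible* when its diagnosis
p-value is below `alpha` and every screened confounder p-value is at or
above `alpha`, and ranks eligible layers by diagnosis $R^2$. "No eligible
layer" is a reported outcome, not an error: abstention is the correct
behaviour when every group-separating layer is confounded.

**A screening caveat worth knowing.** When confounders are themselves
correlated with diagnosis — as sex and constipation are in this disease
setting — any layer with a genuine diagnosis effect acquires a *marginal*
confounder association of magnitude roughly
$R^2_{group} \cdot \mathrm{cor}(confounder, group)^2$. With an
$\alpha = 0.05$ screen over three confounders, a guide layer is therefore
occasionally screened out even when no confounder effect was planted
(three exact 5% tests alone abstain in about one run in seven). The
package keeps the screen as specified; users screening many correlated
confounders should expect conservative abstentions, and the test suite
exercises the selection property against the manipulated confounder.

# Stage 2: metabolite differential analysis

Unidentified compounds are removed before testing (they cannot be linked
to genes). Per feature: a tie-corrected Kruskal-Wallis omnibus test
(vectorized across features; exactly `stats::kruskal.test`'s statistic,
verified in the tests) and Dunn's post hoc z on the joint ranks with the
tie term $\sum_t (t^3-t)/(12(N-1))$, two-sided normal p-values, average
ranks everywhere. Benjamini-Hochberg correction is applied across features
separately within the omnibus family and within each pairwise family,
mirroring the way per-comparison panels are usually reported. A feature
that is constant across all samples gets $p = q = 1$ and a flag — a
degenerate input, not an error. Features pass at $q < 0.05$.

Two-group comparisons use `stats::wilcox.test`: exact for small untied
samples, normal approximation with tie correction otherwise. Effect sizes
are $\log_2$ fold changes of group means with a scale-adaptive pseudocount
of half the smallest positive value of the table — small enough not to
distort real fold changes, large enough to keep zero means finite; the
value used is recorded in the output's attributes.

Variance explained per feature and clinical factor is the one-way ANOVA
decomposition $1 - SS_W/SS_T$, clipped to $[0,1]$: unitless, invariant
under affine rescaling of the feature, 1 when levels are internally
constant but different, and 0 (flagged) for a zero-variance feature. A
published rendering of this quantity as $(1 - var_{group})/var_{total}$ is
not scale-invariant and can be negative; we read it as a typesetting
artifact of the standard decomposition and additionally return the raw
per-level variances so any alternative summary can be reconstructed.
Samples missing the factor are dropped for that factor only.

# Stage 3: KO linkage

Compound retrieval is by case-insensitive regular expressions over
compound *names* (annotations are text; ids differ across databases),
unanchored by default — a pattern like `glutamate` matches L-, D- and
beta-glutamate, and `^serine$` anchors exactly. A KO is linked to a
compound set when any of its reactions touches the set on either side;
reactants and products are treated symmetrically throughout, since
reaction directionality is not modelled. Because metabolome annotations
typically carry only one beta-glutamate entry, `glutamate_ko_set()`
implements the standard widening to all glutamate species. Pattern sets
per metabolite are user configuration; the pipeline defaults to
exact-name patterns built from the significant compounds, with the
glutamate widening applied automatically.

# Stage 4: genes vs transcripts

`differential_ko()` runs the same Mann-Whitney machinery per KO separately
on sum-normalized funMG and funMT, with BH families per (layer, pair), and
tags rows by layer so the transcript-only dissociation — significant in
funMT, null in funMG — is a simple filter. Missing KOs yield flagged rows.
`pathway_panel()` combines these rows with the log2 fold change of mean
per-KO taxonomic Shannon diversity between the groups and tallies members
decreased/increased in the second group of the pair at $q < 0.05$; the
tallies partition the pathway. Per-KO Shannon diversity is computed per
sample and then averaged within groups (not pooled per group first); a
sample with zero expression of the KO contributes a missing value rather
than $H = 0$, because an unexpressed function has no diversity to measure.
The tensor is an explicit argument of `pathway_panel()` — taxonomic
diversity cannot be derived from the KO-level tables.

Spearman correlations (average-rank ties) between metabolites and features
of another layer use the t approximation for p-values, with an exact
permutation option for very small n; BH is applied across all
(metabolite, feature) pairs. Constant vectors leave rho undefined and
flagged.

# Stage 5: taxon-resolved expression

TPM normalization scales each sample slice of the tensor to $10^6$; no
gene-length term is applied because synthetic features are length-free —
real-data users should supply length-normalized counts. Group profiles are
plain means per (genus, KO, group); per-genus totals are reported both raw
and square-root transformed (a display convention, preserved in the
output rather than applied silently). Genus clustering uses the Canberra
distance on the log2 fold-change matrix with Ward.D2 linkage; Canberra
terms with a zero denominator contribute 0 — base `dist()` instead
rescales them like missing values, which is why the package carries its
own 15-line implementation. The cluster count `k` is a user parameter with
default 4, matching the narrative four-cluster structure typically
described for such heatmaps; the dendrogram order is emitted so any `k`
can be revisited. Clustering is fully deterministic.

# Stage 6: the community metabolic network

KOs present in at least 50% of samples (inclusive boundary: nonzero in
$\ge \lceil 0.5 n \rceil$ samples means a KO at exactly 50% is kept) are
connected to the non-cofactor reactants and products of their reactions.
Cofactor removal commutes with construction, and compounds left without
edges are dropped. The KO projection joins two KOs sharing any non-cofactor
compound; the compound projection ("inverted network") joins two compounds
sharing a KO. Projections are simple and unweighted — the shared labels and
their multiplicity are kept as edge attributes so weighted variants remain
possible, but centralities are computed on the unweighted graph because
single per-node centrality values are the analysis target. A directed
product-to-reactant chaining variant was considered and not made the
default: with directionality unmodelled, the symmetric rule is the
conservative reading.

Activity ratios per KO node are
$(\bar{MT} + \varepsilon)/(\bar{MG} + \varepsilon)$ over sum-normalized
layers with the shared half-minimum pseudocount, so KOs absent from one
layer stay finite (and flagged). Betweenness centrality is reported both
raw (shortest-path counts over unordered pairs) and normalized by
$(n-1)(n-2)/2$; graphs with fewer than 3 nodes score 0, and disconnected
graphs are handled per component with global normalization. Subnetwork
summaries compare the mean *whole-graph* centrality over a node subset
against the mean over all nodes — deliberately not recomputed on the
induced subgraph, because the question is the subset's importance within
the whole community; both scales are reported since mixing them produces
incomparable numbers.

# The synthetic study

`generate_study()` produces a fully consistent study under three presets
(`paper-like`, `null`, `hub-demo`). What it emulates, and what it does not:

* **Counts.** Gamma-Poisson (overdispersion shape 3, a mid-range value
  for stool profiles) around log-normal feature baselines, with
  log-normal sequencing depths (sdlog 0.3). It does *not* emulate
  phylogenetic correlation between features, zero-inflation beyond what
  the mixture produces, or batch structure — so passing tests show the
  statistics behave under honest compositional noise, not that they
  survive every real-data pathology.
* **Cohort.** 49 HC / 27 iRBD / 46 PD; male excess (50/80/65%) and
  elevated constipation (12/30/33%) in the disease groups; ages from one
  shared distribution; two recruitment cohorts. The constipation gap is
  set at the low end of what such cohorts report: because constipation is
  correlated with diagnosis, any stronger gap makes the generator violate
  its own declared truth that the metabolome carries no confounder effect
  (see the screening caveat above).
* **Metabolome.** Three blocks (180 untargeted of which 30 unidentified,
  8 SCFA, 12 bile acids). Twenty planted differential compounds at
  4-fold in PD with a $\sqrt{}$-attenuated iRBD effect, including a
  beta-glutamate and branched-SCFA increase and primary-bile-acid
  decreases. Planted compounds are generated as *minor* constituents
  (baseline intensity scaled by 1/12): this calibrates the layer-level
  group separation to the modest $R^2 \approx 0.04$–$0.06$ scale reported
  for real fecal metabolomes while leaving rank-based per-feature power
  untouched — rank tests are invariant to a feature's absolute scale.
* **Transcript-only effects.** 30 KOs multiplied by 0.25 in PD in funMT
  only; funMG is generated from the same baselines without the effect.
  The tensor splits each tensor-KO's expression across genera with sparse
  Dirichlet-like loadings, and funMT rows of tensor KOs are the exact
  genus-collapse of the tensor — an identity the pipeline asserts.
* **Confounder leakage.** 3-fold sex effects on 15% of taxMT and funMT
  features only, so guide-layer selection must reject the transcript
  layers.
* **Network truth.** One non-cofactor hub compound, named "L-glutamate",
  participates in 25% of reactions (60% in `hub-demo`); 12 cofactors
  (water, energy carriers) are attached to most reactions and excluded at
  network construction.

All randomness flows from one master seed through fixed per-component
substreams; identical seeds give byte-identical studies, and the planted
truth is serialized next to the data.

# Numerical choices and degenerate inputs

* Pseudocounts: half the smallest positive value of the relevant table(s);
  recorded in outputs.
* Ties: average ranks everywhere; Kruskal-Wallis and Dunn carry explicit
  tie corrections; Mann-Whitney switches to the normal approximation under
  ties.
* Constant features: $p = q = 1$ with a flag (testing a constant is a
  well-defined null, not an error). Constant vectors in correlations:
  undefined rho, flagged.
* All-zero samples: rejected by normalization, Bray-Curtis and TPM with
  the sample named.
* Permutation p-values: add-one estimator, never 0, seed-stable through
  isolated RNG streams (`withr::with_seed`), pair order locale-independent.
* Tolerances: symmetry of distance matrices to $10^{-12}$; normalized
  columns to $10^{-9}$; exact equality where the quantity is discrete.

# Problem sizes used by the test suite

The package's reference dimensions are 300 taxa, 800 KOs, 150 compounds
(12 cofactors), 200 metabolome features and a 40 × 120 tensor at the full
cohort size. The test suite runs the same machinery at reduced feature
dimensions (40–200 KOs, 40–70 metabolome features) chosen so the whole
suite completes in about two minutes; the properties checked — oracle
agreement, type-I calibration, planted-truth recovery, determinism — do
not depend on those sizes, and replicated checks (100-replicate FDR and
recovery runs, 500 null permutation simulations) keep the full cohort
where power matters.

# Known limitations

* The guide-layer screen abstains conservatively when confounders
  correlate with diagnosis (quantified above); in a 100-replicate
  evaluation of the selection scenario, the conjunction of "metabolome
  flagged" and "both transcript layers rejected" holds in 93–96 runs,
  with the remainder lost to the screen's own 5% false-alarm rate and to
  borderline group-effect power at the calibrated effect size.
* Reaction directionality, stoichiometry and flux are not modelled; the
  network is a connectivity summary.
* TPM here carries no gene-length correction.
* Multi-factor and interaction PERMANOVA, dispersion tests and ordination
  graphics are out of scope; the distance matrices and statistics behind
  them are the package's surface.
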