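---
title: "Methods: signature reversal screening with a fingerprint QSAR ensemble"
author: "reposcreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature reversal screening with a fingerprint QSAR ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`reposcreen` implements a computational drug-repositioning funnel for
neuroprotection discovery: disease gene signatures built from expression
cohorts, a connectivity screen that scores compounds for transcriptional
reversal of those signatures, a fingerprint-based potency regression ensemble
with an applicability domain, Shapley-value interpretation mapped back to
molecular substructures, and an orchestrated screening funnel. This vignette
describes the statistical models, the choices that were genuinely open, and
what the synthetic-data tests do and do not establish.

## Disease signatures

Expression cohorts (log2 microarray intensities) are quantile-normalized so
that every sample shares the across-sample mean quantile distribution
(`limma::normalizeQuantiles`, ties averaged; the operation is idempotent and
rank-preserving within samples). Probe-level rows collapse to genes by
keeping the probe with the highest mean expression — a standard microarray
convention chosen here for determinism; ties break by probe id. Whether the
input is already on log2 scale is declared by the caller
(`already_logged`), never guessed from value ranges.

Differential expression uses a two-sample moderated t-test: per-gene pooled
variances are shrunk toward an empirical-Bayes prior,
$\tilde{s}^2_g = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$, with the prior
$(d_0, s_0^2)$ estimated by method of moments from the observed variance
distribution (`limma::squeezeVar`); p-values use $d + d_0$ degrees of
freedom. Setting the prior df to zero recovers the ordinary pooled-variance
t-test exactly, which the tests verify against a brute-force implementation,
and the default path is cross-checked against the full `limma`
`lmFit`/`eBayes` pipeline. Genes pass the filter when $p < 0.05$ and
$|\log_2 FC| > 0$, both inequalities strict; the fold-change threshold of
zero is read literally (any nonzero fold change qualifies) and both
thresholds are configurable. No multiple-testing correction enters the
filter; a Benjamini–Hochberg column is emitted for information only.

Cohort signatures are intersected separately for up- and down-regulated
sets. With direction-disjoint per-cohort sets a gene can never survive in
both intersected directions; the conflict guard (drop from both, with a
message) exists for robustness against externally supplied set files.

## Connectivity scoring

Each compound's perturbation profile is the unweighted mean of its replicate
signatures (dose, cell line and duration deliberately averaged away), then
ranked: rank 1 is the gene most up-regulated by the compound, ties broken by
gene id so ranking is deterministic. For a query set of size $t$ in a
profile of $n$ genes with ordered in-set ranks $V(1) < \dots < V(t)$, the
enrichment score uses the Kolmogorov–Smirnov form

$$a = \max_{j} \left[ \frac{j}{t} - \frac{V(j)}{n} \right], \qquad
  b = \max_{j} \left[ \frac{V(j)}{n} - \frac{j-1}{t} \right],$$

with $ES = a$ if $a > b$ and $ES = -b$ otherwise. The overall connectivity
score is $s = 0$ when the up- and down-set scores share a sign, and
$s = (ES_{up} - ES_{down})/2 \in [-1, 1]$ otherwise; negative $s$ means the
compound reverses the disease signature. Two conventions here were open:

* the combination rule could plausibly carry a per-batch normalization by
  the largest $|s|$; the raw $/2$ scale is kept (a `normalize` flag is easy
  to add downstream) because it keeps scores comparable across runs;
* the screening statistic behind the "KS screen" stage is a one-sample KS
  uniformity test of the pooled up+down query-gene ranks within each
  compound's profile, at $\alpha = 0.05$. Other variants (per-direction
  tests, D+ only) are defensible; this one uses all query genes at once and
  is the package's documented choice.

A position-sweep oracle (empirical CDF of the in-set ranks against the
uniform CDF, evaluated at every rank) verifies the closed form on random
instances; swapping the query's up and down sets negates every score
exactly.

## Molecular fingerprints

Molecules are parsed and canonicalized by OpenBabel (via ChemmineR /
ChemmineOB); invalid SMILES yield a soft failure flag, multi-fragment
inputs keep their largest fragment, and no tautomer canonicalization is
attempted. Formal charges are recovered from bracket atoms of the canonical
SMILES (with a valence-based fallback), because the intermediate SDF
representation does not carry them reliably.

Six encodings are available. Four hashed kinds are computed natively from
the molecular graph so that every set bit can be traced to the atom
environments that produced it — the property the interpretation stage needs
and that no installed library provides:

* **ECFP4 / FCFP4** — circular (Morgan) fingerprints of radius 2, default
  2048 bits. ECFP atom invariants are (atomic number, heavy degree,
  implicit H count, formal charge, ring membership, aromaticity); FCFP
  starts from a six-bit pharmacophore code (donor, acceptor, aromatic,
  halogen, basic, acidic). Duplicate environments (identical bond sets) are
  emitted once.
* **Path-topological** — all simple bond paths between `min_path = 1` and
  `max_path = 7` bonds, atoms encoded by element and aromaticity, bonds by
  order/aromaticity, direction-canonicalized and hashed to 2048 bits.
* **Avalon-style** — a feature-class fingerprint (512 bits) enumerating
  atom types, augmented atoms, bond types, ring features and short paths,
  with capped occurrence counts; an in-house implementation of the
  feature-enumeration approach.

MACCS keys (166 + an index-0 pad) come from OpenBabel; their predefined
SMARTS are read from the installed OpenBabel data table at run time, so
MACCS substructure reports carry SMARTS but no atom indices. The PHYSCHEM
block is an explicit frozen registry of 123 named scalar properties
(including QED, MolWt, TPSA; topological indices computed from the graph;
OpenBabel's logP/MR/TPSA) followed by 85 named `fr_*` SMARTS fragment
counts — 208 values in total. The QED entry is a geometric mean of smooth
property desirabilities with package-chosen shapes (weight, logP, H-bond
counts, TPSA, rotatable bonds, aromatic rings, structural alerts); it is a
drug-likeness score in $(0, 1]$, not a reimplementation of any external
parameterization.

Hashed bit positions are meaningful only within one configuration (kind,
bit length, path bounds), which is why the configuration is stamped into
every trained model bundle; feature indices reported by the interpretation
stage are configuration-relative by construction.

Tanimoto similarity $|A \cap B| / |A \cup B|$ is defined for bit kinds only
(the PHYSCHEM block is rejected at type level); two empty fingerprints
score 0. Tanimoto is not a metric, so no triangle-type property is claimed.

## The potency ensemble

Training examples are (SMILES, EC50 in µM) pairs; the regression target is
pEC50 $= 6 - \log_{10}(\mathrm{EC50}_{\mu M})$. Modeling on the log scale is
implied by the order-of-magnitude agreement statistic used to judge
predictions, and the back-transform $10^{6 - \mathrm{pEC50}}$ restores µM.
The data split is random 4:1 (test size $\mathrm{round}(N/5)$), seeded;
scaffold-based splitting is the more rigorous option for publication-grade
generalization claims and can be layered on top, but the random split is
the default to match the screening context in which the model is deployed.

Three regressors are fit on the identical fingerprint matrix: a random
forest (`randomForest`), an RBF $\varepsilon$-SVR (`e1071`, unscaled inputs
since bits are already 0/1), and gradient-boosted trees (`xgboost`,
single-threaded for determinism, base score at the target mean). The
ensemble prediction is the unweighted arithmetic mean of the three pEC50
outputs — the simplest combination rule, kept because the members have
comparable error scales; weighted variants are deliberately out of the
default path. Default hyperparameters (RF: 500 trees, depth cap 16,
one-third feature sampling; SVR: $C = 10$, $\gamma = 0.01$,
$\varepsilon = 0.1$; GBDT: 300 rounds, $\eta = 0.05$, depth 4, 80%
subsampling) are sensible for a few hundred compounds on a few hundred to
a few thousand bits.

Hyperparameter tuning is a compact tree-structured Parzen estimator:
after a random start-up phase, trials split at the $\gamma = 0.25$ loss
quantile; per parameter, Parzen mixtures over the good and bad trial values
(bandwidths from neighbour spacing, floored at 0.05 in unit space) give
densities $l(x)$ and $g(x)$; candidates are drawn from $l$ and the
$l/g$-maximizer is evaluated by 5-fold cross-validated RMSE. Integer and
log-scale parameters are handled in transformed space. The search spaces
are RF {trees 100–1000, depth 3–30, feature fraction 0.1–1}, SVR
{$C \in [10^{-2}, 10^3]$, $\gamma \in [10^{-4}, 1]$ (both log),
$\varepsilon \in [0.01, 1]$} and GBDT {rounds 100–1000, learning rate
$[10^{-3}, 0.3]$ log, depth 2–8, subsample 0.5–1}. Tuning is off by
default (`tune_budget = 0`); the default budget when enabled is 100 trials.

Performance reports carry MAE, MRE $= \overline{|y - \hat y| / |y|}$
(observations with $y = 0$ excluded and counted), MSE, RMSE and
$R^2 = 1 - SS_{res}/SS_{tot}$, verified against a naive elementwise
implementation in the tests.

The applicability domain is the maximum Tanimoto similarity of a candidate
to any training fingerprint, in the bundle's own fingerprint space; a
candidate is in-domain iff that maximum strictly exceeds 0.6. The gate is
strict by specification — a candidate at exactly 0.6 is out of domain.

## Interpretation

Tree models (RF, GBDT) are explained exactly under the path-dependent
formulation: the value of a feature subset $S$ is the tree-walk expectation
that follows the instance at splits on features in $S$ and averages
children by their cover fractions elsewhere. The package ships a
polynomial-time implementation of this computation (Rcpp; EXTEND/UNWIND
weight recursions along root-to-leaf paths). Covers for `randomForest`
trees, which do not store them, are estimated by passing the training data
through each tree. For GBDT the attribution comes from xgboost's built-in
TreeSHAP, which also serves as an independent cross-check of the Rcpp
implementation in the tests; an exhaustive-subset Shapley oracle over the
tree-walk value function is the ground truth for both on small models.

The SVR is explained by Kernel SHAP against a fixed background of at most
100 training rows: features identical between the instance and every
background row receive exactly zero; the remaining $M$ features are solved
by weighted least squares over coalitions — fully enumerated (exact
Shapley) when $M \le 13$, otherwise paired-complement sampling with
Shapley-kernel size weights, under the local-accuracy constraint
$\phi_0 + \sum_i \phi_i = f(x)$. This explainer asymmetry (exact for trees,
sampled for the margin model) is deliberate and documented.

Feature importance for the top-$k$ panels is the mean absolute Shapley
value over the explained instances, descending, ties by feature index;
consensus across the three models is plain set intersection (pairwise
intersections are reported for Venn-style exports). One subtlety matters
when interpreting hashed fingerprints: a planted substructure typically
occupies a small *class* of equivalent bits (several paths inside the same
group, all present exactly when the group is), and correlated-feature
credit assignment differs across model families — boosted trees tend to
concentrate on one representative while forests spread credit. Substructure
recovery is therefore assessed at the substructure level: recovery means
some bit of the planted class survives the three-model top-20 intersection.
`planted_bit()` exposes the whole class via its `candidates` attribute.

`explain_compound()` ties the pieces together for one molecule: for each
consensus feature it reports presence in the molecule's fingerprint, the
per-model Shapley values, and — via the recorded bit environments — the
atom/bond sets and induced-subgraph SMILES behind the bit.

## Screening funnel

Stages run in a fixed, documented order: KS screen → curated-list
intersection (skipped when no list is supplied; curated lists and exclusion
lists are consumed as user-supplied ids, never computed) → applicability
domain (strict > 0.6) → ensemble prediction → ranking by ascending
predicted EC50 (most potent first; ties by connectivity score, then
compound id) → top-$n$ cut (default 50) → exclusion-list removal. The
ranking criterion for the top-$n$ cut was open; predicted potency is the
natural choice given the model exists to rank potency, and the
connectivity-score tiebreak keeps the ordering deterministic. Every record
keeps the flag of the stage that dropped it, so stage counts are monotone
non-increasing by construction and each shortlist member's path is fully
reconstructible; reports serialize byte-identically under identical seeds.
Whether a curated list should apply before or after the KS screen is
ambiguous in general; the configured order (KS first) is documented and
the stage is a no-op without a list.

## Synthetic data: what it emulates and what it does not

The generators plant known truth so that every stage is testable offline:

* **Cohorts** — per-gene baselines $\mathcal{N}(8, 1)$ on the log2 scale
  with iid $\mathcal{N}(0, \sigma)$ noise; planted genes shift by
  $\pm$`effect` in cases with signs shared across cohorts. Defaults
  (2000 genes, 10 vs 10 samples, 100 planted genes, effect 2, $\sigma$ 0.5,
  3 cohorts) are the conditions under which the pipeline is expected to
  recover $\ge 90\%$ of planted genes; Gaussian noise matches the
  log-intensity data class, not RNA-seq counts.
* **Signature database** — background compound signatures
  $\mathcal{N}(0, 1)$ per gene; planted reversers shift the query's up
  genes down and down genes up by `strength` (default 3); 1–3 replicate
  conditions per compound exercise profile averaging.
* **SAR library** — valid SMILES enumerated by decorating five scaffolds
  with small substituents; half the compounds carry a planted sulfonamide,
  and pEC50 $=$ base $+$ effect $\times$ carrier $+ \mathcal{N}(0, \sigma)$
  (defaults: $n = 200$, base 5, effect 1.5, $\sigma$ 0.3). Enumerated
  decoration keeps the substructure ground truth unambiguous for the
  interpretation tests.

Every generator is a pure function of its arguments and seed. Passing tests
on these data show that the machinery is correct — formulas match oracles,
planted signal is recovered under the stated effect sizes — not that the
pipeline reproduces any particular clinical dataset: real cohorts have
correlated genes, batch effects and platform idiosyncrasies; real
structure–activity landscapes are not single-substructure additive; and
real compound databases have heterogeneous assay noise. The two
cohort-reproduction checks that require the original GEO series matrices
run only when those files are available locally.

## Numerical choices and problem sizes

Ties in ranking break lexically by gene id; hashing uses an exact-in-doubles
polynomial hash mod $2^{31} - 1$; Kernel SHAP adds a $10^{-10}$ ridge to
its normal equations; degenerate (zero-variance) targets fit a constant
model with a warning; empty gene sets and empty candidate tables are
handled explicitly. The test-suite experiments use deliberately moderate
sizes — 512-bit path fingerprints, 300-tree forests, 200-round boosters,
20 explained instances with a 16-row background and 400 sampled coalitions
per instance, 20 seeds per stochastic claim — chosen so the whole suite
runs comfortably on a single CPU while leaving the measured margins (e.g.
median ensemble test $R^2 \approx 0.8$ against the 0.6 criterion) wide.

## Known limitations

Fingerprint bit indices are not comparable across configurations or to any
external implementation's indices. OpenBabel's aromaticity and charge
perception differ in places from other toolkits, so descriptor values are
internally consistent rather than toolkit-portable. The KS screening
variant and the score-combination scale are reconstructions of
under-specified steps and are flagged as such above. Kernel SHAP for the
SVR is stochastic at high feature counts; its seed and budgets are recorded
wherever it is used. No 3D chemistry, conformers, docking or
blood–brain-barrier prediction is attempted, and curated drug lists are
inputs, not outputs.
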