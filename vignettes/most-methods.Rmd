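---
title: "Most-similar ligand target inference: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Most-similar ligand target inference: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference model

Chemical similarity searching rests on the observation that structurally
similar compounds tend to share biological activities. Recent benchmark work
suggests that when a query compound is compared against a target's annotated
ligand set, the prediction is driven almost entirely by the single
most-similar ligand — the rest of the set adds little. This package takes
that observation literally and adds one refinement: the *potency* of that
most-similar ligand matters. If a query is equally similar to the best
ligand of target A and of target B, the target whose ligand is the more
potent binder is the better bet.

For a query compound $q$ and a target $t$ with curated ligand set
$L_t$, the package computes Tanimoto similarities over fingerprint on-bit
sets and extracts the nearest neighbour:

$$Tc_{most} = \max_{\ell \in L_t} Tc(q, \ell), \qquad
  pKi_{most} = pKi(\arg\max_{\ell} Tc(q, \ell)).$$

The pair $(Tc_{most}, pKi_{most})$ is the entire feature vector. A global
probabilistic classifier, trained on such pairs pooled across all targets,
returns the probability $p_a$ that the query is active on the target and its
complement $p_i = 1 - p_a$. For the logistic backend,

$$p_a = \frac{1}{1 + e^{-(a_0 + a_1 Tc_{most} + a_2\, pKi_{most})}}.$$

The query is called active when $p_a > p_i$; an exact tie is conservatively
called inactive. Crucially, $p_i$ behaves like a p-value for the hypothesis
"this target is not a target of the query", which turns multiple-target
scanning into a standard multiple-testing problem: raw $p_i$ values across a
scanned panel are corrected by Benjamini–Hochberg adjustment and Storey
q-values, and hits are ranked by adjusted p-value, then similarity, then
target id.

### Bioactivity representations

Two activity encodings are supported. *Explicit* mode feeds $pKi_{most}$
into the model as-is; *implicit* mode reduces it to the indicator
$\mathbf{1}[pKi_{most} \ge \tau]$ at the labelling threshold $\tau$. The two
modes share identical nearest-neighbour searches and differ only in feature
encoding, which the test suite verifies on shared folds. Explicit mode is
the default and the recommended configuration for scanning because its
p-values grade smoothly with neighbour potency, which is what makes p-value
thresholding an effective false-positive filter; the implicit encoding
collapses that gradient.

### Classifier backends

Three backends are available behind one `most_train()`/`predict()` surface:
logistic regression (`stats::glm`, binomial family), naive Bayes
(`e1071::naiveBayes`; Gaussian class-conditional densities per feature, a
choice forced by the features being continuous — the indicator feature in
implicit mode is modelled as Gaussian too, for uniformity), and random
forest (`randomForest`, 100 trees, default depth, probabilities as mean
leaf class frequencies, seeded from the model spec). The logistic backend
exposes its fitted $(a_0, a_1, a_2)$ and its predictions are the
closed-form sigmoid at machine precision. One *global* model is trained on
pairs pooled over all targets rather than per-target models: per-target
scan p-values must be comparable across targets to enter one FDR
correction, and a single calibrated map from $(Tc_{most}, pKi_{most})$ to
probability is what makes them comparable.

## Curation rules

Raw ChEMBL-style Ki tables are reduced to one measurement per
target–ligand pair:

1. Keep only records with activity type `Ki`, confidence score 9 (direct
   binding), a present positive value, a recognised concentration unit
   (pM/nM/uM/M, case-insensitive, micro-sign tolerant), a present
   reference, and relation `=`. The accepted-operator set is deliberately
   `{=}` only: `>`, `<` and `~` bound or approximate the value rather than
   state it, so they are treated as ambiguous and dropped.
2. Within one publication, the smallest Ki (highest pKi) survives,
   reflecting assay optimisation within a study.
3. Across publications, the arithmetic mean of the per-publication minima
   is taken on the Ki concentration scale and only then converted to
   pKi. Averaging on the concentration scale is the literal reading of
   "mean Ki"; a `mean_scale = "pKi"` switch provides geometric-mean
   averaging for sensitivity analyses.
4. Targets with fewer than 10 or more than 10,000 curated ligands are
   dropped; counts are taken after deduplication and before labelling.

Every rule increments a machine-readable audit counter so a curation run is
reproducible and auditable. Activity labels are `1` iff pKi ≥ τ with
τ ∈ {5, 6} — 10 µM and 1 µM operating points.

## Fingerprints

Both schemes are computed by OpenBabel through ChemmineOB: `morgan` is the
ECFP4 circular fingerprint (radius 2) in its native 4096-bit space, `fp2`
the path-based FP2 in 1024 bits. Inputs are canonicalised first, so
different SMILES spellings of one molecule map to one cached fingerprint.
The native 4096-bit space is kept as the Morgan default rather than
refolding to the 2048 bits common elsewhere: similarity search only needs a
consistent space, an extra fold would shift every Tanimoto value for no
accuracy gain, and a `fold` argument exposes shorter spaces (any divisor of
the native length) when compactness matters. Published Tanimoto values
computed with other toolkits' Morgan implementations may differ by a few
hundredths; this backend sensitivity is inherent to hashed fingerprints.
Similarity always operates on folded bit *sets* (not counts), so both
schemes share one Tanimoto code path. Two all-zero fingerprints are defined
as dissimilar (Tc = 0, logged): a featureless pair carries no evidence.
Nearest-neighbour ties on Tc break towards the higher pKi (the more useful
neighbour under the model), then lexicographic ligand id, making search
results independent of ligand order.

## Validation machinery

**Sevenfold cross-validation.** Each target's ligands are randomly
partitioned into 7 disjoint folds (≈14.3% test each); fold *i* tests on
fold *i* and trains on the rest, so the union of test sets covers the panel
exactly once. The described alternative — seven independent 15% draws — is
available as `split_mode = "resample15"`, but cannot guarantee full
coverage of the data, so the disjoint partition that honours the coverage
intent is the default. Training features are built leave-one-out (each
training ligand against the remaining training ligands of its target); test
ligands are matched against training ligands only. Metrics are pooled over
targets into per-fold confusion counts and summarised as mean ± standard
deviation over folds (the dispersion label is sd, not standard error).
Accuracy and the Matthews correlation coefficient are both reported; MCC is
the informative one under class imbalance, and a zero denominator factor
defines MCC = 0 by the usual convention.

**Temporal validation.** The entire old-release panel trains one model;
the test set is exactly the target–ligand pairs newly deposited in a later
release, restricted to targets present in both releases, each scored
against the old release's ligand set.

**Threshold trade-off curves.** For the positive calls of a run, the
fraction of true and of false positives retained while a threshold tightens
is computed on two axes: a Tc floor ($Tc_{most} \ge k$, grid 0–1 step 0.05)
and a p-value ceiling ($p \le t$, grid 0.5→0 step 0.025). The difference
$f_{TP} - f_{FP}$ is the trade-off index; its argmax is the operating point
keeping the most true positives per false positive removed. The package's
synthetic benchmark reproduces the qualitative finding that a p-value
ceiling in explicit mode removes false positives far more selectively than
a similarity floor.

**FDR control.** Benjamini–Hochberg adjustment is delegated to
`stats::p.adjust(method = "BH")` and cross-checked in the tests against a
brute-force step-up oracle. Storey q-values are computed as
$q_i = \hat\pi_0 \cdot \tilde p_i$ with the fixed-λ estimator
$\hat\pi_0 = \#\{p > \lambda\}/(m(1-\lambda))$ at λ = 0.5, capped at 1;
when every p-value falls below λ the estimator degenerates and the code
falls back to $\hat\pi_0 = 1$ (reducing q-values to BH) with a warning. The
fixed-λ form was chosen over the smoother variant because scanned panels
are typically a few hundred to a few thousand targets, where the smoother's
extra variance buys nothing. No Tc floor is applied before scanning by
default — filtering happens on the p-value scale — though `min_tc` exists.

## The synthetic study

All tests run offline on generated data. The generator emulates three
layers of the real pipeline's inputs:

**Raw tables.** `simulate_bioactivity_table()` plants same-publication
duplicates (resolved by the minimum rule), cross-publication duplicates
(resolved by the mean rule) and at least one record violating each
curation rule, and emits the curated table it expects back, making curation
golden-testable.

**Ligand panels.** `simulate_panel()` builds structures from one
combinatorial family: a benzene core with a target-specific ether/alkyl
tail, three near-duplicate active "seed" ligands per target (pKi uniform
in [6.5, 10], above both labelling thresholds) and decorated variants
carrying substituents chosen so that any two contribute nearly disjoint
fingerprint bits. Because nearest-neighbour identity depends only on
structure, the generator computes each ligand's realised within-target
nearest neighbour — using the scanner's own tie-break — and then assigns
variant activities by conditional resampling (Gibbs sweeps over the
nearest-neighbour dependency graph, iterated with the graph to a joint
fixed point) so that every variant's label follows the planted law
$P(\text{active}) = \sigma(a_0 + a_1 Tc_{most} + a_2 pKi_{most})$ given
its realised features. An active variant's pKi lands above the labelling
threshold, an inactive one's below. The expected accuracy of the
Bayes-optimal classifier is then computable: a variant is called correctly
with probability $\max(p, 1-p)$, a seed (deterministically active) iff its
$p > 0.5$. Cross-validated accuracy of the fitted model is compared against
this Bayes ceiling within binomial sampling error.

Default conditions: 50 targets × 20 ligands (1,000 pairs — sized so the
full benchmark, including fingerprinting, completes in about a minute on
one CPU while keeping the binomial sampling error on accuracy near one
percentage point), planted coefficients $(-15.5, 6, 2)$, labelling
threshold 6. The intercept was chosen so the panel is roughly 80% active
at pKi ≥ 6, matching the class balance of real curated Ki corpora, while
keeping both classes populous enough for a non-degenerate MCC.

**Feature data.** `simulate_feature_data()` draws
$Tc \sim U(0,1)$, $pKi$ from an equal N(5,1)/N(8,1) mixture, and labels
from the logistic law directly — the clean route for parameter-recovery
checks (the planted $(-10, 6, 1)$ is recovered within 10% at n = 10,000).

**What the synthetic study does not show.** The structure family is a
narrow homologous series; real ligand sets have multiple scaffolds,
stereochemistry, tautomers and charge states, none of which are exercised.
Similarities are computed with one backend, so numerical Tc values are not
transferable to other toolkits. The generator's activity law is exactly
the model family being fitted, so the benchmark measures correctness of
the machinery (feature extraction, folding, fitting, calibration), not the
adequacy of the logistic form for real pharmacology. Passing tests
therefore certify the implementation, not real-data accuracy; published
benchmark figures on full ChEMBL corpora (accuracy ≈ 0.95/0.87 at the two
thresholds in cross-validation) require those corpora and are directional
references only.

## Numerical and degenerate-input choices

- `p_a + p_i = 1` is enforced by construction (`p_i := 1 - p_a`); the
  invariant is asserted to 1e-12 in tests.
- Exact `p_a = p_i = 0.5` ties predict inactive (conservative).
- Training refuses single-class data rather than returning a degenerate
  model; implicit-mode models refuse raw pKi features at predict time.
- Cross-validation skips (with a warning) test ligands whose target has an
  empty training split in a fold; temporal validation likewise skips new
  pairs on targets absent from the old release.
- No feature scaling is applied: both features are bounded/low-range and
  unscaled coefficients remain interpretable against the sigmoid form.
- All randomness flows from explicit integer seeds; rerunning any
  generator, split, fit or scan with the same seed is bit-identical.

## Reproducing the numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` regenerates
the synthetic study from scratch — planted-law recovery, the 50-target
cross-validation against its Bayes ceiling, the p ≤ 0.1 trade-off
fractions, and the null-panel FDR call rate — and writes them as JSON.
The README shows one worked run with the numbers it printed.
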