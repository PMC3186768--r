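---
title: "Classifying P-glycoprotein substrates from topological descriptors"
author: "pgpsub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying P-glycoprotein substrates from topological descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgpsub)
```

## The problem

P-glycoprotein (P-gp) is an ATP-driven efflux transporter that pumps a wide
range of structurally diverse drugs out of cells. Whether a compound is a
P-gp **substrate** (class 1) or a **non-substrate** (class 0) shapes its
oral absorption, brain penetration and clearance, so an *in silico*
classifier is useful long before transport assays are run. `pgpsub`
implements a complete binary-classification pipeline for this problem:
2D (topological) molecular descriptors computed from the bonding graph
alone, F-score-driven feature selection, and a grid-searched RBF-kernel
support vector machine evaluated by a repeated-split protocol with a
diversity-selected external validation set.

## Molecular graphs

All descriptors are computed on the **hydrogen-suppressed molecular
graph**: atoms are vertices labelled with an element symbol, bonds are
edges labelled single/double/triple/aromatic. Choices a user should know
about:

* **Hydrogen suppression.** Explicit hydrogens are removed at parse time.
  The implemented descriptor families are defined on the heavy-atom graph,
  and reference descriptor software operates on H-depleted graphs by
  default.
* **Aromaticity is taken from the input** — lowercase SMILES atoms or MOL
  V2000 bond type 4 — and never re-perceived. An aromatic bond has
  conventional order 1.5. This is why SMILES are parsed by the package's
  own reader rather than routed through a converter that kekulizes rings.
* **Salts and mixtures.** Only the fragment with the most heavy atoms is
  kept (`[Na+].CC(=O)[O-]` keeps the acetate): substrate classification
  concerns the parent drug, not the counter-ion. The data the pipeline was
  developed against does not state how salts were handled; this is the
  package's own, recorded policy.
* **Stereochemistry and formal charge** are parsed and carried but ignored
  by every descriptor: topological descriptors are constitution-only, so
  no 3D geometry is ever generated or optimized.
* Element coverage is defined by the packaged property table (H, C, N, O,
  F, P, S, Cl, Br, I); any other element is a hard parse error rather than
  a silent zero.

## The descriptor families

The pipeline's default descriptor block is the six-descriptor set of the
final substrate-classification model: `ATS1m`, `EEig12x`, `ESpm02d`,
`BELv6`, `BELe6`, `BELp6`. Each belongs to a generalized family the
package implements in full.

**Broto–Moreau autocorrelation (`ATS<lag><w>`).** With carbon-scaled
atomic weights $w_i = p(\text{element}_i)/p(\text{C})$ for property $p$,

$$\mathrm{ATS}_k = \sum_{\{i,j\}:\, d_{ij} = k} w_i\, w_j,$$

summing over unordered atom pairs at topological distance exactly $k$
(shortest path in bonds). `ATS1m` is the lag-1, mass-weighted member: a
size-and-composition signal concentrated on bonded pairs.

**Burden eigenvalues (`BEL<n><w>`, `BEH<n><w>`).** The Burden matrix has
the carbon-scaled weights on the diagonal and, for bonded pairs, $0.1 b$
off-diagonal ($b$ the conventional bond order, 1.5 for aromatic) with
$+0.01$ added when either atom is terminal; all non-bonded pairs get
$0.001$. `BEL`$n$ is the $n$-th smallest eigenvalue, `BEH`$n$ the $n$-th
largest. The weighting properties are van der Waals volume (`v`),
Sanderson electronegativity (`e`), polarizability (`p`) and mass (`m`).
The descriptor list that motivated this package glosses `BELp6` as a
"highest" eigenvalue even though the `BEL` prefix conventionally denotes
the lowest series; `pgpsub` implements `BELp6` as the 6th-*lowest*
eigenvalue, consistent with `BELv6`/`BELe6` in the same list, and treats
the gloss as a typographical slip.

**Edge-adjacency descriptors (`EEig<n><w>`, `ESpm<k><w>`).** The edge
adjacency matrix is bonds-by-bonds, with 1 where two bonds share an atom
and a bond weight on the diagonal: the *edge degree* (number of adjacent
bonds, code `x`) or the *bond dipole moment* (code `d`) from a small
packaged table of standard group moments. `EEig`$n$ is the $n$-th largest
eigenvalue; `ESpm`$k$ is the spectral moment $\mathrm{tr}(E^k)$.

**Padding policy.** A molecule with fewer than $n$ atoms (or bonds) cannot
supply eigenvalue $n$; those descriptors return 0 with an explicit pad
flag instead of failing, because real training sets contain small
molecules and the pipeline must carry them. Pad flags travel with every
descriptor matrix so downstream users can filter on them.

**What is deliberately out of scope.** Only these families are
implemented — not the thousands of descriptors of a full commercial
package — and no numeric parity with any proprietary implementation is
claimed: correctness is defined by the package's hand-computed oracles
(2×2 analytic eigendecompositions, trace identities, permutation
invariance), which the test suite checks to 1e-9.

## Property tables

Atomic masses (IUPAC standard atomic weights), Sanderson
electronegativities, static polarizabilities (CRC) and Bondi-radius van
der Waals volumes ship as a versioned plain-text table
(`inst/extdata/atom_properties.tsv`); bond dipole moments for common
heavy-atom bond types come from standard group-moment compilations
(`inst/extdata/bond_dipoles.tsv`). Both are user-overridable through the
`properties`/`dipoles` arguments. Dipole lookup is symmetric in the
element pair, homonuclear bonds are 0 by definition, and a missing
(pair, order) entry falls back to the pair's single-bond value.

## Dataset construction

`load_dataset()` reads a delimited compound table (id, name, smiles,
class, source) and enforces unique ids and \{0, 1\} labels. The packaged
table (`packaged_compound_table()`) is a **synthetic stand-in** with the
study's composition — 197 compounds, 99 substrates, 98 non-substrates —
generated by `synthetic_compound_table()`: substrates are drawn larger
(longer hetero-chains, more frequent aromatic rings) than non-substrates,
so the classes genuinely differ in descriptor space. It exists to exercise
every pipeline path with real chemistry-shaped input; it is not a
literature compilation, and no claim about real P-gp biology rests on it.

**External validation set.** Model assessment needs compounds never seen
by any selection or tuning step. `build_external_set()` z-scores each
descriptor over the whole dataset, computes pairwise molecular similarity
as the Pearson correlation of the standardized descriptor profiles,
clusters each class into 16 groups and samples one compound per group,
yielding a 16 + 16 external set. The grouping algorithm is
average-linkage agglomerative clustering on distance $1 - r$: the source
procedure says only that descriptor space was "divided" into subsets, so
the package picks a deterministic, standard method and records it in the
split manifest. Standardization before correlating is the package's
choice too — raw descriptor scales differ by orders of magnitude and
would otherwise dominate the profile correlation. The clustering runs on
the post-filter descriptor matrix (after `filter_low_information()`),
since similarity over near-constant columns is noise.

**Train/test splits** are stratified by class (largest-remainder
allocation), so a 165-compound pool at the default 0.8 ratio always gives
a 33-compound test set with both classes represented. Stratification is a
package decision: the protocol's near-equal sensitivity and specificity
imply balanced class exposure.

## Feature selection

1. **Low-information filter.** Descriptors with more than 80% zero values
   are dropped, as are descriptors with "too small" standard deviation.
   The package reads the latter as a coefficient of variation below 0.03
   (sd relative to mean absolute value), with constant columns always
   dropped; the threshold's baseline is genuinely ambiguous, so the rule
   and every dropped column are written to an auditable drop log.
2. **F-score ranking.** For feature $x$ with class means
   $\bar x^{+}, \bar x^{-}$ and overall mean $\bar x$:
   $$F = \frac{(\bar x^{+} - \bar x)^2 + (\bar x^{-} - \bar x)^2}
   {\tfrac{1}{n^+ - 1}\sum (x_k^{+} - \bar x^{+})^2 +
    \tfrac{1}{n^- - 1}\sum (x_k^{-} - \bar x^{-})^2}.$$
   $F$ is invariant under affine rescaling of the feature; a zero
   denominator with separated means returns `Inf`.
3. **Correlation pruning.** Scanning in descending $F$, a feature is
   dropped when $|r| > 0.9$ against any already-kept feature — among
   correlated descriptors the higher-F one survives. The scan order is
   the package's choice; the source rule states only which member of a
   correlated pair is kept.
4. **Incremental forward selection.** Features are added in rank order;
   each prefix is scored by stratified k-fold cross-validated SVM
   accuracy, and the scan stops the first time accuracy falls below the
   running best. The best prefix wins; ties go to fewer features. Two
   numerical choices matter here: the fold assignment is *fixed across
   prefix sizes*, so consecutive accuracies differ only through the added
   feature, not through resampling noise; and the scan runs at fixed
   kernel parameters (`select_C`, `select_gamma`, default $C = 1$,
   $\gamma = 1/p$) with the full grid search applied once to the selected
   set — tuning the grid inside every prefix would multiply cost without
   changing which features carry signal. Whether the original procedure
   validated on a fixed held-out set or by cross-validation is ambiguous;
   cross-validation on the training part is used because it exposes no
   extra data to selection.

## The SVM protocol

The classifier is a soft-margin SVM with the Gaussian RBF kernel
$K(u, v) = \exp(-\gamma \lVert u - v \rVert^2)$, trained by libsvm (via
`e1071`) on z-scored features; the scaler is fitted on training data only
and reapplied verbatim everywhere else. $(C, \gamma)$ are chosen by
exhaustive grid search over exponentially growing sequences — defaults
$C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$,
$\gamma \in \{2^{-15}, \ldots, 2^{3}\}$, the canonical libsvm grids —
scored by seeded stratified k-fold cross-validation (default 5 folds; the
source protocol never states its fold count). Ties break toward smaller
$C$, then smaller $\gamma$: the least-flexible model among equals.

`run_protocol()` repeats the whole downstream pipeline `n_runs` times
(default 100): fresh stratified 0.8/0.2 split of the training pool,
feature selection on the 0.8 part, grid search, refit, evaluation on
training, test and external sets. Feature selection is repeated inside
every run — the stated pipeline order implies it — with a `features`
argument to pin a fixed set instead. All randomness flows from one master
seed through named streams (`derive_seed()`), so a protocol result is
bit-for-bit reproducible.

A trained model serializes to a plain-text JSON container (feature names,
scaler, $C$, $\gamma$, support vectors, dual coefficients, bias);
prediction is computed from that container directly through the package's
own kernel, so a stored model does not depend on solver internals — and
the round trip is itself a test that the decision function matches
libsvm's.

**Final-model rule.** `select_final_model()` filters candidates to those
with a training–test accuracy gap strictly below 5 percentage points (an
overfitting guard), then picks the fewest-descriptor candidate, breaking
ties by highest external-set MCC. When nothing survives the gap filter it
errors rather than silently relaxing the threshold.

## Evaluation conventions

`classification_metrics()` reports ACC, SE, SP as percentages (full
precision internally, rounding only at report time) and the Matthews
correlation coefficient
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$
which equals the Pearson correlation (phi coefficient) of the binary
label vectors — the test suite asserts that identity to 1e-12 on random
confusion matrices. A zero factor in the denominator yields MCC = 0
(standard convention); SE or SP with an empty denominator is `NA`, never
a silent 0 or 100.

## The synthetic generator, and what passing tests mean

`synthetic_feature_dataset()` draws two Gaussian classes: informative
features differ in mean by `separation` within-class standard deviations,
noise features are shared N(0, 1), and optional near-duplicate columns
(r > 0.95) exercise the correlation pruning. This is the simplest
structure under which F-score ranking and RBF-SVM accuracy have known
expectations, which is exactly why it is the benchmark: at separation
$3\sigma$ on two planted features the protocol should recover those
features and classify test sets almost perfectly, and at separation 0 it
should sit at chance. The benchmark problem sizes used by the tests and
the acceptance script are 99 + 98 compounds (the study shape), 2 planted
and 10 noise features, 100 protocol runs per dataset over 20 (tests) or
10 (script) dataset seeds for the separable case and 3 for the null, with
a deliberately coarse grid ($C \in 2^{\{-1,1,3,5\}}$,
$\gamma \in 2^{\{-7,-5,-3,-1\}}$, 3 folds) that spans the regime where
these datasets are separable without spending time on grid cells no
synthetic dataset needs.

What the generator does **not** emulate: real descriptor distributions
(heavy tails, discreteness, pad-induced zero inflation), label noise from
contradictory assays, and covariance structure between descriptor
families. Passing the synthetic benchmarks therefore demonstrates that
the machinery — selection, tuning, splitting, evaluation — behaves as
specified, not that any particular accuracy will be achieved on a real
substrate dataset; headline accuracies on curated literature compounds
additionally depend on descriptor values and labels this package does not
vendor.

## Known limitations

* SMILES support covers the organic subset plus bracket atoms, rings,
  branches and charges — sufficient for drug-like molecules over the
  supported elements, but not full OpenSMILES (no isotopic descriptors
  beyond parsing, no extended stereo).
* Bond dipole values are a compact standard table, not a fitted model;
  dipole-weighted descriptors inherit its granularity.
* `EEig12x` pads to 0 for molecules with fewer than 12 bonds, which makes
  it uninformative below that size — visible in the packaged table, where
  about half the small synthetic compounds pad it.
* The external-set clustering is one reasonable reading of a
  one-sentence description; other clusterings would select different but
  equally defensible external compounds. The split manifest records the
  method so results remain auditable.
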