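---
title: "Estimating AAindex properties for non-canonical amino acids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating AAindex properties for non-canonical amino acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncaaprop)
```

## The problem and the model

The AAindex database assigns each of its physicochemical property scales
one value per canonical amino acid -- and only per canonical amino acid.
Proteins in the PDB, however, contain over a thousand distinct
non-canonical amino acids (ncAAs): hydroxyproline in collagen,
methylated and acetylated lysines, chromophore-forming residues, and
many more. Any pipeline that uses AAindex scales as features is blind
to them.

`ncaaprop` estimates an arbitrary AAindex scale for an arbitrary ncAA
from nothing but its SMILES string. The idea is that a property value
can be approximated as a linear function of coarse chemical composition.
Each amino acid is described by 13 integer descriptors counted directly
from its SMILES text (`component_keys()`): double-bonded oxygen, any
oxygen, non-aromatic and aromatic nitrogen, double-bonded nitrogen,
non-aromatic and aromatic carbon, chiral carbon, sulfur, first and
second ring closures, any double bond, and positive charge. For a
property with values $y_1,\dots,y_{20}$ over the canonical amino acids
and count vectors $x_i \in \mathbb{Z}^{13}_{\ge 0}$, the model is

$$ y_i = c + \sum_{k \in S} b_k\, x_{ik} + \varepsilon_i, $$

where the retained predictor set $S$ is chosen by F-gated stepwise
regression. A prediction for an ncAA is the same linear form evaluated
on its count vector, reported as value $\pm$ RMSE.

With only 20 training rows and 13 candidate predictors, overfitting is
the central danger; everything below is shaped by it.

## Counting semantics

Counting is *literal and case-sensitive over the raw SMILES string*,
not over a perceived molecular graph. This is deliberate: the method is
defined on the strings as distributed, and a canonicalizing parser
would silently change the features. The exact rules:

* Single-character components (`O`, `N`, `n`, `C`, `c`, `S`, `=`, `+`)
  count occurrences of that character, including inside bracket atoms
  (`[C@H]` contributes to `C`; `[N+]` contributes to `N` and `+`).
  Characters belonging to a two-letter element symbol never count
  toward a one-letter component: the tokenizer knows that `Cl` is
  chlorine, not carbon, and `[Se]` is selenium, not sulfur. Such
  elements are outside the modeling domain anyway (see below), but the
  distinction is enforced regardless.
* Two-character components: `dblO` counts `=O` plus `O=`; `dblN`
  counts `=N`, `N=` and `=[N`; `chiralC` counts `[C@`.
* Ring components count an atom letter in {`c`,`C`,`n`,`N`,`S`}
  *immediately followed* by the closure digit `1` (`ring1`) or `2`
  (`ring2`). Bracket placement therefore matters: in
  `O[C@H]1CN[C@@H](C1)C(O)=O` (4-hydroxyproline) the first closure
  digit follows `]` and does not count, so `ring1 = 1` -- exactly the
  published predictor value for this worked example. The flip side of
  the literal rule is that a ring like `C1CCCC1` counts 2, because both
  closure digits follow atom letters. Closure digits of 3 and above
  carry no component; their presence is recorded in the `deep_rings`
  attribute.
* Components deliberately overlap: every `=O` also counts toward `O`
  and toward `=`; every chiral carbon also counts toward `C`. The
  worked example's counts confirm both overlaps.

One consequence worth stating plainly: every isomeric SMILES of alanine
contains three `C` characters (methyl, chiral alpha carbon, carboxyl),
so its carbon count is 3 under these rules -- the bracketed chiral
carbon counts, exactly as it does in the 4-hydroxyproline reference
vector where `C = 5` includes both bracketed stereocenters.

The tokenizer validates the string first (balanced brackets and
parentheses, no dangling bond, every ring-closure digit appearing an
even number of times) and reports the offending position. An empty
string is an error, not an all-zero vector.

### The element-domain filter

The training set contains only C, H, N, O and S. An ncAA containing
As, B, Br, Cl, F, I, P or Se (`excluded_elements()`) is outside the
model's domain: no coefficient in the model has seen such an atom.
`build_database()` applies this filter before predicting and lists the
excluded entries with their offending elements. Matching is by parsed
element symbol, never raw substring, so `CCl` is excluded for chlorine
without implicating carbon.

## The regression core

`ols_fit()` fits ordinary least squares with an intercept and reports,
per predictor, the coefficient $b_k$, its standard deviation $SD_k$
(standard error with residual variance $\mathrm{sse}/(n - p - 1)$), and
the statistic

$$ F_k = (b_k / SD_k)^2, $$

the squared t statistic, which gates both entry and stay. The intercept
is always present and never gated. When the residual sum of squares
falls below the perfect-fit tolerance ($\mathrm{sse}/n \le 10^{-12}
\cdot \mathrm{var}(y)$), the standard deviations lose meaning -- a
property that is an exact linear function of the counts, such as a
positive-charge scale matched by the `+` column, has $SD = 0$ and an
undefined statistic. The fit is then flagged `perfect_fit` and all F
values are reported as `Inf`, so a perfectly predictive model survives
any gate.

`stepwise_select()` searches for a *fixpoint*: a predictor subset
whose joint refit leaves every retained F at or above the threshold.
The search is forward inclusion (the candidate with the greatest
residual-sum-of-squares reduction is tried first, ties broken by
component order) interleaved with backward elimination (repeatedly
dropping the lowest-F predictor while any F is below the threshold),
iterated until no accepted step remains. Two refinements matter in
practice:

* Predictors can be jointly significant while individually failing the
  gate, which a purely forward path never discovers. A second route
  runs backward elimination from the full feasible candidate set, and
  the lower-sse fixpoint of the two routes is returned. On fixtures
  small enough to enumerate, the result matches an exhaustive search
  over all predictor subsets for the best-sse subset satisfying the
  all-F condition (this equivalence is asserted in the test suite).
* A perfect fit defeats F-based elimination (every F is infinite), so
  perfect fits are pruned to a minimal subset that retains zero
  residual. Without this, a numerically-zero coefficient could ride
  along protected by its infinite F.

Zero-variance columns are removed from candidacy per fit -- including
independently inside each cross-validation fold, where a column can
lose its variance when its only carrier is held out. If nothing
survives, the constant-only model (the training mean) is returned.
Rank-deficient candidate subsets are reported with the collinear
columns named.

## Cross-validation and the threshold

The F threshold is a model-complexity knob, and it is chosen by
leave-one-out cross-validation (`loo_predict()`,
`optimize_threshold()`): for each row $i$, a model is selected and fit
on the other 19 rows at the candidate threshold and applied to row
$i$; the quality of a threshold is the Pearson correlation $r_{j\text{-}n}$
between the 20 held-out predictions and the actual values.

* **Grid.** The default grid is 0.5 to 12 in steps of 0.1
  (`default_f_grid()`), configurable. Useful thresholds for n = 20 sit
  in the low single digits (an F of 4 corresponds to |t| = 2); the grid
  brackets that region generously on both sides.
* **Tie-break.** Ties in $r_{j\text{-}n}$ (within $10^{-9}$, an
  equality tolerance for floating point) go to the *largest* threshold,
  i.e. the sparsest model.
* **RMSE.** The reported RMSE is computed from the LOO prediction
  vector at the chosen threshold, not from in-sample residuals, and it
  is the $\pm$ attached to every ncAA prediction. In-sample residuals
  under-state prediction error badly here (13 candidate predictors for
  20 points); the LOO definition is the conservative choice, and the
  model store records `rmse_definition` so downstream consumers know
  which convention they are reading. The in-sample correlation is
  reported alongside as `r_insample`.
* **Degenerate cases.** For perfect-fit properties the threshold is
  reported as `NA` and the RMSE as 0 -- the gate plays no role. When a
  property has missing values, the masked amino acids are dropped from
  training *for that property only* ($n < 20$; the model records
  `n_used`), rather than discarding the whole property.
* **A known artifact.** If no fold retains any predictor, every fold
  predicts the training mean of the other 19 values, which is a
  *decreasing* linear function of the held-out value; $r_{j\text{-}n}$
  then collapses to exactly $-1$. This is a property of leave-one-out
  evaluation itself, not of the models. It is harmless for threshold
  selection (it makes empty models maximally unattractive), but
  $r_{j\text{-}n}$ of a near-useless model should not be read as a
  meaningful magnitude.

## The synthetic-property generator

Real AAindex values cannot be bundled, so validation rests on
synthetic properties with known structure (`synthetic_spec()`,
`generate_property()`): $y = X_S\beta + c + N(0, \sigma)$ over the
canonical design matrix, seeded and reproducible. The generator
emulates what the model assumes a property is -- a sparse linear
function of composition counts with coefficient magnitudes like those
of real normalized scales (a few tenths to ~1) and Gaussian noise of
sd 0 to 0.3. It does *not* emulate inter-property correlation
structure, heavy-tailed measurement error, or properties that are
genuinely nonlinear in composition; passing recovery tests therefore
demonstrates correctness of the machinery, not real-data accuracy.

The canonical design itself constrains what is testable. It has 20
rows, and among its 13 columns there are *exact* linear dependencies
-- for instance, every double bond in a canonical amino acid is a
double bond to O or to N, so the any-double-bond column equals the sum
of those two. A signal placed on an aliased column has multiple
perfect representations, and no algorithm could recover "the" support.
`well_conditioned_supports()` therefore enumerates supports that (a)
avoid all columns involved in exact dependencies and (b) have a
submatrix condition number below 100; recovery fixtures draw from this
set so that a failure indicates a bug, not aliasing. On these
fixtures, noiseless properties are recovered exactly (support,
coefficients to $10^{-8}$, $r_{j\text{-}n} = 1$), and median support
recovery degrades monotonically as the noise sd rises through 0.1 and
0.3.

Validation problem sizes: oracle-equivalence checks run 50 seeded OLS
fixtures, exhaustive-subset comparisons on up to all 13 candidate
columns, independent LOO re-implementation on 20 seeded properties,
and recovery sweeps of 100 seeded properties per noise level.

## The bundled canonical SMILES table

Training requires the 20 canonical amino acids as SMILES in a fixed
dialect. The bundled table (`canonical_aa_table()`) is written in the
PDB chemical-component-dictionary isomeric dialect -- side chains and
the `C(O)=O` carboxyl written as in dictionary entries, arginine and
histidine in their +1 protonation -- and was validated chemically
(molecular formula, net charge, and CIP stereodescriptors: all-S alpha
carbons except the R cysteine, 2S,3R threonine, 2S,3S isoleucine).

Because the featurizer is literal, counts depend on the dialect:
ring-digit placement relative to brackets and protonation states change
component values. Models trained on a differently written canonical
table are therefore *not* interchangeable with models trained on this
one. In particular, in this dialect the ten predictors of the reference
EISD840101 model (consensus normalized hydrophobicity) satisfy an exact
linear dependency, so that coefficient set cannot be re-derived from
this design; it is shipped as a frozen reference fixture
(`eisd840101_published_model()`) and used for the worked
4-hydroxyproline example, which is dialect-independent arithmetic:
featurize, dot product, constant.

All bundled files are checksum-pinned; a silently edited fixture is a
load-time error.

## A worked run

```{r example}
# featurize 4-hydroxyproline and predict its consensus hydrophobicity
cv <- count_components("O[C@H]1CN[C@@H](C1)C(O)=O")
cv
m <- eisd840101_published_model()
predict_with_error(m, cv)   # -0.343 +/- 0.282 after display rounding

# train models on the bundled synthetic AAindex demo records
recs <- parse_aaindex1(synthetic_aaindex_path())
models <- train_models(recs, canonical_aa_table(), grid = default_f_grid(1, 8, 0.5))
model_summary(models)

# predict all three properties for the 25 frequent PDB ncAAs
db <- build_database(models, ncaa_frequent_table())
head(db$long)
```

## Limitations

* A linear model in 13 coarse counts cannot represent positional or
  electronic effects; properties that are not approximately
  compositional will predict poorly regardless of the machinery, and
  the per-property $r_{j\text{-}n}$ is the honest signal of that.
* $n = 20$ is immutable: standard errors are wide, the stepwise path
  is variance-prone, and the LOO estimate itself is noisy.
* Predictions are only defined inside the element domain of the
  training set; the filter refuses the rest rather than extrapolating.
* The literal counting rule ties models to a SMILES dialect; mixing
  dialects between training and prediction is silently wrong, which is
  why the bundled tables are fixed and checksummed.
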