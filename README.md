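# ncaaprop

Estimating AAindex physicochemical properties for non-canonical amino
acids (ncAAs) from SMILES strings.

The AAindex database assigns each property scale one value per
*canonical* amino acid, yet PDB structures contain more than a thousand
distinct non-canonical residues (hydroxyproline, methylated lysines,
chromophores, ...). `ncaaprop` fills that gap for researchers who use
AAindex scales as features in protein structure, function or
interaction models: it trains, per property, a linear model on 13
integer SMILES substring-count descriptors of the 20 canonical amino
acids, and evaluates that model on any ncAA's SMILES.

## The method

For a property with canonical values $y_1,\dots,y_{20}$ and per-residue
component counts $x_i \in \mathbb{Z}^{13}_{\ge 0}$ (oxygen, nitrogen,
carbon, chirality, sulfur, ring, double-bond and charge counts taken
literally from the SMILES text):

* **Model.** $y_i = c + \sum_{k \in S} b_k x_{ik} + \varepsilon_i$,
  fit by ordinary least squares.
* **Selection.** A predictor stays in $S$ only if its statistic
  $F_k = (b_k/SD_k)^2$ (squared t) is at or above a threshold;
  stepwise search runs to a fixpoint of that rule.
* **Threshold choice.** The F threshold is picked by leave-one-out
  cross-validation over a grid: the quality of a threshold is
  $r_{j\text{-}n}$, the Pearson correlation between held-out
  predictions and actual values; ties go to the sparsest model.
* **Uncertainty.** The RMSE of the LOO predictions at the chosen
  threshold is attached to every ncAA prediction as its $\pm$.
* **Domain.** ncAAs containing As, B, Br, Cl, F, I, P or Se are
  refused: those elements never occur in the training set.

See the vignette (`vignettes/ncaa-property-models.Rmd`) for the full
counting semantics, numerical choices, and validation design.

## Worked example

Featurize 4-hydroxyproline and predict its consensus normalized
hydrophobicity (EISD840101) with the bundled reference model:

```r
library(ncaaprop)
cv <- count_components("O[C@H]1CN[C@@H](C1)C(O)=O")
cv
#>    dblO    anyO  aliphN   aromN    dblN  aliphC   aromC chiralC       S   ring1
#>       1       3       1       0       0       5       0       2       0       1
#>   ring2     dbl    plus
#>       0       1       0
predict_with_error(eisd840101_published_model(), cv)
#>    value     rmse
#> -0.34293  0.28200
```

The value is $(-0.563688)\times 3 + (-0.556289)\times 1 + 0.11307
\times 5 + (-0.290756)\times 1 + 1.629829 = -0.34293$, i.e.
$-0.343 \pm 0.282$ after display rounding — hydroxyproline is
predicted markedly more hydrophilic than proline's tabulated $-0.07$.

Train models end to end on the bundled synthetic AAindex demo records
and build a prediction database over the 25 most frequent PDB ncAAs:

```r
recs <- parse_aaindex1(synthetic_aaindex_path())
models <- train_models(recs, canonical_aa_table(),
                       grid = default_f_grid(1, 8, 0.5))
model_summary(models)
#>    accession      r_jn       RMSE F_star P_num n_used
#> 1 SYNH000101 0.9851168 0.09250835    1.5     4     20
#> 2 SYNP000102 0.9618036 0.18285686    2.0     6     20
#> 3 SYNR000103 1.0000000 0.00000000     NA     1     20

db <- build_database(models, ncaa_frequent_table())
db
#> <ncaa_database> 25 record(s): 25 kept, 0 excluded, 0 failed
#>   75 prediction row(s) over 3 properties
head(db$long, 3)
#>   code  accession     value       rmse      r_jn
#> 1  MLY SYNH000101 1.2242580 0.09250835 0.9851168
#> 2  MLY SYNP000102 1.3947885 0.18285686 0.9618036
#> 3  MLY SYNR000103 0.1000000 0.00000000 1.0000000
```

`r_jn` is each model's LOO correlation (its reliability), `rmse` the
uncertainty attached to each predicted value, `F_star` the chosen
threshold (`NA` for an exactly fitting property, where the gate plays
no role), and `P_num` the number of retained predictors. To train on
the real AAindex, pass a downloaded AAindex1 flat file to
`parse_aaindex1()` (or to the `train` subcommand of
`inst/scripts/ncaaprop`).

## Command line

`inst/scripts/ncaaprop` is a thin Rscript front end:

```sh
ncaaprop featurize --smiles 'O[C@H]1CN[C@@H](C1)C(O)=O'
ncaaprop train --aaindex aaindex1 --out models.json --summary summary.tsv
ncaaprop predict --models models.json --table ncaa.tsv --out predictions.tsv
ncaaprop selftest
```
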