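# combosens

Dose-specific prediction of drug-combination sensitivity in cancer cell
lines — and everything you can rebuild from such predictions: dose-response
curves and matrices, IC levels, CMax viabilities, and per-cell-line
treatment rankings.

## The problem

Machine-learning work on drug-combination screens mostly predicts *synergy
scores*. Synergy measures whether two drugs beat the expectation from their
monotherapies — not whether the combination is effective, which is what a
personalized treatment recommendation needs. `combosens` instead trains
models that predict the **relative inhibition** of a cell line treated with
one or two drugs *at explicit concentrations*, and evaluates them
**cell-blind**: training and test cell-line sets are disjoint, mimicking
prediction for a new patient.

Because the model output is dose-specific, standard pharmacology is
recoverable from predictions alone:

- **Dose-response curves** (monotherapies) via the three-parameter logistic

  `f(x) = c + (1 − c) / (1 + exp(b · (log x − log e)))`

  with upper asymptote 1, lower asymptote `c ∈ [0, 1]`, slope `b > 0` and
  inflection concentration `e` (µM). Fits need ≥ 5 dose-response points and
  are discarded above the conventional quality gate RMSE > 0.3.
- **IC50 / IC75 / IC90**: where the curve crosses viability 0.5 / 0.75 /
  0.90, inverted in closed form.
- **CMax viability**: the curve evaluated at the drug's CMax (peak plasma
  concentration at the highest clinically recommended dose) — comparable
  across drugs because the reference concentration is clinically anchored.
- **Combination CMax viability**: the minimum bilinearly interpolated
  viability over the box `[0, CMax_A] × [0, CMax_B]` of a dose-response
  matrix, on a 100 × 100 concentration lattice. Taking the box minimum
  (not the corner value) captures synergy windows below the CMax doses.
- **Treatment prioritization**: treatments ranked per cell line from
  smallest to largest (combination) CMax viability, scored against the
  actual ranking by Spearman correlation, top-k overlap, best-treatment
  ranks, and the achieved viability gap.

Inputs follow the conventions of public combination-screen resources: a
six-column screen table `(cell_line, drug_row, drug_col, conc_row,
conc_col, inhibition)` with inhibitions in [−200, 200], a genes × cell
lines expression matrix, drug feature tables (binary fingerprints, numeric
physico-chemical descriptors, drug→target mappings), and a per-drug CMax
table. Four drug/concentration encodings are provided (one-hot
concentration, one-hot + target counts, fingerprint blocks, descriptor
blocks); the order-dependent encodings duplicate each combination entry in
both drug orders so predictions become order-robust. A synthetic screen
generator with full ground truth makes the entire pipeline testable
without downloading anything.

## Worked example

```r
library(combosens)
library(dplyr)

world <- generate_world(synthetic_world_config(
  n_cells = 16, n_drugs = 7, n_combinations = 10, replicates = 2, seed = 42))

replicate_noise_summary(world$screen)
#> # A tibble: 1 × 3
#>   mean_sd median_sd n_replicated_keys
#>     <dbl>     <dbl>             <int>
#> 1    5.66      4.84              4560

screen <- preprocess_screen(world$screen,
                            cells_with_expression = colnames(world$expression),
                            drug_min_entries = 1)
split <- make_split(screen, split_spec("cell_blind", test_fraction = 0.2, seed = 42))
split
#> Screen split (cell_blind): 3705 train / 855 test entries

cell_model <- fit_cell_features(world$expression, split$train_cells, n_components = 8)
enc <- drug_encoding_config("maccs", fingerprints = world$fingerprints)
train <- build_dataset(split$train, cell_model, enc, world$expression, duplicate = TRUE)
test  <- build_dataset(split$test,  cell_model, enc, world$expression, duplicate = TRUE)

forest <- regressor_spec("random_forest",
                         grid = list(num_trees = 300, mtry_frac = NA, min_node_size = 5))
pred <- fit_predict(forest, train, test, seed = 42)
baseline <- fit_predict(regressor_spec("mean_baseline"), train, test)
round(c(forest_mae = mean(abs(pred - test$y)),
        mean_baseline_mae = mean(abs(baseline - test$y))), 2)
#>        forest_mae mean_baseline_mae
#>             11.83             22.44
```

The forest roughly halves the error of the always-predict-the-mean
baseline on unseen cell lines. Overall correlations are inflated by
between-drug mean differences, so per-drug correlations are the honest
metric:

```r
errs <- tibble::tibble(actual = test$y, predicted = pred,
                       drug_row = test$provenance$drug_row,
                       drug_col = test$provenance$drug_col)
glance(summarize_errors(errs, "per_drug"))
#> # A tibble: 1 × 9
#>   overall_n overall_mae overall_pcc overall_r2 mean_mae mean_pcc mean_r2
#>       <int>       <dbl>       <dbl>      <dbl>    <dbl>    <dbl>   <dbl>
#> 1       105        14.4       0.892      0.712     14.4    0.897   0.706
```

Sensitivity measures and a per-cell-line ranking, from the
replicate-averaged screen on the raw micromolar scale:

```r
raw <- preprocess_screen(world$screen, drug_min_entries = 1, log1p_concs = FALSE)
measures <- reconstruct_measures(raw, world$cmax)
measures |> filter(cell_line == "CL001", measure == "cmax_viability") |> head(3)
#>   cell_line treatment type  measure        value flag
#> 1 CL001     DRUG01    mono  cmax_viability 0.324 <NA>
#> 2 CL001     DRUG02    mono  cmax_viability 0.357 <NA>
#> 3 CL001     DRUG03    mono  cmax_viability 0.273 <NA>

ranking <- build_ranking(
  measures |> filter(cell_line == "CL001",
                     measure %in% c("cmax_viability", "combination_cmax_viability")),
  scope = "mono_plus_combo")
head(tibble::as_tibble(ranking), 5)
#>   treatment       type        viability  rank
#> 1 DRUG02 + DRUG07 combination    0.0174     1
#> 2 DRUG04 + DRUG06 combination    0.0300     2
#> 3 DRUG01 + DRUG06 combination    0.0362     3
#> 4 DRUG01 + DRUG04 combination    0.0547     4
#> 5 DRUG01 + DRUG07 combination    0.0570     5
```

The ranking reads top-down as the recommendation list for that cell line:
smaller CMax viability means a stronger effect achievable at clinically
feasible doses.

A thin command-line front end (`inst/cli/combosens.R`) exposes the
`simulate`, `preprocess`, `noise`, `measures` and `prioritize` steps for
shell pipelines; see its header for usage.

## Package tour

| Module | Contents |
|---|---|
| `R/screen_io.R` | screen-table reader/writer, preprocessing pipeline, replicate-noise summary |
| `R/featurize.R` | PCA cell features, the four drug encodings, dataset assembly with AB/BA duplication |
| `R/modeling.R` | cell-blind / random-entry splits, 5-fold CV by MAE with per-fold PCA refit, random forest / elastic net / neural network / baselines behind one contract |
| `R/response_measures.R` | viability conversion, 3PL fitting, IC levels, CMax viability, dose-response matrices, combination CMax viability |
| `R/evaluate.R` | grouped MAE/PCC/R², duplicate agreement, paired Wilcoxon + Bonferroni + effect sizes |
| `R/prioritize.R` | treatment rankings and ranking scores |
| `R/synthetic_screen.R` | ground-truth world generator |
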