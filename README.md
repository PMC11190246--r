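# gcn16: predicting 16S rRNA gene copy number from sequence

Amplicon surveys count 16S rRNA gene *reads*, but prokaryotes carry
1–21 gene copies per genome, so read fractions systematically
over-represent high-copy taxa. Quantitative community profiling divides
each taxon's read fraction by its gene copy number (GCN) and
renormalizes — which requires predicting the GCN of unmeasured
organisms. `gcn16` is an R toolkit for that problem, aimed at
microbiome researchers and method developers. It provides:

* **A stacked ensemble regressor** (`sem()`) that predicts GCN directly
  from the 16S sequence: 6-mer counts feed a deep multi-layer
  perceptron (hidden layers 489-926-645-929-582-82; GELU/ReLU/ReLU/
  ELU/GELU/linear) and an RBF support vector regression (C = 11,
  gamma = 'auto') on 100 principal-component scores, aggregated by a
  ridge meta-learner (alpha = 49):

  `ghat(s) = beta_mlp * MLP(x_s) + beta_svr * SVR(PCA(x_s)) + beta' PCA(x_s) + beta_0`,

  where `x_s` is the k-mer count vector of sequence `s`.
* **Classical baselines**: taxonomy aggregation (`taxonomy_tree()`,
  every taxon's value is the mean of its sub-taxa) and five
  phylogenetic hidden-state-prediction algorithms (`hsp_*`): empirical
  probabilities, subtree averaging, Sankoff maximum parsimony,
  weighted-squared-change parsimony, independent contrasts.
* **Sequence preparation**: IUPAC-aware reverse complementation,
  strand orientation by seed-and-extend alignment against a conserved
  template with Karlin–Altschul E-values, degenerate-primer trimming
  to hypervariable subregions.
* **Community correction** (`correct_composition()`) with
  mock-community evaluation by Bray–Curtis dissimilarity.
* **Interpretation**: Kernel SHAP attribution of k-mer features
  (exact for ≤ 12 active features, constrained sampling otherwise),
  projection onto alignment/reference coordinates, per-locus
  substitution/deletion/insertion rates, and a rank-clustered ELU fit
  of the SHAP-vs-insertion-rate envelope.
* **Seeded simulators** (`simulate_gcn_dataset()`) producing trees,
  evolved sequences with their *true* alignments, motif-determined
  copy-number traits with known Bayes error, nested lineages and mock
  communities, so every component is testable without downloads.

## Worked example

```r
library(gcn16)

sim <- simulate_gcn_dataset(n_tips = 120, seed = 42)
train <- names(sim$labels)[1:90]
test  <- setdiff(names(sim$labels), train)

fit <- sem(sim$sequences[train], sim$labels[train],
           mlp_layers = c(64L, 32L), mlp_activations = c("gelu", "relu"),
           epochs = 50, batch_size = 32, pca_components = 50, seed = 1)
fit
#> Stacked ensemble 16S copy-number model
#>   training sequences: 90 | k-mer vocabulary: 1592 (K = 6)
#>   MLP: 64-32 + linear out | PCA components: 50
#>   SVR: C = 11 , gamma = 0.02 | ridge alpha = 49 (oof stacking)
#>   training RMSE: 0.4689 copies/genome

pred <- predict(fit, sim$sequences[test])
round(head(pred, 4), 2)
#>  t91  t92  t93  t94
#> 5.65 4.90 5.08 4.31
rmse(pred, sim$labels[test])
#> held-out RMSE: 0.659 copies/genome
```

Held-out predictions track the simulated copy numbers (truth for the
four tips above: 6.73, 6.32, 4.61, 4.59). The baselines on the same
split are worse — phylogenetic independent contrasts reach RMSE 0.731
and taxonomy aggregation 0.908 — reproducing the expected ordering:
sequence-based ensemble ≤ phylogeny ≤ taxonomy.

Correcting a ten-strain mock community with the ensemble's estimates
roughly halves the compositional error:

```r
mock <- make_mock_community("even", n = 10,
                            gcn = unname(sim$labels[test[1:10]]), seed = 1)
evaluate_mock(mock$cell_count, mock$gcn,
              list(sem = unname(pred[test[1:10]])))
#>     estimator bray_curtis
#> 1 uncorrected      0.1105
#> 2         sem      0.0639
#> 3      oracle      0.0000
```

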