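# epigat

Enhancer–promoter interaction (EPI) prediction with a dynamic
graph-attention edge classifier, in R.

Enhancers regulate genes across tens to hundreds of kilobases, and the
wiring is rarely one-to-one: single enhancers drive several promoters,
several enhancers converge on one promoter, and these relationships form
small, densely connected regulatory neighbourhoods. `epigat` models EPI
prediction as **edge classification on a bipartite graph**: enhancers
and promoters are nodes carrying windowed epigenomic signal profiles,
candidate pairs are edges, and a hybrid neural network decides per edge
whether the pair interacts.

The model, for node features $x_i$ and edge features $e_{ij}$:

- per-element CNN encoders (independent for enhancers and promoters)
  over the 7 × 21 marker-by-window feature matrix, with kernels `(1, k)`
  that slide along the window axis only:
  $x_{cnn} = W_{fc}\,\mathrm{Flatten}(\mathrm{MaxPool}(\mathrm{LeakyReLU}(W_{conv} * x + b))) + b_{fc}$;
- node inputs $x = [x_{cnn}; x_{deg}; x_{type}]$ (embedding, degree,
  one-hot type);
- a multi-head GATv2 layer with **dynamic attention**
  $\alpha_{ij} = \mathrm{softmax}_j\, a^\top \mathrm{LeakyReLU}(W [x_i; x_j; e_{ij}])$,
  node update $x_i' = \mathrm{ELU}(\sum_j \alpha_{ij} W [x_i; x_j; e_{ij}])$;
- an edge attention classifier
  $p = W_{clas}\,\mathrm{ELU}(a_e \odot [x_i'; x_j'; e_{ij}]) + b_{clas}$;
- a combined loss
  $L = w\,\mathrm{BCE}(\sigma(p), y) + (1-w)\max(0,\, 1 - y'p)$ with
  $y' = 2y - 1$.

Around the model sits the full pipeline: positive selection from
BENGI-style pair tables, promoter mapping (TSS −1500/+500, strand
aware), distance filtering (42 kb–500 kb), balanced negative sampling
from interaction-free promoters, masked 7 × 21 feature extraction from
narrowPeak tracks, **leakage-free connectivity-based 3:1:1 splits**
(whole connected components per split), EPI-network topology statistics
(degree distributions, bipartite clustering coefficients,
connected-subgraph statistics, cross-dataset intersections,
random-forest feature importance), and a synthetic fixture generator
with planted regulatory structure. The forward and backward passes are
implemented in vectorised base R and verified against a straight-line
oracle and finite-difference gradient checks.

## Worked example

The package ships a self-contained generator, so a complete study runs
in about half a minute:

```r
library(epigat)

run <- run_epi_pipeline(benchmark_config(seed = 1),
                        model_config(seed = 2),
                        train_config(epochs = 50, seed = 2))
str(run$prep)
#> List of 4
#>  $ n_raw         : int 387
#>  $ n_positive_raw: int 387
#>  $ n_positive    : int 387
#>  $ n_negative    : int 371
str(run$metrics)
#> List of 8
#>  $ auc      : num 1
#>  $ aupr     : num 1
#>  $ tpr      : num 0.966
#>  $ fpr      : num 0
#>  $ precision: num 1
#>  $ n_pos    : int 87
#>  $ n_neg    : int 63
#>  $ threshold: num 0.5
```

The fixture plants 387 positive pairs over ~700 elements with a
5-standard-deviation signal enrichment at interacting elements;
`prepare_samples()` matches them with 371 interaction-free negatives
(the quota rule caps negatives at the per-enhancer positive count).
After a connectivity-based split, 50 training epochs recover the
planted signal essentially perfectly on the held-out test components
(AUC/AUPR 1.0; TPR 0.966 and precision 1.0 at threshold 0.5). Re-running
the identical pipeline with `shuffle_labels = TRUE` collapses held-out
AUC to ~0.5 — the negative control that shows nothing but the planted
signal reaches the model.

Individual stages are exported: `generate_fixture()` /
`write_fixture()`, `prepare_samples()`, `featurize_all()`,
`build_epi_graph()`, `split_by_connectivity()`, `train_epi_model()`,
`evaluate_epi_model()`, and the `degree_distributions()` /
`bipartite_clustering()` / `component_stats()` / `epi_intersection()` /
`feature_importance()` topology tools. A command-line driver with
`simulate`, `prepare`, `featurize`, `train`, `evaluate` and `netstats`
subcommands is installed at `inst/cli/epigat.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/epigat.R", package="epigat"))')" \
    simulate --config sim.yaml --out fixture/
```

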