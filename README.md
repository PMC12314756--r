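# tdtgraph

Graph learning for suicidal-ideation screening from Tree-Drawing Test (TDT)
feature codes.

## The problem

The Tree-Drawing Test is a projective psychological assessment: a subject
draws a tree, and raters code the drawing on a fixed vocabulary of binary
features (canopy shape, line quality, roots, attachments, ...). Screening
studies binarize a Beck-style ideation scale at mean + SD, which produces a
severely imbalanced classification problem — in the study structure this
package targets, 94 of 806 subjects are high-ideation (7.57:1).

`tdtgraph` treats screening as **transductive node classification** on a
bipartite *semantic graph*: drawings and the 98 catalog features are both
vertices, with an edge whenever a drawing exhibits a feature
(A(i,j) = 1 iff e_ij ∈ E). The pipeline is:

1. **Graph construction** from the binary coding matrix, with the
   symmetrically normalized adjacency  = D^(−1/2) A D^(−1/2);
2. **node2vec-style initialization** — biased second-order random walks
   (return parameter p, in–out parameter q) plus skip-gram with negative
   sampling give each vertex a k-dimensional embedding X;
3. a **cost-sensitive two-layer GCN**,
   H^(l+1) = ReLU(Â H^(l) W^(l)), H^(0) = X, with a 2-logit softmax head,
   trained by the weighted cross-entropy
   −(1/T) Σ_j [ w_c·y_j·log ŷ_j + (1−y_j)·log(1−ŷ_j) ]
   (the positive class alone carries the weight, default w_c = 7);
4. **imbalance-aware evaluation**: precision_0, recall_1, macro-F1, G-mean
   and FPR.

The package also provides a seeded synthetic-cohort generator emulating the
study's structure (no drawing data is publicly deposited), a surrogate
per-feature extractor trained with the cost-sensitive multi-label
cross-entropy (weight w_f on each feature's minority class, default 4),
classic ML baselines (LR, DT, SVM, RF), and an experiment harness for
feature-class ablation, w_c / w_f / depth sensitivity, and stability under
training-set shrinkage and edge dropout. It is intended for methods
researchers in computational psychiatry who want a reproducible, fully
synthetic testbed for graph-based screening pipelines.

## Worked example

```r
library(tdtgraph)

cohort <- simulate_cohort(cohort_config(seed = 42))
cohort
#> <tdt_cohort> 806 drawings x 98 features, 94 high / 712 low ideation (seed 42)

graph <- build_semantic_graph(cohort$Z, cohort$labels)
graph
#> <semantic_graph> 806 image + 98 feature vertices, 16108 edges (density 0.0395)

split <- split_nodes(n_images = 806, train_fraction = 0.8, seed = 42)  # 645 / 161

emb <- embed_graph(graph, embedding_config(
  k = 64, walks_per_node = 5, walk_length = 40, window = 5, epochs = 3,
  seed = 42
))

fit <- train_detector(graph, emb, split$train, train_config(seed = 42))
fit
#> <tdt_gcn> 2-layer GCN, w_c=7.0, 600 epochs (best 597), train loss 0.6311

metrics <- evaluate_detector(fit, split$test)
dplyr::mutate(
  metrics[c("macro_F1", "G_mean", "recall_1", "precision_0", "FPR")],
  dplyr::across(dplyr::everything(), as_percent)
)
#> # A tibble: 1 × 5
#>   macro_F1 G_mean recall_1 precision_0   FPR
#>      <dbl>  <dbl>    <dbl>       <dbl> <dbl>
#> 1     64.9   72.7     66.7        94.1  20.7
```

Reading the numbers: the default synthetic cohort plants a moderate group
signal (log-odds +2) in the "leaf and flower" feature class. On the held-out
161 drawings the detector recovers two thirds of the high-ideation subjects
(recall_1 66.7%) while keeping the false-positive rate at 20.7%; G-mean
72.7% summarizes the balance between the two class recalls. With the class
weight lowered to `w_c = 1` the same model collapses to the majority class
(recall_1 = G-mean = 0) — the behaviour the cost-sensitive loss exists to
fix.

Experiment protocols run the whole pipeline across seeds and return tidy
tables with `autoplot()` methods, e.g.

```r
ablation <- run_ablation(run_config(n_seeds = 5))
autoplot(ablation)
```

A thin command-line front end over the same functions is installed at
`inst/cli/tdtgraph` (subcommands `simulate`, `build-graph`, `embed`,
`train`, `evaluate`, `compare`, `ablate`, `sweep-wc`, `sweep-wf`,
`sweep-layers`, `stability-train`, `stability-edges`).

## Package layout

- `R/` — catalog, cohort simulator, semantic graph, embeddings (Rcpp core
  in `src/`), GCN detector, metrics, baselines, experiment harness,
  tidiers and plots.
- `vignettes/methods.Rmd` — the model, its assumptions, parameter
  defaults, numerical choices and known limitations.
- `tests/testthat/` — unit and property tests per module plus end-to-end
  acceptance checks (`test-acceptance.R`).
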